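# Feature-level aggregation of enrichment z-scores and the comparative
# statistics: head-on vs codirectional contrasts, paired genotype
# differences, and the per-genotype enrichment-vs-expression regression.

#' Aggregate a z-score track over annotated features
#'
#' The enrichment score of a feature is the median robust z-score of the
#' bins covering it, taken on the strand sense to the transcript. The
#' scored window is the whole feature or its first 100 bp from the 5' end
#' (features shorter than the window use their full span). Masked features
#' (e.g. multicopy rRNA collapsed to a consensus) are skipped; a feature
#' with no covered bins is recorded as missing, not zero.
#'
#' @param ztrack Data frame with `start`, `end`, `strand`, `z` (one row
#'   per bin; see [robust_z()]).
#' @param features Feature data frame (as from [generate_genome()]).
#' @param window `"full"` or `"first100"`.
#' @param keep_masked Include masked features (default `FALSE`).
#' @return A feature score table: `feature_id`, `feature_class`,
#'   `orientation`, `window`, `score`, `n_bins`.
#' @export
score_features <- function(ztrack, features, window = c("full", "first100"),
                           keep_masked = FALSE) {
  window <- match.arg(window)
  .check_columns(ztrack, c("start", "end", "strand", "z"), "ztrack")
  .check_columns(features, c("feature_id", "feature_class", "start", "end",
                             "strand", "orientation"), "features")
  feats <- features
  if (!keep_masked && "masked" %in% names(features))
    feats <- features[!features$masked, , drop = FALSE]
  mids <- (ztrack$start + ztrack$end) / 2
  score <- numeric(nrow(feats)); nb <- integer(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    s <- f$start; e <- f$end
    if (window == "first100" && (e - s) > 100) {
      if (f$strand == "+") e <- s + 100 else s <- e - 100
    }
    hit <- ztrack$strand == f$strand & mids >= s & mids < e
    nb[i] <- sum(hit)
    score[i] <- if (nb[i] > 0) stats::median(ztrack$z[hit]) else NA_real_
  }
  data.frame(feature_id = feats$feature_id,
             feature_class = feats$feature_class,
             orientation = feats$orientation,
             window = window, score = score, n_bins = nb,
             stringsAsFactors = FALSE)
}

.star_category <- function(q) {
  ifelse(is.na(q), "",
         ifelse(q < 0.001, "***",
                ifelse(q < 0.01, "**",
                       ifelse(q < 0.05, "*", ""))))
}

.boot_ci_median_diff <- function(a, b, n_boot, seed, paired = FALSE) {
  set.seed(seed)
  if (paired) {
    d <- b - a
    stat <- vapply(seq_len(n_boot), function(i)
      stats::median(d[sample.int(length(d), replace = TRUE)]), numeric(1))
  } else {
    stat <- vapply(seq_len(n_boot), function(i)
      stats::median(a[sample.int(length(a), replace = TRUE)]) -
        stats::median(b[sample.int(length(b), replace = TRUE)]),
      numeric(1))
  }
  stats::quantile(stat, c(0.025, 0.975), names = FALSE)
}

#' Head-on vs codirectional comparison of feature scores
#'
#' Difference of group medians (head-on minus codirectional) with a seeded
#' percentile-bootstrap 95% CI and a two-sided Wilcoxon rank-sum p-value.
#' Optional filters restrict to one feature class and to the top or bottom
#' expression quintile (computed within the filtered class). Groups with
#' fewer than `min_n` features get a point estimate only, mirroring the
#' treatment of the low-copy rRNA class. Run a batch of comparisons through
#' [add_fdr()] to attach Benjamini-Hochberg q-values and star categories.
#'
#' @param scores Feature score table from [score_features()].
#' @param feature_class Optional class filter.
#' @param expression Optional data frame `feature_id`, `expr_z` used by
#'   `expression_filter`.
#' @param expression_filter `"none"`, `"top20"` or `"bottom20"`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @param min_n Minimum group size for CI and test (default 3).
#' @return One-row data frame: `label`, `n_head_on`, `n_codirectional`,
#'   `estimate` (median difference), `ci_lower`, `ci_upper`, `p_value`.
#' @export
orientation_comparison <- function(scores, feature_class = NULL,
                                   expression = NULL,
                                   expression_filter = c("none", "top20",
                                                         "bottom20"),
                                   n_boot = 1000, seed = 1, min_n = 3) {
  expression_filter <- match.arg(expression_filter)
  s <- scores[!is.na(scores$score), , drop = FALSE]
  if (!is.null(feature_class))
    s <- s[s$feature_class %in% feature_class, , drop = FALSE]
  if (expression_filter != "none") {
    if (is.null(expression))
      stop("`expression` required for an expression filter", call. = FALSE)
    s <- merge(s, expression[, c("feature_id", "expr_z")],
               by = "feature_id")
    cut <- stats::quantile(s$expr_z,
                           if (expression_filter == "top20") 0.8 else 0.2)
    s <- if (expression_filter == "top20")
      s[s$expr_z >= cut, , drop = FALSE]
    else s[s$expr_z <= cut, , drop = FALSE]
  }
  ho <- s$score[s$orientation == "head_on"]
  cd <- s$score[s$orientation == "codirectional"]
  if (!length(ho) || !length(cd))
    stop("both orientation groups must be non-empty after filters",
         call. = FALSE)
  est <- stats::median(ho) - stats::median(cd)
  label <- paste0(if (is.null(feature_class)) "all"
                  else paste(feature_class, collapse = "+"),
                  if (expression_filter != "none")
                    paste0(":", expression_filter) else "",
                  ":", scores$window[1])
  out <- data.frame(label = label, n_head_on = length(ho),
                    n_codirectional = length(cd), estimate = est,
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  if (length(ho) >= min_n && length(cd) >= min_n) {
    ci <- .boot_ci_median_diff(ho, cd, n_boot, seed)
    out$ci_lower <- ci[1]; out$ci_upper <- ci[2]
    out$p_value <- stats::wilcox.test(ho, cd, exact = FALSE)$p.value
  }
  out
}

#' Paired genotype difference of feature scores
#'
#' Per-feature difference of enrichment scores between two genotypes
#' (b minus a), paired by feature. Reports the median paired difference
#' with a seeded percentile-bootstrap 95% CI and a Wilcoxon signed-rank
#' p-value. Classes with fewer than `min_n` paired features are reported
#' as point estimates only: the default of 4 exempts the handful of
#' consensus rRNA loci from interval estimation and testing.
#'
#' @param scores_a,scores_b Feature score tables sharing feature ids.
#' @param feature_class Optional class filter.
#' @param n_boot,seed As in [orientation_comparison()].
#' @param min_n Minimum paired features for a CI and test (default 4).
#' @return One-row data frame like [orientation_comparison()], with `n`
#'   the number of paired features.
#' @export
genotype_paired_difference <- function(scores_a, scores_b,
                                       feature_class = NULL,
                                       n_boot = 1000, seed = 1, min_n = 4) {
  m <- merge(scores_a[, c("feature_id", "feature_class", "score")],
             scores_b[, c("feature_id", "score")],
             by = "feature_id", suffixes = c("_a", "_b"))
  m <- m[!is.na(m$score_a) & !is.na(m$score_b), , drop = FALSE]
  if (!is.null(feature_class))
    m <- m[m$feature_class %in% feature_class, , drop = FALSE]
  if (!nrow(m))
    stop("no shared features after filtering", call. = FALSE)
  d <- m$score_b - m$score_a
  out <- data.frame(label = if (is.null(feature_class)) "all"
                    else paste(feature_class, collapse = "+"),
                    n = length(d), estimate = stats::median(d),
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  if (length(d) >= min_n) {
    ci <- .boot_ci_median_diff(m$score_a, m$score_b, n_boot, seed,
                               paired = TRUE)
    out$ci_lower <- ci[1]; out$ci_upper <- ci[2]
    out$p_value <- stats::wilcox.test(d, exact = FALSE)$p.value
  }
  out
}

#' Benjamini-Hochberg correction and star categories for a batch
#'
#' Attaches `q_value` (BH-adjusted across the batch) and the printed star
#' bands: `*` for 0.01 <= FDR < 0.05, `**` for 0.001 <= FDR < 0.01,
#' `***` for FDR < 0.001.
#'
#' @param comparisons Data frame of stacked comparison rows with a
#'   `p_value` column.
#' @return The input with `q_value` and `stars` columns.
#' @export
add_fdr <- function(comparisons) {
  .check_columns(comparisons, "p_value", "comparisons")
  comparisons$q_value <- stats::p.adjust(comparisons$p_value,
                                         method = "BH")
  comparisons$stars <- .star_category(comparisons$q_value)
  comparisons
}

#' Bayesian regression of CDS enrichment on orientation and expression
#'
#' Fits, for one genotype, the linear model
#' `score ~ orientation + expression z + orientation:expression z` with a
#' normal likelihood and weakly-informative conjugate priors
#' (Normal-Inverse-Gamma: coefficients N(0, 100 sigma^2), scale
#' InvGamma(0.01, 0.01)), and returns exact posterior draws.
#'
#' @param scores Feature score table restricted to CDSs (rows with other
#'   classes are dropped).
#' @param expression Data frame `feature_id`, `expr_z`.
#' @param n_draws Posterior draws (default 500).
#' @param seed Draw seed.
#' @return Object of class `feature_regression`: draws matrix (columns
#'   `intercept`, `orientation_head_on`, `expr_z`, `orientation:expr_z`),
#'   posterior means and 95% quantile intervals.
#' @export
fit_feature_regression <- function(scores, expression, n_draws = 500,
                                   seed = 1) {
  s <- scores[scores$feature_class == "CDS" & !is.na(scores$score), ,
              drop = FALSE]
  s <- merge(s, expression[, c("feature_id", "expr_z")], by = "feature_id")
  if (nrow(s) < 20)
    stop("need at least 20 CDSs with score and expression", call. = FALSE)
  ho <- as.numeric(s$orientation == "head_on")
  X <- cbind(intercept = 1, orientation_head_on = ho, expr_z = s$expr_z,
             `orientation:expr_z` = ho * s$expr_z)
  if (qr(X)$rank < ncol(X))
    stop("collinear (degenerate) design", call. = FALSE)
  y <- s$score
  n <- length(y); p <- ncol(X)
  # Conjugate NIG posterior: V0 = 100 I, m0 = 0, a0 = b0 = 0.01.
  V0i <- diag(p) / 100
  a0 <- 0.01; b0 <- 0.01
  Vn <- solve(V0i + crossprod(X))
  mn <- Vn %*% crossprod(X, y)
  an <- a0 + n / 2
  bn <- b0 + 0.5 * (sum(y^2) - t(mn) %*% (V0i + crossprod(X)) %*% mn)
  set.seed(substream_seed(seed, "feature_regression"))
  sigma2 <- 1 / stats::rgamma(n_draws, an, rate = as.numeric(bn))
  L <- chol(Vn)
  z <- matrix(stats::rnorm(n_draws * p), n_draws, p)
  draws <- sweep(z %*% L * sqrt(sigma2), 2, as.numeric(mn), `+`)
  colnames(draws) <- colnames(X)
  qi <- apply(draws, 2, .quantile_interval, level = 0.95)
  structure(list(draws = draws, mean = colMeans(draws),
                 ci_lower = qi[1, ], ci_upper = qi[2, ],
                 n = n, n_draws = n_draws),
            class = "feature_regression")
}

#' @export
print.feature_regression <- function(x, ...) {
  cat(sprintf("Feature regression: %d CDSs, %d draws\n", x$n, x$n_draws))
  print(round(cbind(mean = x$mean, `2.5%` = x$ci_lower,
                    `97.5%` = x$ci_upper), 4))
  invisible(x)
}

#' @export
coef.feature_regression <- function(object, ...) object$mean
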