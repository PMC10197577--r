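# Bayesian per-CDS mutation-rate regression. For each mutation class m
# (transition, transversion, indel), per-CDS-per-genotype counts are
#   y ~ Poisson(exposure * exp(eta)),  exposure = CDS length x generations
# with eta a linear predictor in genotype, RDH enrichment z, expression z,
# orientation (head-on = 1) and declared interactions. Standardized
# coefficients get Normal(0, 1) priors; the intercept (a log rate per bp
# per generation) gets a diffuse normal prior. Hypotheses about each
# coefficient are scored by region-based Bayes factors: K for the favored
# directional hypothesis, K0 for the region of practical equivalence
# around zero.

.known_interactions <- c("genotype:rdh", "genotype:expr",
                         "orientation:expr", "orientation:rdh")

# Shared recipe: model matrix from covariate rows. `genotypes` fixes the
# reference level and dummy order.
.design_matrix <- function(df, genotypes, interactions) {
  ho <- as.numeric(df$orientation == "head_on")
  X <- cbind(intercept = rep(1, nrow(df)))
  for (g in genotypes[-1])
    X <- cbind(X, as.numeric(df$genotype == g))
  colnames(X)[-1] <- paste0("genotype_", genotypes[-1])
  X <- cbind(X, rdh_z = df$rdh_z, expr_z = df$expr_z, head_on = ho)
  for (ia in interactions) {
    if (!ia %in% .known_interactions)
      stop(sprintf("unknown interaction '%s' (available: %s)", ia,
                   paste(.known_interactions, collapse = ", ")),
           call. = FALSE)
    if (ia == "orientation:expr")
      X <- cbind(X, `head_on:expr_z` = ho * df$expr_z)
    if (ia == "orientation:rdh")
      X <- cbind(X, `head_on:rdh_z` = ho * df$rdh_z)
    if (ia == "genotype:rdh")
      for (g in genotypes[-1]) {
        X <- cbind(X, as.numeric(df$genotype == g) * df$rdh_z)
        colnames(X)[ncol(X)] <- paste0("genotype_", g, ":rdh_z")
      }
    if (ia == "genotype:expr")
      for (g in genotypes[-1]) {
        X <- cbind(X, as.numeric(df$genotype == g) * df$expr_z)
        colnames(X)[ncol(X)] <- paste0("genotype_", g, ":expr_z")
      }
  }
  X
}

#' Assemble the mutation-regression design
#'
#' Builds one row per (CDS, genotype) with per-class mutation counts,
#' exposure (CDS length in bp times the genotype's total generations),
#' and standardized covariates: RDH enrichment z (per genotype), shared
#' expression z, and the head-on indicator. Insertions and deletions are
#' pooled into the `indel` class. Continuous covariates are re-standardized
#' by robust z over the assembled design; rows with a missing covariate
#' are dropped with a message.
#'
#' @param features Feature data frame; CDS rows define the analysis set.
#' @param feature_scores Named list (one per genotype) of score tables
#'   from [score_features()] providing the per-CDS RDH covariate.
#' @param expression Data frame `feature_id`, `expr_z`.
#' @param catalog A `mutation_catalog` (counts and generations).
#' @param interactions Character vector among
#'   `"genotype:rdh"`, `"genotype:expr"`, `"orientation:expr"`,
#'   `"orientation:rdh"`.
#' @return Object of class `mutation_design`: `data` (rows with counts and
#'   covariates), `X` (model matrix), `classes`, `genotypes`,
#'   `interactions`.
#' @export
build_design <- function(features, feature_scores, expression, catalog,
                         interactions = character(0)) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  genotypes <- names(feature_scores)
  unknown <- setdiff(genotypes, names(catalog$generations))
  if (length(unknown))
    stop(sprintf("unknown genotype(s) in scores: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cds <- features[features$feature_class == "CDS", , drop = FALSE]
  mut <- catalog$mutations
  mut$class3 <- ifelse(mut$class %in% c("insertion", "deletion"), "indel",
                       mut$class)
  rows <- list()
  for (g in genotypes) {
    sc <- feature_scores[[g]]
    d <- merge(cds[, c("feature_id", "start", "end", "orientation")],
               sc[, c("feature_id", "score")], by = "feature_id")
    d <- merge(d, expression[, c("feature_id", "expr_z")],
               by = "feature_id")
    d$genotype <- g
    mg <- mut[mut$genotype == g, , drop = FALSE]
    for (cls in c("transition", "transversion", "indel")) {
      mc <- mg[mg$class3 == cls, , drop = FALSE]
      cnt <- integer(nrow(d))
      if (nrow(mc)) {
        for (i in seq_len(nrow(d)))
          cnt[i] <- sum(mc$position >= d$start[i] & mc$position < d$end[i])
      }
      d[[paste0("count_", cls)]] <- cnt
    }
    d$exposure <- as.numeric(d$end - d$start) * catalog$generations[[g]]
    rows[[g]] <- d
  }
  data <- do.call(rbind, rows)
  names(data)[names(data) == "score"] <- "rdh_z"
  drop <- !is.finite(data$rdh_z) | !is.finite(data$expr_z)
  if (any(drop)) {
    message(sprintf("dropping %d row(s) with missing covariates",
                    sum(drop)))
    data <- data[!drop, , drop = FALSE]
  }
  if (any(data$exposure <= 0))
    stop("non-positive exposure", call. = FALSE)
  data$rdh_z <- robust_z(data$rdh_z)
  data$expr_z <- robust_z(data$expr_z)
  rownames(data) <- NULL
  X <- .design_matrix(data, genotypes, interactions)
  structure(list(data = data, X = X,
                 classes = c("transition", "transversion", "indel"),
                 genotypes = genotypes, interactions = interactions),
            class = "mutation_design")
}

#' @export
print.mutation_design <- function(x, ...) {
  cat(sprintf("Mutation design: %d rows (%d genotypes), %d terms [%s]\n",
              nrow(x$data), length(x$genotypes), ncol(x$X),
              paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

.mut_model_string <- "
model {
  for (i in 1:N) {
    log(lambda[i]) <- lex[i] + inprod(X[i, ], beta)
    y[i] ~ dpois(lambda[i])
  }
  beta[1] ~ dnorm(0, 0.01)
  for (k in 2:P) { beta[k] ~ dnorm(0, prec) }
}
"

#' Fit the Bayesian mutation-rate model
#'
#' Samples the posterior of the per-class Poisson regression by MCMC.
#' Classes share the design but have class-specific coefficients (no
#' pooling). Convergence is gated on the split-chain potential scale
#' reduction factor; an unconverged fit is an error reporting the worst
#' coefficient.
#'
#' @param design A [build_design()] result.
#' @param prior_sd Prior sd for standardized coefficients (default 1).
#' @param n_draws Total retained draws per class (default 1000).
#' @param chains,adapt,burn,thin MCMC controls; the block GLM sampler is
#'   fast per iteration but autocorrelated, so chains are run long and
#'   thinned (default thin 20).
#' @param seed Sampler seed.
#' @param rhat_max Convergence gate (default 1.01); set `Inf` to disable.
#' @param classes Subset of classes to fit (default all three).
#' @return Object of class `mutation_fit`: per class, coefficient draws
#'   and a pointwise log-likelihood matrix (used by [loo_compare()]).
#' @export
fit_mutation_model <- function(design, prior_sd = 1, n_draws = 1000,
                               chains = 2, adapt = 1000, burn = 2000,
                               thin = 20, seed = 1, rhat_max = 1.01,
                               classes = NULL) {
  stopifnot(inherits(design, "mutation_design"))
  if (nrow(design$data) < 50)
    stop("need at least 50 design rows", call. = FALSE)
  if (is.null(classes)) classes <- design$classes
  X <- design$X
  P <- ncol(X)
  per_chain <- ceiling(n_draws / chains)
  lex <- log(design$data$exposure)
  rjags::load.module("glm", quiet = TRUE)
  fits <- list()
  for (cls in classes) {
    y <- design$data[[paste0("count_", cls)]]
    # Center the intercept on the pooled log rate (folded into the
    # offset): a pure reparameterization that keeps the sampler in a
    # well-scaled region. The intercept prior is N(pooled, 10) on the
    # log-rate scale, i.e. diffuse.
    lpool <- log(max(sum(y), 0.5) / sum(design$data$exposure))
    data <- list(y = y, X = X, lex = lex + lpool, N = length(y), P = P,
                 prec = 1 / prior_sd^2)
    inits <- lapply(seq_len(chains), function(ch) list(
      beta = rep(0, P), .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = substream_seed(seed, paste0("mut_", cls, "_", ch))))
    model <- rjags::jags.model(textConnection(.mut_model_string),
                               data = data, inits = inits,
                               n.chains = chains, n.adapt = adapt,
                               quiet = TRUE)
    stats::update(model, burn, progress.bar = "none")
    sims <- rjags::coda.samples(model, "beta",
                                n.iter = per_chain * thin, thin = thin,
                                progress.bar = "none")
    rhats <- vapply(seq_len(P), function(k) .split_rhat(
      sapply(sims, function(s) as.matrix(s)[, k])), numeric(1))
    if (max(rhats) > rhat_max)
      stop(sprintf(paste0("mutation model for class '%s' did not ",
                          "converge: max split-Rhat %.3f at term '%s'"),
                   cls, max(rhats), colnames(X)[which.max(rhats)]),
           call. = FALSE)
    draws <- do.call(rbind, lapply(sims, as.matrix))[seq_len(n_draws), ,
                                                     drop = FALSE]
    colnames(draws) <- colnames(X)
    draws[, "intercept"] <- draws[, "intercept"] + lpool
    eta <- X %*% t(draws)                       # N x S
    loglik <- t(stats::dpois(y, exp(sweep(eta, 1, lex, `+`)), log = TRUE))
    fits[[cls]] <- list(draws = draws, loglik = loglik, rhat = rhats,
                        intercept_prior = list(mean = lpool, sd = 10))
  }
  structure(list(classes = classes, fits = fits, design = design,
                 prior_sd = prior_sd, n_draws = n_draws),
            class = "mutation_fit")
}

#' @export
print.mutation_fit <- function(x, ...) {
  cat(sprintf("Mutation-rate model: classes [%s], %d rows, %d draws\n",
              paste(x$classes, collapse = ", "), nrow(x$design$data),
              x$n_draws))
  invisible(x)
}

#' @export
coef.mutation_fit <- function(object, ...) {
  sapply(object$fits, function(f) colMeans(f$draws))
}

#' @export
summary.mutation_fit <- function(object, rope_halfwidth = 0.05, ...) {
  compute_bayes_factors(object, rope_halfwidth = rope_halfwidth)
}

#' Map a Bayes factor to the printed evidence category
#'
#' @param k Numeric Bayes factor(s).
#' @return `"very strong"` for K >= 150, `"strong"` for 20 <= K < 150,
#'   `"positive"` for 3 <= K < 20, `"weak"` otherwise.
#' @export
bf_category <- function(k) {
  ifelse(k >= 150, "very strong",
         ifelse(k >= 20, "strong",
                ifelse(k >= 3, "positive", "weak")))
}

# Region-based Bayes factor from posterior and prior masses of a
# hypothesis region: posterior odds over prior odds.
.bf_odds <- function(post, prior) {
  if (prior <= 0 || prior >= 1)
    stop("hypothesis has zero prior mass on one side; Bayes factor ",
         "undefined", call. = FALSE)
  if (post >= 1) return(Inf)
  (post / (1 - post)) / (prior / (1 - prior))
}

.bf_one <- function(post_masses, prior_masses) {
  direction <- if (post_masses[["pos"]] >= post_masses[["neg"]])
    "positive" else "negative"
  K <- .bf_odds(post_masses[[substr(direction, 1, 3)]],
                prior_masses[[substr(direction, 1, 3)]])
  K0 <- .bf_odds(post_masses[["rope"]], prior_masses[["rope"]])
  list(direction = direction, K = K, K0 = K0)
}

#' Region-based Bayes factors for model coefficients
#'
#' Scores three hypotheses for each coefficient beta: directional
#' (beta > delta or beta < -delta, whichever the posterior favors) and
#' near-zero (|beta| <= delta), with delta the half-width of the region of
#' practical equivalence. Each Bayes factor is the posterior odds of the
#' hypothesis against its complement divided by the prior odds, with
#' prior masses computed analytically from the normal prior. K reports
#' the directional evidence and K0 the near-zero evidence; a precisely
#' estimated coefficient close to zero can score high on both.
#'
#' @param x A `mutation_fit`, a numeric vector or matrix of posterior
#'   draws, or a list `list(mean =, sd =)` describing a normal posterior
#'   (masses then computed analytically).
#' @param prior List `list(mean = 0, sd = 1)` describing the normal prior
#'   (for a `mutation_fit`, taken from the fit; the intercept uses its own
#'   diffuse prior sd of 100).
#' @param rope_halfwidth Half-width delta of the near-zero region, in
#'   prior-sd units of the standardized coefficients (default 0.05).
#' @return A `posterior_report` data frame: one row per coefficient with
#'   posterior mean, 90% interval, `direction`, `K`, `K0` and the
#'   evidence `category` from [bf_category()].
#' @export
compute_bayes_factors <- function(x, prior = list(mean = 0, sd = 1),
                                  rope_halfwidth = 0.05) {
  .check_number(rope_halfwidth, "rope_halfwidth",
                lower = .Machine$double.eps)
  d <- rope_halfwidth

  prior_masses <- function(mean, sd) list(
    pos = stats::pnorm(d, mean, sd, lower.tail = FALSE),
    neg = stats::pnorm(-d, mean, sd),
    rope = stats::pnorm(d, mean, sd) - stats::pnorm(-d, mean, sd))

  report_vec <- function(draws, term, pr, class = NA_character_) {
    pm <- list(pos = mean(draws > d), neg = mean(draws < -d),
               rope = mean(abs(draws) <= d))
    bf <- .bf_one(pm, prior_masses(pr$mean, pr$sd))
    qi <- .quantile_interval(draws, 0.90)
    data.frame(class = class, term = term, mean = mean(draws),
               q05 = qi[1], q95 = qi[2], direction = bf$direction,
               K = bf$K, K0 = bf$K0, category = bf_category(bf$K),
               stringsAsFactors = FALSE)
  }

  if (inherits(x, "mutation_fit")) {
    out <- do.call(rbind, lapply(x$classes, function(cls) {
      draws <- x$fits[[cls]]$draws
      do.call(rbind, lapply(colnames(draws), function(term) {
        pr <- if (term == "intercept") x$fits[[cls]]$intercept_prior
        else list(mean = 0, sd = x$prior_sd)
        report_vec(draws[, term], term, pr, class = cls)
      }))
    }))
  } else if (is.list(x) && !is.null(x$mean) && !is.null(x$sd)) {
    # Analytic normal masses, with odds in log space so that saturated
    # tail masses (posterior mass ~ 1 on one side) still give finite K.
    logodds <- function(m, s) list(
      pos = stats::pnorm(d, m, s, lower.tail = FALSE, log.p = TRUE) -
        stats::pnorm(d, m, s, lower.tail = TRUE, log.p = TRUE),
      neg = stats::pnorm(-d, m, s, lower.tail = TRUE, log.p = TRUE) -
        stats::pnorm(-d, m, s, lower.tail = FALSE, log.p = TRUE),
      rope = {
        p_rope <- stats::pnorm(d, m, s) - stats::pnorm(-d, m, s)
        comp <- stats::pnorm(d, m, s, lower.tail = FALSE) +
          stats::pnorm(-d, m, s)
        log(p_rope) - log(comp)
      })
    lo_post <- logodds(x$mean, x$sd)
    lo_prior <- logodds(prior$mean, prior$sd)
    direction <- if (stats::pnorm(d, x$mean, x$sd, lower.tail = FALSE) >=
                       stats::pnorm(-d, x$mean, x$sd))
      "positive" else "negative"
    side <- substr(direction, 1, 3)
    K <- exp(lo_post[[side]] - lo_prior[[side]])
    K0 <- exp(lo_post$rope - lo_prior$rope)
    out <- data.frame(class = NA_character_, term = "coefficient",
                      mean = x$mean,
                      q05 = stats::qnorm(0.05, x$mean, x$sd),
                      q95 = stats::qnorm(0.95, x$mean, x$sd),
                      direction = direction, K = K, K0 = K0,
                      category = bf_category(K),
                      stringsAsFactors = FALSE)
  } else if (is.matrix(x)) {
    out <- do.call(rbind, lapply(colnames(x), function(term)
      report_vec(x[, term], term, prior)))
  } else if (is.numeric(x)) {
    out <- report_vec(x, "coefficient", prior)
  } else stop("unsupported input to compute_bayes_factors", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("posterior_report", "data.frame")
  out
}

#' @export
print.posterior_report <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$K <- signif(y$K, 3); y$K0 <- signif(y$K0, 3)
  y$mean <- round(y$mean, 3); y$q05 <- round(y$q05, 3)
  y$q95 <- round(y$q95, 3)
  print(y)
  invisible(x)
}

# Truncated importance-sampling LOO for one pointwise log-likelihood
# matrix (draws x observations). Returns elpd_i and an instability flag.
.tis_loo <- function(loglik) {
  S <- nrow(loglik)
  elpd <- numeric(ncol(loglik)); unstable <- logical(ncol(loglik))
  for (i in seq_len(ncol(loglik))) {
    ll <- loglik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    w <- exp(lw)
    cap <- sqrt(S) * mean(w)
    unstable[i] <- any(w > cap)
    w <- pmin(w, cap)
    elpd[i] <- log(sum(w * exp(ll)) / sum(w))
  }
  list(elpd = elpd, unstable = unstable)
}

#' Compare mutation models by approximate leave-one-out cross-validation
#'
#' Estimates each model's expected log pointwise predictive density by
#' importance sampling over posterior draws (with weight truncation at
#' sqrt(S) times the mean weight), pooling all fitted mutation classes,
#' and reports differences to the best model with standard errors.
#' Observations whose importance weights required truncation are counted
#' in `n_unstable`.
#'
#' @param fits Named list of `mutation_fit` objects sharing observation
#'   rows (and fitted classes).
#' @return Data frame sorted by elpd: `model`, `elpd`, `se_elpd`,
#'   `delta_elpd`, `se_delta`, `n_unstable`.
#' @export
loo_compare <- function(fits) {
  if (is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  mats <- lapply(fits, function(f) {
    stopifnot(inherits(f, "mutation_fit"))
    do.call(cbind, lapply(f$fits, `[[`, "loglik"))
  })
  ncols <- vapply(mats, ncol, integer(1))
  if (length(unique(ncols)) != 1L)
    stop("fits must share the same observation rows and classes",
         call. = FALSE)
  loos <- lapply(mats, .tis_loo)
  elpd_i <- sapply(loos, `[[`, "elpd")      # n_obs x n_models
  elpd <- colSums(elpd_i)
  best <- which.max(elpd)
  n <- nrow(elpd_i)
  out <- data.frame(
    model = names(fits), elpd = elpd,
    se_elpd = apply(elpd_i, 2, stats::sd) * sqrt(n),
    delta_elpd = elpd - elpd[best],
    se_delta = vapply(seq_along(fits), function(j) {
      if (j == best) 0 else stats::sd(elpd_i[, j] - elpd_i[, best]) *
        sqrt(n)
    }, numeric(1)),
    n_unstable = vapply(loos, function(l) sum(l$unstable), integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$elpd), ]
  rownames(out) <- NULL
  out
}

#' Fitted mutation-rate curves over a covariate grid
#'
#' Expected mutation count per unit exposure as one covariate varies with
#' all others held at their design means, summarized over posterior draws
#' as the mean and 90% quantile interval; optionally stratified by
#' orientation. Grid points outside the observed covariate range trigger
#' an extrapolation warning and are flagged.
#'
#' @param fit A `mutation_fit`.
#' @param class Mutation class to display.
#' @param covariate `"rdh_z"` or `"expr_z"`.
#' @param grid Numeric grid (default: 25 points over the observed range).
#' @param stratify_orientation If `TRUE`, one curve per orientation.
#' @return Data frame: `covariate_value`, optional `orientation`, `mean`,
#'   `q05`, `q95`, `extrapolated`.
#' @export
fitted_mutation_curves <- function(fit, class, covariate = c("rdh_z",
                                                             "expr_z"),
                                   grid = NULL,
                                   stratify_orientation = FALSE) {
  stopifnot(inherits(fit, "mutation_fit"))
  covariate <- match.arg(covariate)
  if (!class %in% fit$classes)
    stop(sprintf("class '%s' not fitted", class), call. = FALSE)
  data <- fit$design$data
  rng <- range(data[[covariate]])
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 25)
  extrapolated <- grid < rng[1] | grid > rng[2]
  if (any(extrapolated))
    warning("grid extends outside the fitted covariate range; ",
            "extrapolation flagged")
  orientations <- if (stratify_orientation)
    c("codirectional", "head_on") else "mean"
  draws <- fit$fits[[class]]$draws
  ho_mean <- mean(data$orientation == "head_on")
  base <- data.frame(
    genotype = fit$design$genotypes[1],
    rdh_z = mean(data$rdh_z), expr_z = mean(data$expr_z),
    orientation = "codirectional", stringsAsFactors = FALSE)
  rows <- list()
  for (orient in orientations) {
    nd <- base[rep(1, length(grid)), , drop = FALSE]
    nd[[covariate]] <- grid
    if (orient != "mean") nd$orientation <- orient
    Xn <- .design_matrix(nd, fit$design$genotypes,
                         fit$design$interactions)
    if (orient == "mean") Xn[, "head_on"] <- ho_mean
    # hold genotype at its design mean: average the dummies
    for (g in fit$design$genotypes[-1])
      Xn[, paste0("genotype_", g)] <-
        mean(data$genotype == g)
    rate <- exp(Xn %*% t(draws))        # grid x S, per unit exposure
    qi <- apply(rate, 1, .quantile_interval, level = 0.90)
    rows[[orient]] <- data.frame(
      covariate_value = grid,
      orientation = orient,
      mean = rowMeans(rate), q05 = qi[1, ], q95 = qi[2, ],
      extrapolated = extrapolated, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "covariate") <- covariate
  attr(out, "class_name") <- class
  out
}
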