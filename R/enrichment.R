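# Bayesian estimation of strand-specific binned log2 pulldown/input
# enrichment. Observation model: for bin b and sample j of a genotype,
#   y_bj ~ NB(mean = sf_j * lambda_b * 2^(alpha_b * is_pulldown_j), phi)
# with variance mean + mean^2/phi, a Normal(0,1) prior on the bin-level
# log2 enrichment alpha_b, a weak log-normal prior on the bin abundance
# lambda_b, and a shared per-genotype dispersion. Size factors use
# median-of-ratios normalization (robust to a minority of enriched bins,
# and invariant to rescaling any sample's counts); raw library totals are
# the fallback. Posteriors are sampled by MCMC (JAGS); 500 retained draws by
# default, summarized as the mean and equal-tailed 90% quantile interval.

# Size factors (per genotype). Within each sample type (input, pulldown),
# replicate depth differences are removed by median-of-ratios against the
# type's geometric-mean reference bin. The pulldown scale is then aligned
# to the input scale at the mode of the per-bin log ratio of the two
# reference tracks: enriched bins shift the mean and even the median of
# that ratio, but the background (unenriched) bins dominate its mode, so
# the alignment pins unenriched bins at zero log2 enrichment. Falls back
# to library totals when fewer than 10 bins are covered in every sample.
.size_factors <- function(counts, library_size, types) {
  covered <- rowSums(counts == 0) == 0
  if (sum(covered) < 10) {
    sf <- library_size
    return(sf / exp(mean(log(sf))))
  }
  m <- counts[covered, , drop = FALSE]
  sf <- numeric(ncol(m))
  refs <- list()
  for (t in unique(types)) {
    j <- which(types == t)
    ref <- exp(rowMeans(log(m[, j, drop = FALSE])))
    refs[[t]] <- ref
    sf[j] <- apply(m[, j, drop = FALSE], 2,
                   function(col) stats::median(col / ref))
  }
  if (all(c("input", "pulldown") %in% types)) {
    lr <- log(refs[["pulldown"]] / refs[["input"]])
    d <- stats::density(lr, n = 512)
    mode_lr <- d$x[which.max(d$y)]
    sf[types == "pulldown"] <- sf[types == "pulldown"] * exp(mode_lr)
  }
  sf / exp(mean(log(sf)))
}

.enrich_model_string <- "
model {
  for (n in 1:N) {
    mu[n] <- sf[n] * lam[bin[n]] * pow(2, alpha[bin[n]] * pull[n])
    p[n] <- phi / (phi + mu[n])
    y[n] ~ dnegbin(p[n], phi)
  }
  for (b in 1:B) {
    alpha[b] ~ dnorm(0, prec_alpha)
    llam[b] ~ dnorm(lmu0, 0.04)
    lam[b] <- exp(llam[b])
  }
  phi ~ dgamma(2, 0.1)
}
"

#' Fit the binned pulldown/input enrichment model
#'
#' Estimates per-bin, per-strand log2 enrichment of pulldown over input
#' sequencing for each genotype, with an approximate Bayesian posterior
#' sampled by MCMC. All-zero bins are shrunk toward zero enrichment by the
#' prior rather than producing NaN.
#'
#' @param counts A `count_matrix` (see [simulate_pulldown_counts()] or
#'   [read_count_matrix()]).
#' @param priors List: `alpha_sd` (prior sd of log2 enrichment, default 1)
#'   and `llam_sd` (prior sd of log bin abundance, default 5).
#' @param n_draws Retained posterior draws per genotype (default 500,
#'   minimum 100).
#' @param chains,adapt,burn MCMC controls.
#' @param seed Integer seed for the sampler.
#' @return An object of class `enrichment_fit` with per-genotype posterior
#'   draws, means and 90% quantile intervals, accessible through
#'   [enrichment_track()] and [coef.enrichment_fit()].
#' @export
fit_enrichment <- function(counts, priors = list(), n_draws = 500,
                           chains = 2, adapt = 500, burn = 1000, seed = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  .check_number(n_draws, "n_draws", lower = 100, integer = TRUE)
  alpha_sd <- if (is.null(priors$alpha_sd)) 1 else priors$alpha_sd
  samples <- counts$samples
  .check_columns(samples, c("sample", "genotype", "replicate", "type",
                            "library_size"), "samples")
  genotypes <- unique(samples$genotype)
  for (g in genotypes) {
    sg <- samples[samples$genotype == g, ]
    if (!any(sg$type == "input") || !any(sg$type == "pulldown"))
      stop(sprintf("genotype '%s' needs both input and pulldown samples",
                   g), call. = FALSE)
  }
  B <- nrow(counts$bins)
  per_chain <- ceiling(n_draws / chains)

  tracks <- list()
  for (g in genotypes) {
    idx <- which(samples$genotype == g)
    sf_sample <- .size_factors(counts$counts[, idx, drop = FALSE],
                               samples$library_size[idx],
                               samples$type[idx])
    y <- as.vector(counts$counts[, idx, drop = FALSE])
    bin <- rep(seq_len(B), times = length(idx))
    pull <- rep(as.numeric(samples$type[idx] == "pulldown"), each = B)
    sf <- rep(sf_sample, each = B)
    in_mean <- mean(counts$counts[, idx[samples$type[idx] == "input"],
                                  drop = FALSE])
    data <- list(y = y, bin = bin, pull = pull, sf = sf, N = length(y),
                 B = B, prec_alpha = 1 / alpha_sd^2,
                 lmu0 = log(max(in_mean, 0.5)))
    inits <- lapply(seq_len(chains), function(ch) list(
      alpha = rep(0, B), llam = rep(data$lmu0, B), phi = 10,
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = substream_seed(seed, paste0("enrich_", g, "_", ch))))
    model <- rjags::jags.model(textConnection(.enrich_model_string),
                               data = data, inits = inits,
                               n.chains = chains, n.adapt = adapt,
                               quiet = TRUE)
    stats::update(model, burn, progress.bar = "none")
    sims <- rjags::coda.samples(model, "alpha", n.iter = per_chain,
                                progress.bar = "none")
    draws <- t(do.call(rbind, lapply(sims, as.matrix)))[, seq_len(n_draws),
                                                        drop = FALSE]
    rhat <- if (chains > 1)
      max(vapply(seq_len(B), function(b) .split_rhat(
        sapply(sims, function(s) as.matrix(s)[, b])), numeric(1)))
    else NA_real_
    qi <- apply(draws, 1, .quantile_interval, level = 0.90)
    tracks[[g]] <- list(draws = draws, mean = rowMeans(draws),
                        q05 = qi[1, ], q95 = qi[2, ], rhat = rhat,
                        size_factors = stats::setNames(sf_sample,
                                                       samples$sample[idx]))
  }
  structure(list(bins = counts$bins, tracks = tracks,
                 genotypes = genotypes, n_draws = n_draws,
                 priors = list(alpha_sd = alpha_sd)),
            class = "enrichment_fit")
}

#' @export
print.enrichment_fit <- function(x, ...) {
  cat(sprintf(paste0("Enrichment fit: %d bins, genotypes [%s], ",
                     "%d posterior draws\n"),
              nrow(x$bins), paste(x$genotypes, collapse = ", "), x$n_draws))
  invisible(x)
}

#' @export
summary.enrichment_fit <- function(object, ...) {
  out <- do.call(rbind, lapply(object$genotypes, function(g) {
    tr <- object$tracks[[g]]
    data.frame(genotype = g,
               mean_alpha = mean(tr$mean),
               sd_alpha = stats::sd(tr$mean),
               max_rhat = tr$rhat, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
coef.enrichment_fit <- function(object, ...) {
  sapply(object$tracks, `[[`, "mean")
}

#' Extract a posterior enrichment track for one genotype
#'
#' @param fit An [fit_enrichment()] result.
#' @param genotype Genotype name.
#' @return An `enrichment_track`: list with `bins`, `mean`, `q05`, `q95`
#'   (90% quantile interval bounds), `draws` and `n_draws`.
#' @export
enrichment_track <- function(fit, genotype) {
  stopifnot(inherits(fit, "enrichment_fit"))
  if (!genotype %in% fit$genotypes)
    stop(sprintf("unknown genotype '%s'", genotype), call. = FALSE)
  tr <- fit$tracks[[genotype]]
  structure(list(bins = fit$bins, mean = tr$mean, q05 = tr$q05,
                 q95 = tr$q95, draws = tr$draws, n_draws = fit$n_draws,
                 genotype = genotype),
            class = "enrichment_track")
}

#' @export
print.enrichment_track <- function(x, ...) {
  cat(sprintf("Enrichment track (%s): %d bins, %d draws\n",
              x$genotype, nrow(x$bins), x$n_draws))
  invisible(x)
}

#' Posterior contrast between two genotype tracks
#'
#' Differences the posterior draws of two enrichment tracks bin by bin,
#' pairing draws by index (independent pairing by option), and summarizes
#' the contrast as mean and 90% quantile interval. The result can be
#' converted to robust z-scores and smoothed like any other track.
#'
#' @param track_a,track_b `enrichment_track` objects on identical bins.
#' @param paired Pair draws by index (default) or shuffle for independent
#'   pairing.
#' @param seed Seed for independent pairing.
#' @return An `enrichment_track` holding the contrast (a - b).
#' @export
genotype_contrast <- function(track_a, track_b, paired = TRUE, seed = 1) {
  stopifnot(inherits(track_a, "enrichment_track"),
            inherits(track_b, "enrichment_track"))
  if (!identical(track_a$bins, track_b$bins))
    stop("tracks have mismatched binning", call. = FALSE)
  db <- track_b$draws
  if (!paired) {
    set.seed(seed)
    db <- db[, sample.int(ncol(db)), drop = FALSE]
  }
  d <- track_a$draws - db
  qi <- apply(d, 1, .quantile_interval, level = 0.90)
  structure(list(bins = track_a$bins, mean = rowMeans(d), q05 = qi[1, ],
                 q95 = qi[2, ], draws = d, n_draws = ncol(d),
                 genotype = paste0(track_a$genotype, "-",
                                   track_b$genotype)),
            class = "enrichment_track")
}

#' Pearson correlation matrix across genotype tracks
#'
#' Genome-wide comparison of posterior-mean enrichment tracks.
#'
#' @param tracks Named list of equal-length numeric vectors (or
#'   `enrichment_track` objects, whose posterior means are used).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
track_correlation_matrix <- function(tracks) {
  vecs <- lapply(tracks, function(t)
    if (inherits(t, "enrichment_track")) t$mean else t)
  n <- lengths(vecs)
  if (length(unique(n)) != 1L)
    stop("tracks must have equal length", call. = FALSE)
  m <- do.call(cbind, vecs)
  if (any(apply(m, 2, stats::sd) == 0))
    stop("zero-variance track", call. = FALSE)
  stats::cor(m)
}
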