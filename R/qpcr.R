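# qPCR-based cross-genotype comparison of hybrid pulldown efficiency.
# Sequencing yields only relative enrichment within a genotype; the ddCq
# statistic against a spike-in reference locus puts genotypes on a common
# absolute scale.

#' Posterior summaries of qPCR ddCq per locus and genotype
#'
#' For each replicate, ddCq = (Cq_pulldown - Cq_input) at the locus minus
#' (Cq_pulldown - Cq_input) at the spike-in locus. Replicate ddCq values
#' are modelled with a normal likelihood, a flat location prior and a
#' half-normal scale prior; the posterior is sampled by MCMC and reported
#' as the mean and 95% highest-posterior-density interval (computed by
#' draw sorting).
#'
#' @param table Data frame with columns `locus`, `genotype`, `replicate`,
#'   `sample_type` (`input`/`pulldown`) and `Cq`.
#' @param spike_locus Name of the spike-in reference locus; must be
#'   measured for every (genotype, replicate, sample_type).
#' @param n_draws Posterior draws (default 2000).
#' @param seed Sampler seed.
#' @return Data frame: `locus`, `genotype`, `n_reps`, `mean`,
#'   `hpd_lower`, `hpd_upper`, plus a `replicate_ddcq` list-column.
#' @export
qpcr_ddcq <- function(table, spike_locus, n_draws = 2000, seed = 1) {
  .check_columns(table, c("locus", "genotype", "replicate", "sample_type",
                          "Cq"), "table")
  if (!spike_locus %in% table$locus)
    stop("spike-in locus absent from table", call. = FALSE)

  cq <- function(locus, genotype, replicate, type) {
    v <- table$Cq[table$locus == locus & table$genotype == genotype &
                    table$replicate == replicate &
                    table$sample_type == type]
    if (length(v) != 1L)
      stop(sprintf(paste0("missing or duplicated Cq for locus '%s', ",
                          "genotype '%s', replicate %s, %s"),
                   locus, genotype, replicate, type), call. = FALSE)
    v
  }

  loci <- setdiff(unique(table$locus), spike_locus)
  combos <- unique(table[table$locus != spike_locus,
                         c("locus", "genotype")])
  vals <- list(); grp <- integer(0)
  for (i in seq_len(nrow(combos))) {
    lc <- combos$locus[i]; g <- combos$genotype[i]
    reps <- unique(table$replicate[table$locus == lc &
                                     table$genotype == g])
    dd <- vapply(reps, function(r) {
      (cq(lc, g, r, "pulldown") - cq(lc, g, r, "input")) -
        (cq(spike_locus, g, r, "pulldown") - cq(spike_locus, g, r, "input"))
    }, numeric(1))
    vals[[i]] <- dd
    grp <- c(grp, rep(i, length(dd)))
  }
  y <- unlist(vals)
  sd_scale <- stats::sd(y)
  if (!is.finite(sd_scale)) sd_scale <- 1   # single replicate overall
  sd_scale <- max(sd_scale, 0.1)
  model_string <- "
  model {
    for (i in 1:N) { y[i] ~ dnorm(mu[grp[i]], tau[grp[i]]) }
    for (g in 1:G) {
      mu[g] ~ dnorm(0, 1.0E-6)
      sigma[g] ~ dnorm(0, prec_s) T(0,)
      tau[g] <- pow(sigma[g], -2)
    }
  }
  "
  data <- list(y = y, grp = grp, N = length(y), G = nrow(combos),
               prec_s = 1 / (10 * sd_scale)^2)
  inits <- list(mu = vapply(vals, mean, numeric(1)),
                sigma = rep(sd_scale, nrow(combos)),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = substream_seed(seed, "qpcr"))
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = 1, n.adapt = 500,
                             quiet = TRUE)
  stats::update(model, 500, progress.bar = "none")
  sims <- as.matrix(rjags::coda.samples(model, "mu", n.iter = n_draws,
                                        progress.bar = "none")[[1]])
  if (nrow(combos) == 1L) colnames(sims) <- "mu[1]"
  out <- combos
  out$n_reps <- lengths(vals)
  out$mean <- NA_real_; out$hpd_lower <- NA_real_; out$hpd_upper <- NA_real_
  for (i in seq_len(nrow(combos))) {
    d <- sims[, paste0("mu[", i, "]")]
    h <- .hpd_interval(d, 0.95)
    out$mean[i] <- mean(d)
    out$hpd_lower[i] <- h[["lower"]]
    out$hpd_upper[i] <- h[["upper"]]
  }
  out$replicate_ddcq <- I(vals)
  rownames(out) <- NULL
  out
}
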