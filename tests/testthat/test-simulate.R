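test_that("expression draws match their log-normal parameters", {
  n <- 1000L
  cfg <- sim_config(seed = 2, genome_length_bp = 2000000L,
                    terminus_pos = 1000000L, n_cds = n, n_ncrna = 0L,
                    n_rrna = 0L, n_trna = 0L, utr_fraction = 0,
                    expr_log_mean = 2, expr_log_sd = 1)
  gen <- generate_genome(cfg)
  expr <- simulate_expression(gen$features, cfg)
  expect_equal(nrow(expr), n)
  # law of large numbers: sample mean of log abundance near 2
  expect_lt(abs(mean(log(expr$abundance)) - 2), 3 / sqrt(n))
  expect_identical(expr, simulate_expression(gen$features, cfg))
  expect_equal(median(expr$expr_z), 0, tolerance = 1e-12)
})

test_that("degenerate expression propagates the robust-z error", {
  cfg <- small_genome_cfg(seed = 2, expr_log_sd = 0)
  gen <- generate_genome(cfg)
  expect_error(simulate_expression(gen$features, cfg), "degenerate")
})

test_that("hybrid truth reflects its generative parameters exactly", {
  zero_block <- list(baseline = 0, expr_slope = 0, utr5_boost = 0,
                     first100_boost = 0)
  cfg0 <- small_genome_cfg(seed = 4,
                           genotype_blocks = list(WT = zero_block))
  gen <- generate_genome(cfg0)
  expr <- simulate_expression(gen$features, cfg0)
  truth <- simulate_hybrid_truth(gen$features, expr, cfg0)
  expect_true(all(truth$truth_WT == 0))

  # a pure 5'-UTR boost separates UTR5 bins from CDS bins by exactly b
  b <- 0.8
  cfgU <- small_genome_cfg(seed = 4, genotype_blocks = list(
    WT = list(baseline = 0, expr_slope = 0, utr5_boost = b,
              first100_boost = 0)))
  truthU <- simulate_hybrid_truth(gen$features, expr, cfgU)
  mids <- (truthU$start + truthU$end) / 2
  in_class <- function(cls) {
    f <- gen$features[gen$features$feature_class == cls, ]
    hit <- rep(FALSE, nrow(truthU))
    for (i in seq_len(nrow(f)))
      hit <- hit | (truthU$strand == f$strand[i] & mids >= f$start[i] &
                      mids < f$end[i])
    hit
  }
  utr5 <- in_class("UTR5")
  cds <- in_class("CDS")
  expect_equal(mean(truthU$truth_WT[utr5]) - mean(truthU$truth_WT[cds]),
               b)
})

test_that("expression slope ordering is recoverable from the truth", {
  cfg <- small_genome_cfg(seed = 9, genotype_blocks = list(
    WT = list(baseline = 0, expr_slope = 0.2, utr5_boost = 0,
              first100_boost = 0),
    rnhC = list(baseline = 0, expr_slope = 0.7, utr5_boost = 0,
                first100_boost = 0)))
  gen <- generate_genome(cfg)
  expr <- simulate_expression(gen$features, cfg)
  truth <- simulate_hybrid_truth(gen$features, expr, cfg)
  cds <- gen$features[gen$features$feature_class == "CDS", ]
  mids <- (truth$start + truth$end) / 2
  zmap <- stats::setNames(expr$expr_z, expr$feature_id)
  rows <- do.call(rbind, lapply(seq_len(nrow(cds)), function(i) {
    hit <- truth$strand == cds$strand[i] & mids >= cds$start[i] &
      mids < cds$end[i]
    data.frame(z = zmap[[cds$feature_id[i]]],
               wt = mean(truth$truth_WT[hit]),
               rc = mean(truth$truth_rnhC[hit]))
  }))
  slope_wt <- coef(lm(wt ~ z, rows))["z"]
  slope_rc <- coef(lm(rc ~ z, rows))["z"]
  expect_gt(slope_rc, slope_wt)
  expect_equal(unname(slope_wt), 0.2, tolerance = 1e-6)
  expect_equal(unname(slope_rc), 0.7, tolerance = 1e-6)
})

test_that("pulldown counts have NB moments around the truth", {
  truth <- data.frame(start = seq(0, 1900, 100),
                      end = seq(100, 2000, 100), strand = "+",
                      truth_WT = 0)
  cfg <- sim_config(seed = 5, genome_length_bp = 2000L,
                    terminus_pos = 1000L, bin_bp = 100L,
                    genotype_blocks = list(WT = list(
                      baseline = 0, expr_slope = 0, utr5_boost = 0,
                      first100_boost = 0)),
                    depth = 50, dispersion = 10, n_reps = 250L,
                    size_factor_sd = 0)
  cm <- simulate_pulldown_counts(truth, cfg)
  pull <- cm$counts[, cm$samples$type == "pulldown"]
  inp <- cm$counts[, cm$samples$type == "input"]
  # zero truth, equal size factors: mean pulldown/input ratio near 1
  expect_equal(mean(rowMeans(pull)) / mean(rowMeans(inp)), 1,
               tolerance = 0.05)
  # overdispersion: across-replicate variance exceeds the mean
  vm <- apply(inp, 1, var) / rowMeans(inp)
  expect_gt(mean(vm), 1.5)
  # NB mean/variance relationship: var ~ mu + mu^2/size
  mu <- mean(rowMeans(inp))
  expect_equal(mean(apply(inp, 1, var)), mu + mu^2 / 10,
               tolerance = 0.15)
  expect_identical(cm$counts, simulate_pulldown_counts(truth, cfg)$counts)
})

test_that("mutation generator respects exposure and coefficients", {
  setup <- make_regression_setup(3, n = 200)
  # zero generations: no mutations at all
  cfg0 <- setup$config
  cfg0$generations_per_line <- 0L
  cat0 <- simulate_ma_mutations(setup$features, setup$covariates, cfg0)
  expect_equal(nrow(cat0$mutations), 0L)

  # all coefficients zero: pooled rate matches exp(intercept)
  cfg1 <- setup$config
  cfg1$mutation_coefs <- list(indel = list(
    intercept = log(2e-10), genotype = c(WT = 0), rdh = 0, expr = 0,
    orientation = 0))
  cat1 <- simulate_ma_mutations(setup$features, setup$covariates, cfg1)
  exposure <- sum(as.numeric(setup$features$end - setup$features$start)) *
    cat1$generations[["WT"]]
  expected <- exposure * 2e-10
  expect_lt(abs(nrow(cat1$mutations) - expected), 3 * sqrt(expected))

  cfg_neg <- setup$config
  cfg_neg$generations_per_line <- -1
  expect_error(simulate_ma_mutations(setup$features, setup$covariates,
                                     cfg_neg), "negative")
})

test_that("a zero RDH coefficient leaves counts uncorrelated with RDH", {
  hits <- vapply(1:100, function(s) {
    setup <- make_regression_setup(s, n = 120,
                                   mutation_coefs = list(indel = list(
                                     intercept = log(3e-10),
                                     genotype = c(WT = 0), rdh = 0,
                                     expr = 0, orientation = 0)))
    counts <- vapply(seq_len(nrow(setup$features)), function(i)
      sum(setup$catalog$mutations$position >= setup$features$start[i] &
            setup$catalog$mutations$position < setup$features$end[i]),
      numeric(1))
    stats::cor.test(setup$covariates$rdh_z, counts)$p.value < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("replication coverage encodes decay, stalls, and symmetry", {
  g <- genome_model(100000L, 0, 50000L)
  cfg <- sim_config(seed = 3, genome_length_bp = 100000L,
                    terminus_pos = 50000L, stall_loci = NULL,
                    coverage_bin_bp = 100L)
  cov <- simulate_replication_coverage(g, cfg)
  # no stalls: expectation symmetric about the terminus
  e <- cov$expected_log2
  n <- length(e)
  term_idx <- which(cov$pos == 50000)
  left <- e[(term_idx + 1):(n - 1)]
  right <- e[(term_idx - 1):2]
  expect_equal(left[seq_len(min(length(left), length(right)))],
               right[seq_len(min(length(left), length(right)))],
               tolerance = 1e-10)

  # zero decay, no stalls: flat
  cfg_flat <- sim_config(seed = 3, genome_length_bp = 100000L,
                         terminus_pos = 50000L, stall_loci = NULL,
                         coverage_decay_log2 = 0)
  cov_flat <- simulate_replication_coverage(g, cfg_flat)
  expect_equal(var(cov_flat$expected_log2), 0)

  # a stall of severity s steepens the local slope by s over its span
  cfg_stall <- sim_config(seed = 3, genome_length_bp = 100000L,
                          terminus_pos = 50000L,
                          stall_loci = data.frame(position = 20000,
                                                  severity = 2,
                                                  span_bp = 5000),
                          coverage_bin_bp = 100L)
  cov_s <- simulate_replication_coverage(g, cfg_stall)
  base_slope <- -cfg_stall$coverage_decay_log2 / 50000 * 100
  # transitions lying entirely inside the stall ramp
  n_pos <- length(cov_s$pos)
  sel <- cov_s$pos[-n_pos] >= 20000 & cov_s$pos[-1] <= 25000
  d <- diff(cov_s$expected_log2)[sel]
  expect_equal(mean(d), base_slope - 2 / 5000 * 100, tolerance = 1e-9)

  expect_error(simulate_replication_coverage(
    g, sim_config(seed = 1, genome_length_bp = 100000L,
                  terminus_pos = 50000L,
                  stall_loci = data.frame(position = 48000, severity = 1,
                                          span_bp = 5000))),
    "outside its replichore")
})
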