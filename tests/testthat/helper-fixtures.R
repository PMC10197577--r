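# Shared fixture builders. Everything is generated in code under explicit
# seeds; no data files.

# A small annotated genome that packs comfortably.
small_genome_cfg <- function(seed = 7, ...) {
  sim_config(seed = seed, genome_length_bp = 40000L, terminus_pos = 20000L,
             n_cds = 25L, n_ncrna = 4L, n_rrna = 1L, n_trna = 4L,
             stall_loci = data.frame(position = 15000, severity = 1.5,
                                     span_bp = 3000),
             ...)
}

# Hand-built count matrix: `truth` gives per-bin log2 enrichment for one
# genotype; input mean = depth, pulldown mean = depth * 2^truth.
make_counts <- function(truth, depth = 60, dispersion = 20, n_reps = 3,
                        seed = 1, genotype = "WT", bin_bp = 100) {
  set.seed(seed)
  B <- length(truth)
  bins <- data.frame(start = seq(0, by = bin_bp, length.out = B),
                     end = seq(bin_bp, by = bin_bp, length.out = B),
                     strand = "+")
  samples <- data.frame(
    genotype = genotype,
    replicate = rep(seq_len(n_reps), 2),
    type = rep(c("input", "pulldown"), each = n_reps))
  samples$sample <- sprintf("%s_%s_%d", samples$genotype, samples$type,
                            samples$replicate)
  counts <- sapply(seq_len(nrow(samples)), function(j) {
    mu <- if (samples$type[j] == "pulldown") depth * 2^truth else
      rep(depth, B)
    stats::rnbinom(B, mu = mu, size = dispersion)
  })
  colnames(counts) <- samples$sample
  samples$library_size <- colSums(counts)
  structure(list(bins = bins, counts = counts, samples = samples),
            class = "count_matrix")
}

# Synthetic per-CDS regression setup: features, covariates, score tables
# and a mutation catalog simulated from known coefficients.
make_regression_setup <- function(seed, n = 150, genotypes = "WT",
                                  mutation_coefs = NULL,
                                  generations_per_line = 30000L,
                                  n_lines = 72L) {
  set.seed(seed)
  feats <- data.frame(
    feature_id = sprintf("g%04d", seq_len(n)), feature_class = "CDS",
    start = seq(0, by = 1000, length.out = n),
    end = seq(0, by = 1000, length.out = n) + 800,
    strand = "+",
    orientation = sample(c("head_on", "codirectional"), n, TRUE,
                         prob = c(0.25, 0.75)),
    masked = FALSE, stringsAsFactors = FALSE)
  cov <- data.frame(feature_id = feats$feature_id, rdh_z = rnorm(n),
                    expr_z = rnorm(n), stringsAsFactors = FALSE)
  blocks <- lapply(stats::setNames(nm = genotypes), function(g)
    list(baseline = 0, expr_slope = 0.2, utr5_boost = 0.5,
         first100_boost = 0.3))
  if (is.null(mutation_coefs))
    mutation_coefs <- list(indel = list(
      intercept = log(2e-10),
      genotype = stats::setNames(rep(0, length(genotypes)), genotypes),
      rdh = 0.3, expr = 0, orientation = 0))
  cfg <- sim_config(seed = seed,
                    genome_length_bp = as.integer(n * 1000 + 1000),
                    terminus_pos = as.integer(n * 500),
                    n_lines = n_lines,
                    generations_per_line = generations_per_line,
                    genotype_blocks = blocks,
                    mutation_coefs = mutation_coefs)
  catalog <- simulate_ma_mutations(feats, cov, cfg)
  scores <- lapply(stats::setNames(nm = genotypes), function(g)
    data.frame(feature_id = feats$feature_id, feature_class = "CDS",
               orientation = feats$orientation, window = "full",
               score = cov$rdh_z, n_bins = 8, stringsAsFactors = FALSE))
  expr <- data.frame(feature_id = feats$feature_id, expr_z = cov$expr_z,
                     stringsAsFactors = FALSE)
  list(features = feats, covariates = cov, scores = scores,
       expression = expr, catalog = catalog, config = cfg)
}

# Fast MCMC settings for bulk statistical property checks; the relaxed
# convergence gate reflects that these runs feed integrated quantities
# (elpd, posterior means), not interval endpoints.
fast_mut_fit <- function(design, seed, classes = "indel", ...) {
  fit_mutation_model(design, n_draws = 400, chains = 2, adapt = 500,
                     burn = 1000, thin = 25, seed = seed,
                     rhat_max = 1.15, classes = classes, ...)
}

# Small end-to-end pipeline configuration (used for determinism checks).
small_pipeline_cfg <- function(dir, seed = 42,
                               stages = c("synthetic", "enrichment",
                                          "features", "ma", "regression",
                                          "replication")) {
  pipeline_config(
    out_dir = dir, seed = seed, stages = stages,
    sim = list(genome_length_bp = 30000L, terminus_pos = 15000L,
               n_cds = 22L, n_ncrna = 4L, n_rrna = 1L, n_trna = 2L,
               bin_bp = 200L,
               n_lines = 72L, generations_per_line = 40000L,
               coverage_bin_bp = 200L,
               stall_loci = data.frame(position = 12000, severity = 1.5,
                                       span_bp = 2000)),
    enrichment = list(n_draws = 120, chains = 2, adapt = 300, burn = 400),
    features = list(n_boot = 300),
    regression = list(n_draws = 1000, adapt = 2000, burn = 4000,
                      thin = 60),
    replication = list(window_bp = 2000, threshold_z = 4))
}
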