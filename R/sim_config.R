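# Simulation configuration: the single place where the synthetic study
# conditions are declared. Defaults emulate a 4 Mb Bacillus-like chromosome
# scaled to 400 kb, three genotypes (wild type plus two RNase-H deletions)
# with expression-dependent hybrid accumulation that differs by genotype,
# negative-binomially overdispersed sequencing counts, Poisson per-CDS
# mutation counts driven by covariates, and origin-to-terminus coverage
# decay with localized fork stalls.

#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generators. A seed is
#' mandatory: all generators are pure functions of (config, seed) and each
#' pipeline stage draws its own substream via [substream_seed()].
#'
#' @param seed Master integer seed (required).
#' @param genome_length_bp,origin_pos,terminus_pos Genome geometry.
#' @param n_cds,cds_length_mean_bp Number of CDSs and their mean length.
#' @param utr_fraction Fraction of CDSs carrying abutting 5'/3' UTRs.
#' @param utr_length_bp UTR length.
#' @param n_ncrna,n_rrna,n_trna Counts of non-CDS feature classes (rRNA
#'   loci are emitted masked, as single consensus copies).
#' @param codirectional_bias Probability that a gene is oriented
#'   codirectionally with replication (bacterial genomes are biased
#'   toward codirectional).
#' @param bin_bp Track bin width in bp; 100 bp resolves first-100-bp
#'   windows with one bin.
#' @param expr_log_mean,expr_log_sd Log-normal expression parameters.
#' @param genotype_blocks Named list (one entry per genotype) of lists with
#'   fields `baseline`, `expr_slope`, `utr5_boost`, `first100_boost`, the
#'   log2-enrichment generative parameters. Defaults encode the qualitative
#'   genotype differences: hybrid accumulation most expression-sensitive in
#'   the RNase HIII deletion (`rnhC`), biased toward 5' UTRs and early CDS
#'   in the RNase HII deletion (`rnhB`).
#' @param depth Mean input fragments per bin.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mean + mean^2 / dispersion); must be > 0.
#' @param n_reps Replicates per (genotype, sample type).
#' @param size_factor_sd Log-normal spread of per-sample size factors.
#' @param mutation_coefs Named list per mutation class (`transition`,
#'   `transversion`, `indel`) of coefficient lists: `intercept` (log rate
#'   per bp per generation), `genotype` (named numeric log-rate offsets),
#'   `rdh`, `expr`, `orientation` (head-on indicator), and optional
#'   interaction terms `orientation_expr`, `orientation_rdh`.
#' @param n_lines MA lines per genotype.
#' @param generations_per_line Generations elapsed per line.
#' @param sv_rate Structural variants per generation per line.
#' @param coverage_depth Expected coverage count at the origin.
#' @param coverage_decay_log2 Total log2 coverage drop from origin to
#'   terminus (marker-frequency decay in exponential growth).
#' @param stall_loci Data frame (`position`, `severity`, `span_bp`) of
#'   replication stalls; each steepens the local slope by `severity` log2
#'   units over its span. May have zero rows.
#' @param coverage_bin_bp Spacing of coverage positions.
#' @param coverage_reps Biological replicates of coverage sequencing.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       genome_length_bp = 400000L,
                       origin_pos = 0L,
                       terminus_pos = 200000L,
                       n_cds = 360L,
                       cds_length_mean_bp = 800L,
                       utr_fraction = 0.35,
                       utr_length_bp = 100L,
                       n_ncrna = 20L,
                       n_rrna = 3L,
                       n_trna = 20L,
                       codirectional_bias = 0.75,
                       bin_bp = 100L,
                       expr_log_mean = 2,
                       expr_log_sd = 1,
                       genotype_blocks = list(
                         WT   = list(baseline = 0, expr_slope = 0.20,
                                     utr5_boost = 0.5, first100_boost = 0.3),
                         rnhB = list(baseline = 0, expr_slope = 0.25,
                                     utr5_boost = 0.9, first100_boost = 0.8),
                         rnhC = list(baseline = 0, expr_slope = 0.70,
                                     utr5_boost = 0.6, first100_boost = 0.3)),
                       depth = 60,
                       dispersion = 20,
                       n_reps = 3L,
                       size_factor_sd = 0.1,
                       mutation_coefs = list(
                         transition = list(
                           intercept = log(1.6e-10),
                           genotype = c(WT = 0, rnhB = log(1.6),
                                        rnhC = log(1.5)),
                           rdh = 0, expr = 0.1, orientation = 0),
                         transversion = list(
                           intercept = log(6e-11),
                           genotype = c(WT = 0, rnhB = 0, rnhC = log(2)),
                           rdh = 0, expr = -0.2, orientation = 0),
                         indel = list(
                           intercept = log(4e-11),
                           genotype = c(WT = 0, rnhB = 0, rnhC = log(1.2)),
                           rdh = 0.3, expr = -0.2, orientation = 0)),
                       n_lines = 72L,
                       generations_per_line = 3688L,
                       sv_rate = 6.4e-5,
                       coverage_depth = 100,
                       coverage_decay_log2 = 1.0,
                       stall_loci = data.frame(position = 180000,
                                               severity = 1.5,
                                               span_bp = 5000),
                       coverage_bin_bp = 100L,
                       coverage_reps = 3L) {
  .check_number(seed, "seed", integer = TRUE)
  .check_number(dispersion, "dispersion", lower = .Machine$double.eps)
  .check_number(depth, "depth", lower = 0)
  .check_number(expr_log_sd, "expr_log_sd", lower = 0)
  .check_number(coverage_decay_log2, "coverage_decay_log2", lower = 0)
  if (n_lines < 0 || generations_per_line < 0)
    stop("`n_lines` and `generations_per_line` must be non-negative",
         call. = FALSE)
  for (g in names(genotype_blocks)) {
    blk <- genotype_blocks[[g]]
    need <- c("baseline", "expr_slope", "utr5_boost", "first100_boost")
    if (!all(need %in% names(blk)))
      stop(sprintf("genotype block '%s' is missing fields: %s", g,
                   paste(setdiff(need, names(blk)), collapse = ", ")),
           call. = FALSE)
  }
  cfg <- mget(names(formals()), envir = environment())
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation config: %d bp genome, %d CDSs, ",
                     "genotypes [%s], seed %d\n"),
              x$genome_length_bp, x$n_cds,
              paste(names(x$genotype_blocks), collapse = ", "), x$seed))
  invisible(x)
}

#' @rdname sim_config
#' @param x A `sim_config` or a plain named list of `sim_config` arguments.
#' @export
as_sim_config <- function(x) {
  if (inherits(x, "sim_config")) return(x)
  if (is.list(x)) return(do.call(sim_config, x))
  stop("`config` must be a sim_config or a named list", call. = FALSE)
}
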