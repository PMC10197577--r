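# Synthetic-data generators for expression, hybrid enrichment truth,
# pulldown/input counts, MA-line mutations, and replication coverage.
# Each is a pure function of (inputs, config): reruns are bit-identical.

#' Strand-aware genome bins
#'
#' Regular bins tiling the genome, duplicated over both strands. The last
#' bin is truncated at the genome end.
#'
#' @param genome A [genome_model()].
#' @param bin_bp Bin width in bp.
#' @return Data frame with columns `start`, `end` (0-based half-open) and
#'   `strand`, plus-strand bins first.
#' @export
genome_bins <- function(genome, bin_bp = 100L) {
  .check_number(bin_bp, "bin_bp", lower = 1, integer = TRUE)
  starts <- seq(0L, genome$length_bp - 1L, by = bin_bp)
  ends <- pmin(starts + bin_bp, genome$length_bp)
  data.frame(start = rep(starts, 2L), end = rep(ends, 2L),
             strand = rep(c("+", "-"), each = length(starts)),
             stringsAsFactors = FALSE)
}

# Parent transcription unit of a feature id ("gene0001_5utr" -> "gene0001").
.parent_unit <- function(feature_id) {
  sub("_(5utr|3utr)$", "", feature_id)
}

#' Simulate per-gene expression
#'
#' Draws log-normal abundances for every transcription unit (CDS, ncRNA,
#' rRNA, tRNA; UTRs inherit their parent CDS) and attaches robust z-scores
#' of log abundance, the standardization used throughout feature scoring.
#'
#' @param features Feature data frame from [generate_genome()].
#' @param config A [sim_config()].
#' @return Data frame with `feature_id`, `abundance`, `expr_z` for each
#'   transcription unit. A degenerate configuration (zero log-sd) raises
#'   the robust-z degenerate-scale error.
#' @export
simulate_expression <- function(features, config) {
  cfg <- as_sim_config(config)
  units <- features[features$feature_class %in%
                      c("CDS", "ncRNA", "rRNA", "tRNA"), , drop = FALSE]
  if (nrow(units) < 2L)
    stop("need at least 2 transcription units", call. = FALSE)
  set.seed(substream_seed(cfg$seed, "expression"))
  log_ab <- stats::rnorm(nrow(units), cfg$expr_log_mean, cfg$expr_log_sd)
  data.frame(feature_id = units$feature_id,
             abundance = exp(log_ab),
             expr_z = robust_z(log_ab),
             stringsAsFactors = FALSE)
}

#' Simulate true log2 hybrid enrichment per bin
#'
#' Ground truth for the enrichment estimator. For each genotype, a bin
#' covered by a transcribed feature (on the strand sense to the transcript;
#' the opposite strand stays at zero) gets
#' `baseline + expr_slope * expression z + utr5_boost [5'-UTR bins] +
#' first100_boost [first 100 bp of a CDS]`. Bins outside any feature are
#' zero.
#'
#' @param features Feature data frame from [generate_genome()].
#' @param expression Output of [simulate_expression()].
#' @param config A [sim_config()]; the genome geometry is taken from it.
#' @param genome Optional [genome_model()] (defaults to the config's).
#' @return Data frame: `start`, `end`, `strand`, and one truth column per
#'   genotype named `truth_<genotype>`.
#' @export
simulate_hybrid_truth <- function(features, expression, config,
                                  genome = NULL) {
  cfg <- as_sim_config(config)
  if (is.null(genome))
    genome <- genome_model(cfg$genome_length_bp, cfg$origin_pos,
                           cfg$terminus_pos)
  bins <- genome_bins(genome, cfg$bin_bp)
  if (any(features$end > genome$length_bp))
    stop("feature bins outside genome", call. = FALSE)
  zmap <- stats::setNames(expression$expr_z, expression$feature_id)
  mids <- (bins$start + bins$end) / 2

  out <- bins
  for (g in names(cfg$genotype_blocks)) {
    blk <- cfg$genotype_blocks[[g]]
    truth <- numeric(nrow(bins))
    for (i in seq_len(nrow(features))) {
      f <- features[i, ]
      hit <- bins$strand == f$strand & mids >= f$start & mids < f$end
      if (!any(hit)) next
      z <- zmap[[.parent_unit(f$feature_id)]]
      if (is.null(z) || is.na(z)) z <- 0
      val <- blk$baseline + blk$expr_slope * z
      if (f$feature_class == "UTR5") val <- val + blk$utr5_boost
      truth[hit] <- truth[hit] + val
      if (f$feature_class == "CDS" && blk$first100_boost != 0) {
        first <- if (f$strand == "+")
          hit & mids < f$start + 100 else hit & mids >= f$end - 100
        truth[first] <- truth[first] + blk$first100_boost
      }
    }
    out[[paste0("truth_", g)]] <- truth
  }
  out
}

#' Simulate pulldown and input sequencing counts
#'
#' Negative-binomial fragment counts for every (genotype, replicate,
#' sample type): input counts have mean `depth x size factor`; pulldown
#' counts multiply the input mean by `2^truth`. Strands are independent.
#' The NB is parameterized so that variance = mean + mean^2 / dispersion.
#'
#' @param truth Output of [simulate_hybrid_truth()].
#' @param config A [sim_config()].
#' @return A `count_matrix`: list with `bins` (start/end/strand), `counts`
#'   (bins x samples integer matrix) and `samples` (sample sheet with
#'   `sample`, `genotype`, `replicate`, `type`, `library_size`).
#' @export
simulate_pulldown_counts <- function(truth, config) {
  cfg <- as_sim_config(config)
  if (cfg$depth <= 0) stop("`depth` must be > 0", call. = FALSE)
  genotypes <- names(cfg$genotype_blocks)
  tcols <- paste0("truth_", genotypes)
  .check_columns(truth, c("start", "end", "strand", tcols), "truth")
  set.seed(substream_seed(cfg$seed, "counts"))
  n_bins <- nrow(truth)
  samples <- expand.grid(replicate = seq_len(cfg$n_reps),
                         type = c("input", "pulldown"),
                         genotype = genotypes,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("genotype", "replicate", "type")]
  samples$sample <- sprintf("%s_%s_%d", samples$genotype,
                            samples$type, samples$replicate)
  sf <- exp(stats::rnorm(nrow(samples), 0, cfg$size_factor_sd))
  counts <- matrix(0L, n_bins, nrow(samples),
                   dimnames = list(NULL, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- cfg$depth * sf[j]
    if (samples$type[j] == "pulldown")
      mu <- mu * 2^truth[[paste0("truth_", samples$genotype[j])]]
    counts[, j] <- stats::rnbinom(n_bins, mu = mu, size = cfg$dispersion)
  }
  samples$library_size <- colSums(counts)
  structure(list(bins = truth[, c("start", "end", "strand")],
                 counts = counts, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix: %d bins x %d samples (%d genotypes)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$genotype))))
  invisible(x)
}

.transition_map <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate mutation-accumulation-line mutations
#'
#' Per-CDS, per-class mutation counts are Poisson with mean
#' `exposure x exp(linear predictor)`, exposure = CDS length in bp times
#' total generations for the genotype, and the linear predictor built from
#' the class coefficient block (genotype offset, RDH z, expression z,
#' orientation, optional interactions). Counts are materialized as
#' positioned records with ref/alt alleles consistent with the class, and
#' assigned to random lines. Structural variants accrue per line at
#' `sv_rate` per generation with uniform positions.
#'
#' @param features Feature data frame (CDS rows are used).
#' @param covariates Data frame per CDS: `feature_id`, `rdh_z`, `expr_z`,
#'   `orientation` (values `head_on` / `codirectional`). Missing CDSs get
#'   covariates 0.
#' @param config A [sim_config()].
#' @return A `mutation_catalog`: list with `mutations` (line_id, genotype,
#'   position, ref, alt, class), `svs` (line_id, genotype, start, end,
#'   sv_type), `generations` (named per-genotype totals) and `lines`.
#' @export
simulate_ma_mutations <- function(features, covariates, config) {
  cfg <- as_sim_config(config)
  if (cfg$generations_per_line < 0)
    stop("negative generations", call. = FALSE)
  cds <- features[features$feature_class == "CDS", , drop = FALSE]
  .check_columns(covariates, c("feature_id", "rdh_z", "expr_z"),
                 "covariates")
  cov <- merge(cds[, c("feature_id", "start", "end", "orientation")],
               covariates[, c("feature_id", "rdh_z", "expr_z")],
               by = "feature_id", all.x = TRUE, sort = FALSE)
  cov$rdh_z[is.na(cov$rdh_z)] <- 0
  cov$expr_z[is.na(cov$expr_z)] <- 0
  head_on <- as.numeric(cov$orientation == "head_on")
  set.seed(substream_seed(cfg$seed, "mutations"))

  genotypes <- names(cfg$genotype_blocks)
  total_gen <- as.numeric(cfg$n_lines) * as.numeric(cfg$generations_per_line)
  generations <- stats::setNames(rep(total_gen, length(genotypes)),
                                 genotypes)
  len <- as.numeric(cov$end - cov$start)
  muts <- list(); svs <- list()
  for (g in genotypes) {
    for (cls in names(cfg$mutation_coefs)) {
      cf <- cfg$mutation_coefs[[cls]]
      eta <- cf$intercept +
        (if (!is.null(cf$genotype[[g]])) cf$genotype[[g]] else 0) +
        cf$rdh * cov$rdh_z + cf$expr * cov$expr_z +
        cf$orientation * head_on +
        (if (!is.null(cf$orientation_expr))
           cf$orientation_expr * head_on * cov$expr_z else 0) +
        (if (!is.null(cf$orientation_rdh))
           cf$orientation_rdh * head_on * cov$rdh_z else 0)
      mu <- len * total_gen * exp(eta)
      n <- stats::rpois(length(mu), mu)
      tot <- sum(n)
      if (tot == 0) next
      idx <- rep(seq_along(n), n)
      pos <- cov$start[idx] +
        floor(stats::runif(tot) * pmax(1, len[idx]))
      ref <- sample(c("A", "C", "G", "T"), tot, replace = TRUE)
      if (cls == "transition") {
        alt <- unname(.transition_map[ref])
      } else if (cls == "transversion") {
        alt <- vapply(ref, function(r) {
          sample(setdiff(c("A", "C", "G", "T"),
                         c(r, .transition_map[[r]])), 1L)
        }, character(1))
      } else {
        ins <- stats::runif(tot) < 0.5
        extra <- sample(c("A", "C", "G", "T"), tot, replace = TRUE)
        alt <- ifelse(ins, paste0(ref, extra), ref)
        ref <- ifelse(ins, ref, paste0(ref, extra))
      }
      muts[[length(muts) + 1L]] <- data.frame(
        line_id = sprintf("%s_line%02d", g,
                          sample.int(max(1L, cfg$n_lines), tot,
                                     replace = TRUE)),
        genotype = g, position = as.integer(pos), ref = ref, alt = alt,
        class = if (cls == "indel")
          ifelse(nchar(alt) > nchar(ref), "insertion", "deletion")
        else cls,
        stringsAsFactors = FALSE)
    }
    n_sv <- stats::rpois(1, cfg$sv_rate * total_gen)
    if (n_sv > 0) {
      s <- floor(stats::runif(n_sv) * (cfg$genome_length_bp - 5000))
      svs[[length(svs) + 1L]] <- data.frame(
        line_id = sprintf("%s_line%02d", g,
                          sample.int(max(1L, cfg$n_lines), n_sv,
                                     replace = TRUE)),
        genotype = g, start = as.integer(s),
        end = as.integer(s + floor(stats::runif(n_sv, 500, 5000))),
        sv_type = sample(c("DEL", "INS", "INV"), n_sv, replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  empty_mut <- data.frame(line_id = character(), genotype = character(),
                          position = integer(), ref = character(),
                          alt = character(), class = character(),
                          stringsAsFactors = FALSE)
  empty_sv <- data.frame(line_id = character(), genotype = character(),
                         start = integer(), end = integer(),
                         sv_type = character(), stringsAsFactors = FALSE)
  structure(list(
    mutations = if (length(muts)) do.call(rbind, muts) else empty_mut,
    svs = if (length(svs)) do.call(rbind, svs) else empty_sv,
    generations = generations,
    lines = stats::setNames(rep(cfg$n_lines, length(genotypes)),
                            genotypes)),
    class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("Mutation catalog: %d mutations, %d SVs, genotypes [%s]\n",
              nrow(x$mutations), nrow(x$svs),
              paste(names(x$generations), collapse = ", ")))
  invisible(x)
}

#' Simulate replication-dependent genome coverage
#'
#' In exponentially growing cells, sequencing coverage decays from the
#' replication origin to the terminus (marker-frequency decay). Expected
#' log2 coverage declines linearly with fork travel distance on each
#' replichore; each stall steepens the local slope by its severity (log2
#' units over its span) and depresses everything downstream of it. Observed
#' counts are Poisson around the expectation, independently per replicate.
#'
#' @param genome A [genome_model()].
#' @param config A [sim_config()]; uses `coverage_depth`,
#'   `coverage_decay_log2`, `stall_loci`, `coverage_bin_bp`,
#'   `coverage_reps`, `seed`.
#' @return List of class `replication_sim`: `pos` (positions), `counts`
#'   (positions x replicates), `expected_log2` (noise-free expectation),
#'   `genome`.
#' @export
simulate_replication_coverage <- function(genome, config) {
  cfg <- as_sim_config(config)
  if (cfg$coverage_decay_log2 < 0) stop("decay rate must be >= 0",
                                        call. = FALSE)
  stalls <- cfg$stall_loci
  pos <- seq(0L, genome$length_bp - 1L, by = cfg$coverage_bin_bp)
  repl <- replichore_of(pos, genome)
  arc_r <- .arc_forward(genome$origin_pos, genome$terminus_pos,
                        genome$length_bp)
  arc_l <- genome$length_bp - arc_r
  fork_d <- ifelse(repl == "right",
                   .arc_forward(genome$origin_pos, pos, genome$length_bp),
                   .arc_forward(pos, genome$origin_pos, genome$length_bp))
  repl_len <- ifelse(repl == "right", arc_r, arc_l)
  log2cov <- log2(cfg$coverage_depth) -
    cfg$coverage_decay_log2 * fork_d / repl_len

  if (!is.null(stalls) && nrow(stalls)) {
    for (k in seq_len(nrow(stalls))) {
      p0 <- stalls$position[k]; sev <- stalls$severity[k]
      span <- stalls$span_bp[k]
      r0 <- replichore_of(p0, genome)
      d0 <- if (r0 == "right")
        .arc_forward(genome$origin_pos, p0, genome$length_bp)
      else .arc_forward(p0, genome$origin_pos, genome$length_bp)
      rl <- if (r0 == "right") arc_r else arc_l
      if (p0 < 0 || p0 >= genome$length_bp || d0 + span > rl)
        stop("stall span outside its replichore", call. = FALSE)
      on_repl <- repl == r0
      frac <- pmin(pmax((fork_d - d0) / span, 0), 1)
      log2cov <- log2cov - ifelse(on_repl, sev * frac, 0)
    }
  }
  set.seed(substream_seed(cfg$seed, "coverage"))
  counts <- matrix(stats::rpois(length(pos) * cfg$coverage_reps,
                                rep(2^log2cov, cfg$coverage_reps)),
                   ncol = cfg$coverage_reps,
                   dimnames = list(NULL,
                                   paste0("rep", seq_len(cfg$coverage_reps))))
  structure(list(pos = pos, counts = counts, expected_log2 = log2cov,
                 genome = genome),
            class = "replication_sim")
}
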