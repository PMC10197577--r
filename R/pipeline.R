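# End-to-end orchestration: synthetic data -> enrichment -> feature
# statistics -> MA-line statistics -> mutation regression -> replication
# profiling, under a single configuration with per-stage seed substreams
# and a checksummed output manifest.

.all_stages <- c("synthetic", "enrichment", "features", "ma",
                 "regression", "replication")

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; every stochastic stage derives its own
#'   substream from it.
#' @param stages Stages to run, in dependency order; later stages require
#'   the in-memory products of earlier ones, so the list must be a prefix
#'   of the full order (`synthetic`, `enrichment`, `features`, `ma`,
#'   `regression`, `replication`) — except `replication`, which only needs
#'   `synthetic`.
#' @param sim Named list of [sim_config()] overrides (the seed is
#'   injected).
#' @param enrichment,features,regression,replication Per-stage option
#'   lists: `enrichment` (`n_draws`, `chains`, `adapt`, `burn`),
#'   `features` (`n_boot`), `regression` (`n_draws`, `chains`, `adapt`,
#'   `burn`, `thin`, `rhat_max`, `rope_halfwidth`), `replication`
#'   (`span`, `window_bp`, `threshold_z`).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, stages = .all_stages,
                            sim = list(), enrichment = list(),
                            features = list(), regression = list(),
                            replication = list()) {
  .check_number(seed, "seed", integer = TRUE)
  bad <- setdiff(stages, .all_stages)
  if (length(bad))
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  need <- setdiff(stages, c("synthetic", "replication"))
  if (length(need) && !"synthetic" %in% stages)
    stop("non-synthetic inputs are not configured: enable the ",
         "'synthetic' stage or provide input files", call. = FALSE)
  structure(list(out_dir = out_dir, seed = seed, stages = stages,
                 sim = sim, enrichment = enrichment, features = features,
                 regression = regression, replication = replication),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order, writes every
#' product to `out_dir` in the standard plain-text formats, and finishes
#' with `manifest.json` listing the resolved configuration and an MD5
#' checksum per output; under fixed seeds a rerun reproduces identical
#' checksums.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  written <- character(0)
  emit <- function(path) written <<- c(written, path)
  opt <- function(block, name, default)
    if (is.null(config[[block]][[name]])) default else
      config[[block]][[name]]

  sim_args <- config$sim
  sim_args$seed <- substream_seed(config$seed, "sim")
  cfg <- do.call(sim_config, sim_args)

  env <- new.env()
  if ("synthetic" %in% config$stages) .stage("synthetic", {
    gen <- generate_genome(cfg)
    env$genome <- gen$genome; env$features <- gen$features
    env$expression <- simulate_expression(gen$features, cfg)
    env$truth <- simulate_hybrid_truth(gen$features, env$expression, cfg,
                                       gen$genome)
    env$counts <- simulate_pulldown_counts(env$truth, cfg)
    # mutation covariates from the simulated ground truth: per-CDS median
    # of the first genotype's hybrid truth plus the expression z-scores
    g1 <- names(cfg$genotype_blocks)[1]
    truth_z <- cbind(env$truth[, c("start", "end", "strand")],
                     z = robust_z(env$truth[[paste0("truth_", g1)]],
                                  fallback_sd = TRUE))
    truth_scores <- score_features(truth_z, gen$features)
    cov_df <- merge(
      data.frame(feature_id = truth_scores$feature_id,
                 rdh_z = truth_scores$score, stringsAsFactors = FALSE),
      env$expression[, c("feature_id", "expr_z")], by = "feature_id")
    env$catalog <- simulate_ma_mutations(gen$features, cov_df, cfg)
    env$coverage <- simulate_replication_coverage(gen$genome, cfg)

    emit(write_genome_fasta(env$genome, out("genome.fasta"), cfg$seed))
    emit(write_features_gff3(gen$features, out("features.gff3")))
    emit(write_tsv(env$expression, out("expression.tsv")))
    emit(write_tsv(env$counts$samples, out("samples.tsv")))
    emit(write_tsv(cbind(env$counts$bins, as.data.frame(env$counts$counts)),
                   out("counts.tsv")))
    emit(write_tsv(env$catalog$mutations, out("mutations.tsv")))
    emit(write_tsv(env$catalog$svs, out("svs.tsv")))
    emit(write_tsv(data.frame(pos = env$coverage$pos,
                              env$coverage$counts),
                   out("coverage.tsv")))
    for (g in names(cfg$genotype_blocks))
      for (st in c("+", "-")) {
        sel <- env$truth$strand == st
        suffix <- if (st == "+") "plus" else "minus"
        emit(write_track_bedgraph(
          env$truth[sel, c("start", "end")],
          env$truth[[paste0("truth_", g)]][sel],
          out(sprintf("truth_%s_%s.bedGraph", g, suffix))))
      }
  })

  if ("enrichment" %in% config$stages) .stage("enrichment", {
    env$fit <- fit_enrichment(
      env$counts,
      n_draws = opt("enrichment", "n_draws", 500),
      chains = opt("enrichment", "chains", 2),
      adapt = opt("enrichment", "adapt", 300),
      burn = opt("enrichment", "burn", 300),
      seed = substream_seed(config$seed, "enrichment"))
    env$ztracks <- list()
    for (g in env$fit$genotypes) {
      tr <- enrichment_track(env$fit, g)
      z <- robust_z(tr$mean)
      env$ztracks[[g]] <- cbind(env$fit$bins, z = z)
      for (st in c("+", "-")) {
        sel <- env$fit$bins$strand == st
        suffix <- if (st == "+") "plus" else "minus"
        for (stat in c("mean", "q05", "q95"))
          emit(write_track_bedgraph(
            env$fit$bins[sel, c("start", "end")], tr[[stat]][sel],
            out(sprintf("enrich_%s_%s_%s.bedGraph", g, stat, suffix))))
        emit(write_track_bedgraph(
          env$fit$bins[sel, c("start", "end")], z[sel],
          out(sprintf("enrich_%s_z_%s.bedGraph", g, suffix))))
      }
    }
    gts <- env$fit$genotypes
    if (length(gts) > 1) {
      cm <- track_correlation_matrix(stats::setNames(
        lapply(gts, function(g) enrichment_track(env$fit, g)), gts))
      emit(write_tsv(cbind(genotype = rownames(cm), as.data.frame(cm)),
                     out("track_correlations.tsv")))
      for (g in gts[-1]) {
        ct <- genotype_contrast(enrichment_track(env$fit, g),
                                enrichment_track(env$fit, gts[1]))
        for (st in c("+", "-")) {
          sel <- env$fit$bins$strand == st
          suffix <- if (st == "+") "plus" else "minus"
          emit(write_track_bedgraph(
            env$fit$bins[sel, c("start", "end")], ct$mean[sel],
            out(sprintf("contrast_%s_vs_%s_mean_%s.bedGraph", g, gts[1],
                        suffix))))
        }
      }
    }
  })

  if ("features" %in% config$stages) .stage("features", {
    n_boot <- opt("features", "n_boot", 1000)
    env$scores <- list()
    comparisons <- list()
    for (g in names(env$ztracks)) {
      zt <- env$ztracks[[g]]
      sc <- score_features(zt, env$features, window = "full")
      env$scores[[g]] <- sc
      emit(write_tsv(sc, out(sprintf("scores_%s.tsv", g))))
      for (cls in c("CDS", "ncRNA")) {
        sub <- sc[sc$feature_class == cls & !is.na(sc$score), ]
        if (length(unique(sub$orientation)) < 2) next
        comparisons[[paste(g, cls)]] <- cbind(
          genotype = g,
          orientation_comparison(sc, feature_class = cls,
                                 n_boot = n_boot,
                                 seed = substream_seed(config$seed,
                                                       paste0("boot", g))))
      }
    }
    cmp <- add_fdr(do.call(rbind, comparisons))
    emit(write_tsv(cmp, out("orientation_comparisons.tsv")))
    gts <- names(env$scores)
    if (length(gts) > 1) {
      paired <- do.call(rbind, lapply(gts[-1], function(g) cbind(
        pair = paste0(g, "-", gts[1]),
        genotype_paired_difference(env$scores[[gts[1]]],
                                   env$scores[[g]],
                                   feature_class = "CDS",
                                   n_boot = n_boot,
                                   seed = substream_seed(config$seed,
                                                         "paired")))))
      emit(write_tsv(paired, out("paired_differences.tsv")))
    }
    reg <- lapply(gts, function(g)
      fit_feature_regression(env$scores[[g]], env$expression,
                             seed = substream_seed(config$seed,
                                                   paste0("reg", g))))
    names(reg) <- gts
    env$feature_reg <- reg
    emit(write_tsv(do.call(rbind, lapply(gts, function(g) data.frame(
      genotype = g, term = names(coef(reg[[g]])),
      mean = unname(coef(reg[[g]])), ci_lower = unname(reg[[g]]$ci_lower),
      ci_upper = unname(reg[[g]]$ci_upper)))),
      out("feature_regression.tsv")))
  })

  if ("ma" %in% config$stages) .stage("ma", {
    cat_ <- env$catalog
    rates <- do.call(rbind, lapply(names(cat_$generations), function(g) {
      mg <- cat_$mutations[cat_$mutations$genotype == g, ]
      do.call(rbind, lapply(c("transition", "transversion", "insertion",
                              "deletion"), function(cls) cbind(
        genotype = g, class = cls,
        mutation_rate_ci(sum(mg$class == cls), cat_$generations[[g]]))))
    }))
    emit(write_tsv(rates, out("mutation_rates.tsv")))
    svr <- do.call(rbind, lapply(names(cat_$generations), function(g)
      cbind(genotype = g, mutation_rate_ci(
        sum(cat_$svs$genotype == g), cat_$generations[[g]]))))
    emit(write_tsv(svr, out("sv_rates.tsv")))
    env$rates <- rates
  })

  if ("regression" %in% config$stages) .stage("regression", {
    design <- build_design(env$features, env$scores, env$expression,
                           env$catalog,
                           interactions = c("orientation:expr"))
    fit <- fit_mutation_model(
      design,
      n_draws = opt("regression", "n_draws", 1000),
      chains = opt("regression", "chains", 2),
      adapt = opt("regression", "adapt", 1000),
      burn = opt("regression", "burn", 2000),
      thin = opt("regression", "thin", 20),
      rhat_max = opt("regression", "rhat_max", 1.01),
      seed = substream_seed(config$seed, "regression"))
    env$mut_fit <- fit
    report <- compute_bayes_factors(
      fit, rope_halfwidth = opt("regression", "rope_halfwidth", 0.05))
    emit(write_tsv(design$data, out("design.tsv")))
    emit(write_tsv(as.data.frame(report), out("posterior_report.tsv")))
  })

  if ("replication" %in% config$stages) .stage("replication", {
    cov <- env$coverage
    lcpm <- mean_log2cpm(cov$counts)
    sm <- smooth_coverage(cov$pos, lcpm,
                          span = opt("replication", "span", 0.03))
    scan <- slope_stall_scan(
      cov$pos, sm, cov$genome,
      window_bp = opt("replication", "window_bp", 5000),
      threshold_z = opt("replication", "threshold_z", 4))
    step <- stats::median(diff(cov$pos))
    bins <- data.frame(start = cov$pos, end = cov$pos + step)
    emit(write_track_bedgraph(bins, lcpm, out("coverage_log2cpm.bedGraph")))
    emit(write_track_bedgraph(bins, sm, out("coverage_smoothed.bedGraph")))
    emit(write_track_bedgraph(
      scan$windows[, c("start", "end")], scan$windows$z,
      out("slope_z.bedGraph")))
    stall_bed <- scan$stalls
    if (nrow(stall_bed)) {
      utils::write.table(
        data.frame("chr", as.integer(stall_bed$start),
                   as.integer(stall_bed$end),
                   sprintf("stall_z%.1f", stall_bed$min_z)),
        out("stalls.bed"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    } else {
      file.create(out("stalls.bed"))
    }
    emit(out("stalls.bed"))
    env$stalls <- scan
  })

  checksums <- as.list(tools::md5sum(sort(unique(written))))
  names(checksums) <- basename(sort(unique(written)))
  manifest <- list(
    config = list(seed = config$seed, stages = config$stages,
                  sim = config$sim, enrichment = config$enrichment,
                  features = config$features,
                  regression = config$regression,
                  replication = config$replication),
    outputs = checksums)
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
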