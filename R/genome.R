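# Circular genome model with bidirectional replication, and the derived
# head-on / codirectional orientation of transcribed features.

#' Construct a circular genome model
#'
#' Describes a bacterial chromosome replicated bidirectionally from a single
#' origin to a terminus. The two replichores partition the circle: on the
#' "right" replichore the fork travels in the direction of increasing
#' coordinate (origin to terminus, possibly wrapping), on the "left"
#' replichore it travels in decreasing coordinate.
#'
#' @param length_bp Genome length in base pairs.
#' @param origin_pos Replication origin coordinate in `[0, length_bp)`.
#' @param terminus_pos Replication terminus coordinate in `[0, length_bp)`;
#'   must differ from `origin_pos`.
#' @param circular Logical; bacterial chromosomes are circular.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(length_bp, origin_pos = 0,
                         terminus_pos = floor(length_bp / 2),
                         circular = TRUE) {
  .check_number(length_bp, "length_bp", lower = 1, integer = TRUE)
  .check_number(origin_pos, "origin_pos", lower = 0, upper = length_bp - 1)
  .check_number(terminus_pos, "terminus_pos", lower = 0,
                upper = length_bp - 1)
  if (origin_pos == terminus_pos)
    stop("origin and terminus must differ", call. = FALSE)
  structure(list(length_bp = as.integer(length_bp),
                 origin_pos = origin_pos,
                 terminus_pos = terminus_pos,
                 circular = isTRUE(circular)),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("Circular genome: %d bp, oriC at %d, terminus at %d\n",
              x$length_bp, as.integer(x$origin_pos),
              as.integer(x$terminus_pos)))
  invisible(x)
}

# Arc distance from `from` to `to` travelling in increasing coordinates.
.arc_forward <- function(from, to, length_bp) {
  (to - from) %% length_bp
}

#' Replichore membership of genome positions
#'
#' A position belongs to the right replichore if it lies on the arc from the
#' origin to the terminus travelled in increasing coordinate direction
#' (wrapping through zero if needed), and to the left replichore otherwise.
#'
#' @param pos Numeric vector of positions in `[0, length_bp)`.
#' @param genome A [genome_model()].
#' @return Character vector, `"right"` or `"left"`.
#' @export
replichore_of <- function(pos, genome) {
  stopifnot(inherits(genome, "genome_model"))
  span <- .arc_forward(genome$origin_pos, genome$terminus_pos,
                       genome$length_bp)
  d <- .arc_forward(genome$origin_pos, pos %% genome$length_bp,
                    genome$length_bp)
  ifelse(d < span, "right", "left")
}

#' Orientation of a feature relative to replication
#'
#' On the replichore where the fork moves in the increasing-coordinate
#' direction, a plus-strand gene is transcribed codirectionally with
#' replication; flipping the strand (or the replichore) flips the
#' orientation to head-on. Membership is decided by the feature midpoint,
#' so features are never split across replichores.
#'
#' @param start,end Feature bounds, 0-based half-open. `end` may exceed
#'   `length_bp` for features wrapping the origin of coordinates.
#' @param strand `"+"` or `"-"` (vectors recycled as usual).
#' @param genome A [genome_model()].
#' @return Character vector, `"codirectional"` or `"head_on"`.
#' @export
feature_orientation <- function(start, end, strand, genome) {
  if (any(start >= end)) stop("feature start must be < end", call. = FALSE)
  mid <- ((start + end) / 2) %% genome$length_bp
  repl <- replichore_of(mid, genome)
  fork_plus <- repl == "right"     # fork moves with increasing coordinate
  gene_plus <- strand == "+"
  ifelse(fork_plus == gene_plus, "codirectional", "head_on")
}

#' Generate a synthetic annotated genome
#'
#' Packs non-overlapping transcribed features onto a circular chromosome:
#' CDSs (a fraction of which carry abutting 5' and 3' UTRs), non-coding
#' RNAs, a small set of rRNA consensus loci (masked from feature scoring,
#' mirroring the single-consensus treatment of multicopy rRNA), and tRNAs.
#' Strands are assigned with a codirectional bias typical of bacterial
#' genomes, and orientation labels are derived from the replichore geometry.
#'
#' @param config A [sim_config()]; fields used: `genome_length_bp`,
#'   `origin_pos`, `terminus_pos`, `n_cds`, `cds_length_mean_bp`,
#'   `utr_fraction`, `utr_length_bp`, `n_ncrna`, `n_rrna`, `n_trna`,
#'   `codirectional_bias`, `seed`.
#' @return A list with elements `genome` (a [genome_model()]) and
#'   `features` (data frame with columns `feature_id`, `feature_class`,
#'   `start`, `end`, `strand`, `orientation`, `masked`; coordinates 0-based
#'   half-open).
#' @export
generate_genome <- function(config) {
  cfg <- as_sim_config(config)
  genome <- genome_model(cfg$genome_length_bp, cfg$origin_pos,
                         cfg$terminus_pos)
  set.seed(substream_seed(cfg$seed, "genome"))

  n_cds <- cfg$n_cds
  cds_len <- pmax(150L, as.integer(round(stats::rlnorm(
    n_cds, log(cfg$cds_length_mean_bp), 0.35))))
  has_utr <- stats::runif(n_cds) < cfg$utr_fraction
  unit_len <- cds_len + ifelse(has_utr, 2L * cfg$utr_length_bp, 0L)

  other_class <- c(rep("ncRNA", cfg$n_ncrna), rep("rRNA", cfg$n_rrna),
                   rep("tRNA", cfg$n_trna))
  other_len <- c(as.integer(round(stats::runif(cfg$n_ncrna, 120, 400))),
                 rep(4500L, cfg$n_rrna), rep(80L, cfg$n_trna))

  n_units <- n_cds + length(other_class)
  total <- sum(unit_len) + sum(other_len)
  min_gap <- 20L
  if (total + n_units * min_gap > genome$length_bp)
    stop(sprintf(paste0("infeasible packing: %d bp of features (+gaps) do ",
                        "not fit a %d bp genome"),
                 total + n_units * min_gap, genome$length_bp),
         call. = FALSE)

  # Distribute the slack as random gaps, then lay units around the circle.
  lens <- c(unit_len, other_len)
  ord <- sample.int(n_units)
  slack <- genome$length_bp - sum(lens) - n_units * min_gap
  gaps <- min_gap + c(stats::rmultinom(1, slack, rep(1, n_units)))
  pos <- cumsum(gaps + lens[ord]) - lens[ord]

  classes <- c(rep("CDS", n_cds), other_class)[ord]
  starts <- pos
  ends <- pos + lens[ord]
  idx_orig <- ord

  fork_right <- replichore_of(((starts + ends) / 2) %% genome$length_bp,
                              genome) == "right"
  codir <- stats::runif(n_units) < cfg$codirectional_bias
  strand <- ifelse(fork_right == codir, "+", "-")

  rows <- list()
  cds_counter <- 0L
  for (i in seq_len(n_units)) {
    cls <- classes[i]
    if (cls == "CDS") {
      cds_counter <- cds_counter + 1L
      j <- idx_orig[i]                 # index into cds vectors
      utr <- has_utr[j]
      id <- sprintf("gene%04d", cds_counter)
      s <- starts[i]; e <- ends[i]; st <- strand[i]
      if (utr) {
        u <- cfg$utr_length_bp
        if (st == "+") {
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = c(paste0(id, "_5utr"), id, paste0(id, "_3utr")),
            feature_class = c("UTR5", "CDS", "UTR3"),
            start = c(s, s + u, e - u),
            end = c(s + u, e - u, e),
            strand = st, stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = c(paste0(id, "_3utr"), id, paste0(id, "_5utr")),
            feature_class = c("UTR3", "CDS", "UTR5"),
            start = c(s, s + u, e - u),
            end = c(s + u, e - u, e),
            strand = st, stringsAsFactors = FALSE)
        }
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = id, feature_class = "CDS", start = s, end = e,
          strand = st, stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = sprintf("%s%03d", tolower(cls), i),
        feature_class = cls, start = starts[i], end = ends[i],
        strand = strand[i], stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, rows)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$orientation <- feature_orientation(features$start, features$end,
                                              features$strand, genome)
  features$masked <- features$feature_class == "rRNA"
  rownames(features) <- NULL
  list(genome = genome, features = features)
}
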