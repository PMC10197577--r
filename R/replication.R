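# Replication-progression profiling from sequencing coverage. The slope of
# the log2 counts-per-million coverage profile along each replichore is a
# proxy for fork progression: a shallow decline means rapid replication, a
# locally steep decline marks a region the fork traverses with difficulty.

#' Convert coverage counts to log2 counts-per-million
#'
#' `log2((count + pseudocount) * 1e6 / library_size)`. The pseudocount
#' (default 0.5) guards zero counts and is recorded as an attribute; set
#' it to 0 for exactness. Invariant under joint rescaling of counts and
#' library size.
#'
#' @param counts Non-negative numeric vector or matrix (positions x
#'   replicates); CPM is computed per sample before any averaging.
#' @param library_size Positive scalar or per-column vector (default:
#'   column sums).
#' @param pseudocount Non-negative pseudocount (default 0.5).
#' @return Same shape as `counts`, with attribute `"pseudocount"`.
#' @export
coverage_log2cpm <- function(counts, library_size = NULL,
                             pseudocount = 0.5) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  .check_number(pseudocount, "pseudocount", lower = 0)
  m <- as.matrix(counts)
  if (is.null(library_size)) library_size <- colSums(m)
  if (any(library_size <= 0))
    stop("`library_size` must be > 0", call. = FALSE)
  out <- log2(sweep(m + pseudocount, 2, library_size, `/`) * 1e6)
  if (is.vector(counts)) out <- drop(out)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Mean log2 CPM across biological replicates
#'
#' @param counts Positions x replicates count matrix.
#' @param library_size Optional per-replicate library sizes.
#' @param pseudocount As in [coverage_log2cpm()].
#' @return Numeric vector of replicate-mean log2 CPM.
#' @export
mean_log2cpm <- function(counts, library_size = NULL, pseudocount = 0.5) {
  rowMeans(coverage_log2cpm(counts, library_size, pseudocount))
}

#' Loess-smooth a coverage track
#'
#' Local linear regression with tricube weights over the nearest
#' span-fraction of points (the loess smoother), evaluated at every input
#' position. The default span of 0.03 smooths for display while
#' preserving replichore-scale slope structure; exactly linear input is
#' reproduced.
#'
#' @param pos Numeric positions (sorted).
#' @param values Numeric track values, same length.
#' @param span Fraction of points per local fit, in (0, 1]; must cover at
#'   least 3 points.
#' @return Numeric vector of smoothed values.
#' @export
smooth_coverage <- function(pos, values, span = 0.03) {
  n <- length(pos)
  if (n < 10) stop("need at least 10 points", call. = FALSE)
  if (length(values) != n)
    stop("`pos` and `values` must have equal length", call. = FALSE)
  .check_number(span, "span", lower = .Machine$double.eps, upper = 1)
  if (span * n < 3)
    stop("span covers fewer than 3 points", call. = FALSE)
  fit <- stats::loess(values ~ pos, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  stats::predict(fit, pos)
}

# Least-squares slope of y on x.
.ls_slope <- function(x, y) {
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(0)
  sum(xc * (y - mean(y))) / denom
}

#' Scan a smoothed coverage profile for replication stalls
#'
#' Computes the local least-squares slope of the smoothed log2 coverage in
#' sliding windows, converts slopes to robust z-scores per replichore
#' after sign adjustment (slopes are expressed per bp of fork travel, so
#' that "more negative" means "slower fork" on both replichores), and
#' reports contiguous runs of z below `-threshold_z` as stall intervals.
#'
#' @param pos Positions (sorted, regularly spaced).
#' @param smoothed Smoothed log2 coverage values.
#' @param genome A [genome_model()] supplying origin/terminus; slope
#'   windows never span a replichore boundary.
#' @param window_bp Slope window width (default 5000).
#' @param threshold_z Stall threshold on the slope z-score (default 4).
#' @return List of class `stall_scan`: `windows` (data frame `start`,
#'   `end`, `mid`, `replichore`, `slope`, `z`) and `stalls` (data frame
#'   `start`, `end`, `min_z`).
#' @export
slope_stall_scan <- function(pos, smoothed, genome, window_bp = 5000,
                             threshold_z = 4) {
  stopifnot(inherits(genome, "genome_model"))
  n <- length(pos)
  if (length(smoothed) != n)
    stop("`pos` and `smoothed` must have equal length", call. = FALSE)
  step <- stats::median(diff(pos))
  k <- max(2L, floor(window_bp / step))
  repl <- replichore_of(pos, genome)

  win <- list()
  for (r in c("right", "left")) {
    idx <- which(repl == r)
    if (length(idx) < k) next
    # fork travel coordinate: increases in the direction of fork movement
    fork_sign <- if (r == "right") 1 else -1
    starts <- seq(1L, length(idx) - k + 1L, by = k)
    for (s0 in starts) {
      ii <- idx[s0:(s0 + k - 1L)]
      slope <- .ls_slope(pos[ii] * fork_sign, smoothed[ii])
      win[[length(win) + 1L]] <- data.frame(
        start = min(pos[ii]), end = max(pos[ii]) + step,
        mid = mean(pos[ii]), replichore = r, slope = slope,
        stringsAsFactors = FALSE)
    }
  }
  windows <- do.call(rbind, win)
  windows$z <- NA_real_
  for (r in unique(windows$replichore)) {
    sel <- windows$replichore == r
    s <- windows$slope[sel]
    if (length(s) >= 2 && stats::mad(s) > 0) {
      windows$z[sel] <- robust_z(s)
    } else {
      windows$z[sel] <- 0    # degenerate (constant) profile: no stalls
    }
  }

  below <- windows$z < -threshold_z
  stalls <- list()
  if (any(below)) {
    ord <- order(windows$replichore, windows$mid)
    wo <- windows[ord, ]; bo <- below[ord]
    runs <- rle(paste0(wo$replichore, "_", bo))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in seq_along(runs$values)) {
      if (!grepl("_TRUE$", runs$values[j])) next
      ii <- starts[j]:ends[j]
      stalls[[length(stalls) + 1L]] <- data.frame(
        start = min(wo$start[ii]), end = max(wo$end[ii]),
        min_z = min(wo$z[ii]), stringsAsFactors = FALSE)
    }
  }
  stalls <- if (length(stalls)) do.call(rbind, stalls) else
    data.frame(start = numeric(0), end = numeric(0), min_z = numeric(0))
  structure(list(windows = windows, stalls = stalls,
                 window_bp = window_bp, threshold_z = threshold_z),
            class = "stall_scan")
}

#' @export
print.stall_scan <- function(x, ...) {
  cat(sprintf("Stall scan: %d windows of %g bp, %d stall interval(s) at |z| > %g\n",
              nrow(x$windows), x$window_bp, nrow(x$stalls), x$threshold_z))
  if (nrow(x$stalls)) print(x$stalls)
  invisible(x)
}
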