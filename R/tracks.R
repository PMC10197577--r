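# Track-level transforms: robust z-scores and rolling medians. These are
# applied both to enrichment tracks and to coverage-derived slope tracks.

#' Robust z-scores
#'
#' Centers by the median and scales by 1.4826 times the raw median absolute
#' deviation, the consistency constant that makes the MAD estimate the
#' standard deviation for normal data. Used to place enrichment and slope
#' tracks from different genotypes on a comparable dimensionless scale.
#'
#' @param x Numeric vector of finite values, length >= 2.
#' @param fallback_sd If `TRUE`, fall back to (x - mean)/sd when the MAD is
#'   zero (e.g. a track that is constant over more than half its length).
#'   The default is to raise a degenerate-scale error.
#' @return Numeric vector of z-scores with median 0 and scaled MAD 1.
#' @examples
#' robust_z(c(1, 2, 3, 4, 100))
#' @export
robust_z <- function(x, fallback_sd = FALSE) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("`x` must be a numeric vector with at least 2 values", call. = FALSE)
  if (!all(is.finite(x)))
    stop("`x` contains non-finite values", call. = FALSE)
  med <- stats::median(x)
  scale <- 1.4826 * stats::median(abs(x - med))
  if (scale == 0) {
    if (!fallback_sd)
      stop("degenerate scale: median absolute deviation is zero",
           call. = FALSE)
    s <- stats::sd(x)
    if (s == 0)
      stop("degenerate scale: all values equal", call. = FALSE)
    return((x - mean(x)) / s)
  }
  (x - med) / scale
}

#' Rolling median smoothing
#'
#' Centered sliding-window median over a regularly binned track, the
#' smoothing used for genome-overview displays of enrichment signal
#' (e.g. a 10 kb sliding median at 100 bp bins) and for contrast tracks
#' (500 bp rolling median). Windows shrink at the edges of linear tracks;
#' for circular tracks the window wraps around the ends. Even-cardinality
#' windows use the midpoint of the two central order statistics.
#'
#' @param x Numeric vector, one value per bin, in genome order.
#' @param window_bp Window width in base pairs; must be at least `bin_bp`.
#' @param bin_bp Width of one bin in base pairs (default 1, i.e. `window_bp`
#'   is a count of bins).
#' @param circular If `TRUE`, windows wrap past the track ends.
#' @return Numeric vector of smoothed values, same length as `x`.
#' @examples
#' rolling_median(c(1, 5, 2, 8, 3), window_bp = 3)
#' @export
rolling_median <- function(x, window_bp, bin_bp = 1, circular = FALSE) {
  if (length(x) == 0L) stop("empty track", call. = FALSE)
  .check_number(window_bp, "window_bp", lower = bin_bp)
  .check_number(bin_bp, "bin_bp", lower = 1)
  w <- max(1L, floor(window_bp / bin_bp))
  if (w == 1L) return(x)
  n <- length(x)
  lo <- -floor((w - 1) / 2)
  hi <- ceiling((w - 1) / 2)
  vapply(seq_len(n), function(i) {
    idx <- i + lo:hi
    if (circular) {
      idx <- ((idx - 1L) %% n) + 1L
    } else {
      idx <- idx[idx >= 1L & idx <= n]
    }
    stats::median(x[idx])
  }, numeric(1))
}
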