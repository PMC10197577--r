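#' @keywords internal
"_PACKAGE"

# Argument checks shared across the package. All errors name the offending
# argument so pipeline-stage failures are traceable.

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` must be in [%s, %s]", name, lower, upper),
         call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(x)
}

.check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("`%s` is missing required column(s): %s", name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Derive a stage-specific random seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed from the master
#' seed through this function, so that stages are decoupled (re-running one
#' stage does not perturb another) while the whole run stays reproducible.
#' Seeds are kept below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stage) {
  .check_number(seed, "seed", integer = TRUE)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 1009 + h * 9176 + 17) %% 2147483647)
}

# Shortest interval containing `prob` mass of the sorted draws.
.hpd_interval <- function(draws, prob = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[(m + 1L):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

# Split-chain potential scale reduction factor (Rhat). `draws` is an
# iterations x chains matrix.
.split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  n2 <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  b <- n2 * stats::var(means)
  w <- mean(vars)
  if (w == 0) return(1)
  sqrt(((n2 - 1) / n2 * w + b / n2) / w)
}

# Equal-tailed interval helper used by every posterior summary.
.quantile_interval <- function(x, level = 0.90) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
}
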