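# Mutation-accumulation-line statistics: mutation classification, the
# structural-variant filtering rules, exact Poisson rate estimates, exact
# conditional rate-ratio tests, and positional mutation density.

.purines <- c("A", "G")

#' Classify a mutation from its ref and alt alleles
#'
#' Equal-length-1 substitutions are transitions (purine to purine or
#' pyrimidine to pyrimidine) or transversions (across classes);
#' length-changing events are insertions or deletions by the sign of the
#' length change. Classification is invariant under reverse-complementing
#' both alleles.
#'
#' @param ref,alt Non-empty allele strings over A/C/G/T (vectorized).
#' @return Character vector in
#'   `{transition, transversion, insertion, deletion}`.
#' @examples
#' classify_mutation("A", "G")   # transition
#' classify_mutation("C", "A")   # transversion
#' classify_mutation("AC", "A")  # deletion
#' @export
classify_mutation <- function(ref, alt) {
  if (length(ref) != length(alt))
    stop("`ref` and `alt` must have equal length", call. = FALSE)
  ok <- grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt)
  if (!all(ok))
    stop("alleles must be non-empty strings over A/C/G/T", call. = FALSE)
  if (any(ref == alt))
    stop("ref and alt must differ", call. = FALSE)
  nr <- nchar(ref); na <- nchar(alt)
  out <- character(length(ref))
  sub1 <- nr == 1L & na == 1L
  same_class <- (ref %in% .purines) == (alt %in% .purines)
  out[sub1 & same_class] <- "transition"
  out[sub1 & !same_class] <- "transversion"
  out[na > nr] <- "insertion"
  out[na < nr] <- "deletion"
  if (any(out == ""))
    stop("equal-length multi-base substitutions are not classifiable",
         call. = FALSE)
  out
}

#' Exclusion window around an intended genetic alteration
#'
#' @param start,end Interval of the engineered alteration (inclusive
#'   coordinates as annotated).
#' @param margin_bp Margin on each side (default 100).
#' @return Named numeric vector `c(start, end)` of the exclusion window.
#' @export
sv_exclusion_window <- function(start, end, margin_bp = 100) {
  if (start > end) stop("interval start must be <= end", call. = FALSE)
  c(start = start - margin_bp, end = end + margin_bp)
}

#' Filter structural variants near the intended alteration
#'
#' Structural variants detected within `margin_bp` of the engineered
#' alteration of an MA line are artifacts of strain construction, not
#' accumulated mutations: any SV overlapping the closed exclusion window
#' `[start - margin, end + margin]` is removed.
#'
#' @param svs Data frame with `start`, `end` columns (and any others).
#' @param intended_interval Length-2 numeric `c(start, end)` of the
#'   engineered alteration.
#' @param margin_bp Margin (default 100).
#' @return The retained SV rows.
#' @export
filter_structural_variants <- function(svs, intended_interval,
                                       margin_bp = 100) {
  .check_columns(svs, c("start", "end"), "svs")
  if (any(svs$start >= svs$end))
    stop("SV start must be < end", call. = FALSE)
  w <- sv_exclusion_window(intended_interval[1], intended_interval[2],
                           margin_bp)
  overlap <- svs$start <= w[["end"]] & svs$end >= w[["start"]]
  svs[!overlap, , drop = FALSE]
}

#' Flag MA lines compromised by SVs in blocklisted genes
#'
#' A line carrying a structural variant that overlaps a blocklisted
#' feature (e.g. a mismatch-repair gene, whose loss would distort the
#' mutation rate and spectrum) is flagged for exclusion from rate
#' estimates, numerator and denominator alike.
#'
#' @param svs Data frame with `line_id`, `start`, `end`.
#' @param blocklist_features Data frame with `start`, `end` (and
#'   optionally `feature_id`).
#' @return Character vector of flagged line ids (possibly empty).
#' @export
flag_compromised_lines <- function(svs, blocklist_features) {
  .check_columns(svs, c("line_id", "start", "end"), "svs")
  if (is.null(blocklist_features) || !nrow(blocklist_features))
    return(character(0))
  .check_columns(blocklist_features, c("start", "end"),
                 "blocklist_features")
  flagged <- character(0)
  for (i in seq_len(nrow(blocklist_features))) {
    b <- blocklist_features[i, ]
    hit <- svs$start <= b$end & svs$end >= b$start
    flagged <- c(flagged, svs$line_id[hit])
  }
  sort(unique(flagged))
}

#' Exact Poisson rate estimate with Garwood confidence interval
#'
#' Rate = count / exposure with the exact (Garwood) CI from chi-square
#' quantiles: lower = qchisq(a/2, 2c) / (2T), upper =
#' qchisq(1 - a/2, 2c + 2) / (2T). A zero count gives a zero lower bound.
#'
#' @param count Non-negative event count.
#' @param exposure Positive exposure (generations, or bp x generations).
#' @param level Confidence level (default 0.95).
#' @return Data frame `count`, `exposure`, `rate`, `ci_lower`, `ci_upper`.
#' @examples
#' mutation_rate_ci(17, 265500)   # the structural-variant rate 6.4e-5
#' @export
mutation_rate_ci <- function(count, exposure, level = 0.95) {
  .check_number(count, "count", lower = 0, integer = TRUE)
  if (exposure <= 0) stop("`exposure` must be > 0", call. = FALSE)
  a <- 1 - level
  lower <- if (count == 0) 0 else
    stats::qchisq(a / 2, 2 * count) / (2 * exposure)
  upper <- stats::qchisq(1 - a / 2, 2 * count + 2) / (2 * exposure)
  data.frame(count = count, exposure = exposure, rate = count / exposure,
             ci_lower = lower, ci_upper = upper)
}

#' Exact conditional rate-ratio test for two Poisson counts
#'
#' Conditional on the total `n = count1 + count2`, `count1` is binomial
#' with success probability `exposure1 / (exposure1 + exposure2)` under
#' the null of equal rates; the p-value is the corresponding binomial
#' tail probability. The ratio is `(count1/exposure1) / (count2/exposure2)`.
#'
#' @param count1,count2 Non-negative counts (not both zero).
#' @param exposure1,exposure2 Positive exposures.
#' @param alternative `"greater"` (rate1 > rate2), `"less"`, or
#'   `"two.sided"` (twice the smaller tail, capped at 1).
#' @return Data frame `ratio`, `p_value`, `alternative`.
#' @examples
#' rate_ratio_test(17, 265500, 6, 6 / 2.2e-5, alternative = "greater")
#' @export
rate_ratio_test <- function(count1, exposure1, count2, exposure2,
                            alternative = c("greater", "less",
                                            "two.sided")) {
  alternative <- match.arg(alternative)
  .check_number(count1, "count1", lower = 0, integer = TRUE)
  .check_number(count2, "count2", lower = 0, integer = TRUE)
  if (exposure1 <= 0 || exposure2 <= 0)
    stop("exposures must be > 0", call. = FALSE)
  if (count1 + count2 == 0)
    stop("test undefined when both counts are zero", call. = FALSE)
  n <- count1 + count2
  p0 <- exposure1 / (exposure1 + exposure2)
  p_greater <- 1 - stats::pbinom(count1 - 1, n, p0)
  p_less <- stats::pbinom(count1, n, p0)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  ratio <- (count1 / exposure1) / (count2 / exposure2)
  data.frame(ratio = ratio, p_value = p, alternative = alternative,
             stringsAsFactors = FALSE)
}

#' Positional density of mutations along the genome
#'
#' Gaussian kernel density of mutation positions on the linear genome
#' coordinate, with bandwidth `adjust` times the Silverman reference rule
#' (0.9 min(sd, IQR/1.34) n^(-1/5)); the narrow default `adjust = 0.2`
#' resolves local clusters such as terminus-proximal transversions.
#'
#' @param positions Numeric vector of at least 2 distinct positions.
#' @param genome_length Genome length; the curve is evaluated on
#'   `[0, genome_length]`.
#' @param adjust Bandwidth multiplier (default 0.2).
#' @param n Number of evaluation points (default 512).
#' @return Data frame `x`, `density` (integrates to 1), with the bandwidth
#'   in attribute `"bw"`.
#' @export
positional_density <- function(positions, genome_length, adjust = 0.2,
                               n = 512) {
  if (length(positions) < 2L)
    stop("need at least 2 positions", call. = FALSE)
  if (length(unique(positions)) == 1L)
    stop("all positions identical: density undefined", call. = FALSE)
  d <- stats::density(positions, bw = "nrd0", adjust = adjust, n = n,
                      from = 0, to = genome_length)
  out <- data.frame(x = d$x, density = d$y)
  attr(out, "bw") <- d$bw
  out
}
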