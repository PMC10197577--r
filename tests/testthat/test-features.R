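mk_ztrack <- function(z, bin_bp = 100, strand = "+") {
  data.frame(start = seq(0, by = bin_bp, length.out = length(z)),
             end = seq(bin_bp, by = bin_bp, length.out = length(z)),
             strand = strand, z = z, stringsAsFactors = FALSE)
}

mk_feature <- function(id, start, end, strand = "+", class = "CDS",
                       orientation = "codirectional", masked = FALSE) {
  data.frame(feature_id = id, feature_class = class, start = start,
             end = end, strand = strand, orientation = orientation,
             masked = masked, stringsAsFactors = FALSE)
}

test_that("feature scores are bin medians on the sense strand", {
  zt <- mk_ztrack(c(-1, 0, 2))
  f <- mk_feature("a", 0, 300)
  expect_equal(score_features(zt, f)$score, 0)
  # single-bin feature takes that bin's z
  expect_equal(score_features(zt, mk_feature("b", 100, 200))$score, 0)
  expect_equal(score_features(zt, mk_feature("c", 200, 300))$score, 2)
  # bin order is irrelevant
  expect_equal(score_features(zt[3:1, ], f)$score, 0)
  # antisense bins do not contribute
  f_minus <- mk_feature("d", 0, 300, strand = "-")
  out <- score_features(zt, f_minus)
  expect_true(is.na(out$score))
  expect_equal(out$n_bins, 0L)
  # masked features are skipped
  fm <- rbind(f, mk_feature("r", 0, 300, class = "rRNA", masked = TRUE))
  expect_equal(nrow(score_features(zt, fm)), 1L)
})

test_that("the first-100-bp window anchors at the 5' end per strand", {
  zt <- mk_ztrack(c(5, 0, 0, 0, 9))
  f_plus <- mk_feature("p", 0, 500)
  f_minus <- mk_feature("m", 0, 500, strand = "-")
  zt_minus <- mk_ztrack(c(5, 0, 0, 0, 9), strand = "-")
  expect_equal(score_features(zt, f_plus, window = "first100")$score, 5)
  expect_equal(score_features(zt_minus, f_minus,
                              window = "first100")$score, 9)
  # features shorter than the window use their full span
  short <- mk_feature("s", 100, 180)
  expect_equal(score_features(zt, short, window = "first100")$score, 0)
})

test_that("orientation comparison recovers a planted shift", {
  set.seed(2)
  n <- 120
  sc <- data.frame(
    feature_id = sprintf("f%03d", 1:n), feature_class = "CDS",
    orientation = rep(c("head_on", "codirectional"), each = n / 2),
    window = "full",
    score = c(rnorm(n / 2) + 1, rnorm(n / 2)),
    stringsAsFactors = FALSE)
  out <- orientation_comparison(sc, feature_class = "CDS", seed = 3)
  expect_equal(out$estimate, 1, tolerance = 0.5)
  expect_gt(out$ci_lower, 0)
  expect_lt(out$p_value, 0.01)
})

test_that("null orientation comparisons are rarely significant", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 80
    sc <- data.frame(
      feature_id = sprintf("f%03d", 1:n), feature_class = "CDS",
      orientation = rep(c("head_on", "codirectional"), each = n / 2),
      window = "full", score = rnorm(n), stringsAsFactors = FALSE)
    orientation_comparison(sc, n_boot = 200, seed = s)$p_value < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("orientation comparison honors filters and small groups", {
  set.seed(4)
  n <- 40
  sc <- data.frame(
    feature_id = sprintf("f%03d", 1:n), feature_class = "CDS",
    orientation = c(rep("head_on", 2), rep("codirectional", n - 2)),
    window = "full", score = rnorm(n), stringsAsFactors = FALSE)
  out <- orientation_comparison(sc)
  expect_true(is.na(out$p_value))      # head-on group below min_n
  expect_false(is.na(out$estimate))

  expr <- data.frame(feature_id = sc$feature_id, expr_z = rnorm(n))
  out_top <- orientation_comparison(
    sc, expression = expr, expression_filter = "top20", min_n = 1)
  expect_lte(out_top$n_head_on + out_top$n_codirectional, ceiling(0.25 * n))
  expect_error(orientation_comparison(sc, expression_filter = "top20"),
               "required")
})

test_that("FDR stars follow the printed bands", {
  cmp <- data.frame(p_value = c(0.03, 0.005, 0.0005, 0.2))
  # single comparisons per batch: q equals p
  stars <- vapply(seq_len(nrow(cmp)), function(i)
    add_fdr(cmp[i, , drop = FALSE])$stars, character(1))
  expect_equal(stars, c("*", "**", "***", ""))
  # batch correction is monotone and q >= p
  batch <- add_fdr(cmp)
  expect_true(all(batch$q_value >= batch$p_value))
  expect_identical(order(batch$q_value), order(batch$p_value))
})

test_that("paired genotype differences behave on constructed tables", {
  set.seed(6)
  n <- 50
  a <- data.frame(feature_id = sprintf("f%02d", 1:n),
                  feature_class = "CDS", orientation = "codirectional",
                  window = "full", score = rnorm(n),
                  stringsAsFactors = FALSE)
  b <- a
  expect_equal(genotype_paired_difference(a, b)$estimate, 0)
  b$score <- a$score + 0.5
  out <- genotype_paired_difference(a, b, seed = 2)
  expect_equal(out$estimate, 0.5, tolerance = 1e-9)
  expect_gt(out$ci_lower, 0)
  # three consensus rRNA features: point estimate only, no CI or test
  ar <- a[1:3, ]; ar$feature_class <- "rRNA"
  br <- b[1:3, ]; br$feature_class <- "rRNA"
  out_r <- genotype_paired_difference(ar, br, feature_class = "rRNA")
  expect_equal(out_r$estimate, 0.5, tolerance = 1e-9)
  expect_true(is.na(out_r$ci_lower) && is.na(out_r$p_value))
  expect_error(genotype_paired_difference(a, b, feature_class = "tRNA"),
               "no shared features")
})

test_that("bootstrap CIs cover a planted median shift", {
  covered <- vapply(1:40, function(s) {
    set.seed(s)
    n <- 200
    a <- data.frame(feature_id = sprintf("f%03d", 1:n),
                    feature_class = "CDS", orientation = "codirectional",
                    window = "full", score = rnorm(n),
                    stringsAsFactors = FALSE)
    b <- a
    b$score <- a$score + 0.4 + rnorm(n, 0, 0.2)
    out <- genotype_paired_difference(a, b, n_boot = 400, seed = s)
    out$ci_lower <= 0.4 && out$ci_upper >= 0.4
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("the feature regression recovers a planted expression effect", {
  set.seed(11)
  n <- 500
  ho <- rbinom(n, 1, 0.3)
  ez <- rnorm(n)
  sc <- data.frame(
    feature_id = sprintf("f%03d", 1:n), feature_class = "CDS",
    orientation = ifelse(ho == 1, "head_on", "codirectional"),
    window = "full",
    score = 0.2 + 0.5 * ez - 0.3 * ho + rnorm(n, 0, 0.5),
    stringsAsFactors = FALSE)
  expr <- data.frame(feature_id = sc$feature_id, expr_z = ez)
  fit <- fit_feature_regression(sc, expr, n_draws = 500, seed = 1)
  expect_equal(ncol(fit$draws), 4L)
  expect_equal(nrow(fit$draws), 500L)
  expect_true(fit$ci_lower["expr_z"] <= 0.5 &&
                fit$ci_upper["expr_z"] >= 0.5)
  post_sd <- sd(fit$draws[, "orientation_head_on"])
  expect_lt(abs(fit$mean["orientation_head_on"] - (-0.3)), 4 * post_sd)
})

test_that("feature regression intervals are calibrated under the null", {
  covered <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 120
    ho <- rbinom(n, 1, 0.3)
    ez <- rnorm(n)
    sc <- data.frame(
      feature_id = sprintf("f%03d", 1:n), feature_class = "CDS",
      orientation = ifelse(ho == 1, "head_on", "codirectional"),
      window = "full", score = rnorm(n), stringsAsFactors = FALSE)
    expr <- data.frame(feature_id = sc$feature_id, expr_z = ez)
    fit <- fit_feature_regression(sc, expr, n_draws = 400, seed = s)
    all(fit$ci_lower[-1] <= 0 & fit$ci_upper[-1] >= 0)
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("degenerate regression designs are rejected", {
  set.seed(3)
  n <- 30
  sc <- data.frame(
    feature_id = sprintf("f%02d", 1:n), feature_class = "CDS",
    orientation = "codirectional", window = "full", score = rnorm(n),
    stringsAsFactors = FALSE)
  expr <- data.frame(feature_id = sc$feature_id, expr_z = 0)
  # orientation constant and expression constant: collinear with intercept
  expect_error(fit_feature_regression(sc, expr), "collinear")
  expect_error(fit_feature_regression(sc[1:10, ],
                                      expr[1:10, , drop = FALSE]),
               "at least 20")
})
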