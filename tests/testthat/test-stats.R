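test_that("clearly bimodal and unimodal samples are classified correctly", {
  set.seed(11)
  bi <- fit_bimodal(c(rnorm(400, -25, 10), rnorm(400, 25, 10)))
  expect_identical(bi$preferred, "double")
  expect_true(bi$bimodal)
  expect_lt(bi$double$mu1, 0)
  expect_gt(bi$double$mu2, 0)
  un <- fit_bimodal(rnorm(800, 12, 15))
  expect_false(un$bimodal)
  # nested models: the richer fit can only reduce the residual sum of squares
  expect_lte(bi$double$ss, bi$single$ss)
  expect_lte(un$double$ss, un$single$ss + 1e-6)
  expect_gte(bi$F, 0)
  expect_gte(un$F, 0)
})

test_that("two same-sign component means are not called bimodal", {
  set.seed(12)
  x <- c(rnorm(400, -40, 8), rnorm(400, -10, 8))
  fit <- fit_bimodal(x)
  expect_identical(fit$preferred, "double")
  expect_false(fit$bimodal)
  expect_lt(fit$double$mu2, 0)
})

test_that("fit_bimodal is mirror-consistent", {
  set.seed(13)
  x <- c(rnorm(350, -30, 9), rnorm(450, 20, 11))
  a <- fit_bimodal(x)
  b <- fit_bimodal(-x)
  expect_identical(a$bimodal, b$bimodal)
  expect_equal(a$double$mu1, -b$double$mu2, tolerance = 0.3)
  expect_equal(a$double$mu2, -b$double$mu1, tolerance = 0.3)
})

test_that("Mann-Whitney, Kruskal-Dunn and Wilcoxon behave as expected", {
  x <- c(1.2, 5.3, 2.2, 8.1, 4.4, 3.3, 6.1, 7.7)
  mw <- compare_groups(x, x, kind = "mann-whitney")
  expect_gt(mw$p.value, 0.95)
  # one-sample signed-rank statistic: all-positive sample of 5 -> V = 15
  # (brute force: sum of ranks of |x| with positive sign = 1+2+3+4+5)
  w <- compare_groups(c(1, 2, 3, 4, 5), kind = "wilcoxon-zero")
  expect_equal(unname(w$statistic), 15)
  expect_error(compare_groups(c(1, 2), c(3, 4, 5), kind = "mann-whitney"),
               "n >= 3")
  # strongly shifted groups separate at p < 0.001 in nearly all seeded runs
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    p <- compare_groups(rnorm(50), rnorm(50, 3), kind = "mann-whitney")$p.value
    hits <- hits + (p < 0.001)
  }
  expect_gte(hits, 20)
  set.seed(3)
  groups <- list(a = rnorm(20), b = rnorm(20, 2.5), c = rnorm(20))
  kd <- compare_groups(groups = groups, kind = "kruskal-dunn")
  expect_lt(kd$kruskal$p.value, 0.01)
  expect_identical(nrow(kd$dunn), 3L)
  ab <- kd$dunn$p_adjusted[kd$dunn$group1 == "a" & kd$dunn$group2 == "b"]
  ac <- kd$dunn$p_adjusted[kd$dunn$group1 == "a" & kd$dunn$group2 == "c"]
  expect_lt(ab, 0.05)
  expect_gt(ac, 0.5)
  expect_true(all(kd$dunn$p_adjusted >= kd$dunn$p - 1e-12))
})

test_that("correlations recover exact linear and antilinear relations", {
  x <- c(1, 3, 4, 7, 9, 12)
  r1 <- chirality_correlation(data.frame(rf_tilt_mean = x, director_mean = 2 * x))
  expect_equal(r1$pearson_r, 1, tolerance = 1e-12)
  expect_equal(r1$spearman_r, 1, tolerance = 1e-12)
  r2 <- chirality_correlation(data.frame(rf_tilt_mean = x, director_mean = -x))
  expect_equal(r2$pearson_r, -1, tolerance = 1e-12)
  expect_equal(r2$spearman_r, -1, tolerance = 1e-12)
})

test_that("Spearman is invariant under monotone transforms; rows with missing readouts drop", {
  set.seed(21)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.7)
  base <- chirality_correlation(data.frame(rf_tilt_mean = x, director_mean = y))
  mono <- chirality_correlation(data.frame(rf_tilt_mean = exp(x),
                                           director_mean = y^3 + 5 * y))
  expect_equal(base$spearman_r, mono$spearman_r, tolerance = 1e-12)
  tab <- data.frame(rf_tilt_mean = c(x, NA), director_mean = c(y, 1))
  withm <- suppressMessages(chirality_correlation(tab))
  expect_identical(withm$n, 30L)
  expect_equal(withm$pearson_r, base$pearson_r, tolerance = 1e-12)
  expect_error(chirality_correlation(
    data.frame(rf_tilt_mean = c(1, 2), director_mean = c(1, 2))), "at least 3")
})
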