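test_that("a well-formed microculture passes QC; undersized ones fail", {
  fx <- culture15()
  roi <- fx$res$roi
  expect_true(roi$qc_pass)
  expect_gt(roi$coverage, 0.9)
  expect_true(roi$width_um >= 225 && roi$width_um <= 375)
  expect_gt(roi$height_um, 550)
  # a 200-um-wide rectangle fails the width rule
  narrow <- make_microculture(10, width_um = 200, seed = 2, n_nuclei = 60)
  roi_n <- suppressMessages(segment_microculture(narrow$phase))
  expect_false(roi_n$qc_pass)
  expect_match(roi_n$qc_reason, "width")
  # a blank frame has no culture at the centre
  blank <- ImageFrame(matrix(100, 600, 400), 0.5, "phase")
  roi_b <- suppressMessages(segment_microculture(blank))
  expect_false(roi_b$qc_pass)
})

test_that("director windows tile the ROI as window/stride geometry dictates", {
  fx <- culture15()
  df <- fx$res$directors
  # 200x500 um ROI, 60 um window, 70% overlap -> 18 um stride -> 8 x 25
  expect_identical(max(df$ix), 8L)
  expect_identical(max(df$iy), 25L)
  expect_identical(nrow(df), 200L)
})

test_that("pure sinusoidal stripes give per-window angles at the drawn tilt", {
  px <- 0.5
  nr <- 1000; nc <- 500
  rr <- matrix(seq_len(nr), nr, nc); cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  a <- 14 * pi / 180
  u <- ((cc - nc / 2) * cos(a) - (rr - nr / 2) * sin(a)) * px
  frame <- ImageFrame(10000 + 5000 * cos(2 * pi * u / 10), px, "phase")
  df <- director_field(frame, NULL)
  expect_true(all(abs(df$angle_deg - 14) < 1))
  expect_true(all(df$coherence > 0.9))
  al <- alignment(df$angle_deg, "directors")
  expect_true(al$aligned)
  expect_equal(al$mean_angle_deg, 14, tolerance = 0.5)
})

test_that("isotropic noise has near-zero coherence and fails alignment", {
  set.seed(99)
  frame <- ImageFrame(matrix(runif(600 * 300, 0, 1000), 600, 300), 0.5, "phase")
  df <- director_field(frame, NULL)
  expect_lt(mean(df$coherence), 0.2)
  al <- alignment(df$angle_deg, "directors")
  expect_false(al$aligned)
})

test_that("axial statistics behave as the doubled-angle construction requires", {
  r0 <- alignment(c(0, 90), "nuclei")
  expect_equal(r0$mean_resultant_length, 0, tolerance = 1e-12)
  expect_false(r0$aligned)
  r1 <- alignment(c(0, 45), "nuclei")
  expect_equal(r1$mean_resultant_length, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(r1$mean_angle_deg, 22.5, tolerance = 1e-9)
  r2 <- alignment(rep(12, 7), "directors")
  expect_equal(r2$mean_resultant_length, 1, tolerance = 1e-12)
  expect_true(r2$aligned)
  expect_equal(r2$mean_angle_deg, 12, tolerance = 1e-9)
  expect_error(alignment(numeric(0), "nuclei"), "at least one")
  # invariance under adding 180 to any subset
  set.seed(7)
  for (i in 1:20) {
    a <- runif(15, -90, 90)
    flip <- sample(c(0, 180), 15, replace = TRUE)
    x <- alignment(a, "nuclei"); y <- alignment(a + flip, "nuclei")
    expect_equal(x$mean_resultant_length, y$mean_resultant_length,
                 tolerance = 1e-9)
    expect_equal(x$mean_angle_deg, y$mean_angle_deg, tolerance = 1e-9)
  }
})

test_that("an analytically drawn ellipse is measured at its drawn orientation", {
  img <- matrix(0, 400, 400)
  img <- chiralcell:::render_ellipse(img, c(200, 200), 24, 12, 25, 20000,
                                     soft_px = 1.5)
  frame <- ImageFrame(img + 400, 0.5, "nuclei")
  rec <- segment_nuclei(frame, NULL)
  expect_identical(nrow(rec), 1L)
  expect_equal(rec$orientation_deg, 25, tolerance = 1)
  expect_gt(rec$major_px, rec$minor_px)
})

test_that("touching nuclei are split at concave points; specks are removed", {
  img <- matrix(0, 300, 300)
  # dumbbell: two ellipses side by side, overlapping
  img <- chiralcell:::render_ellipse(img, c(150, 138), 22, 13, 0, 20000, 1)
  img <- chiralcell:::render_ellipse(img, c(150, 170), 22, 13, 0, 20000, 1)
  frame <- ImageFrame(img + 400, 0.5, "nuclei")
  rec <- segment_nuclei(frame, NULL)
  expect_identical(nrow(rec), 2L)
  # a sub-500-px speck is removed
  speck <- matrix(0, 300, 300)
  speck <- chiralcell:::render_ellipse(speck, c(150, 150), 8, 5, 0, 20000, 1)
  rec2 <- segment_nuclei(ImageFrame(speck + 400, 0.5, "nuclei"), NULL)
  expect_identical(nrow(rec2), 0L)
})

test_that("nuclei and director readouts of one microculture agree", {
  fx <- culture15()
  res <- fx$res
  expect_gte(res$n_nuclei, 50)
  expect_true(res$nuclei_alignment$aligned)
  expect_true(res$director_alignment$aligned)
  expect_lt(abs(res$director_alignment$mean_angle_deg -
                  res$nuclei_alignment$mean_angle_deg), 3)
  # nuclei orientation recovery against the generator's manifest
  truth_mean <- axial_mean_deg(fx$gen$truth$nuclei$orientation_deg)
  expect_lt(abs(res$nuclei_alignment$mean_angle_deg - truth_mean), 1.5)
})

test_that("condition histograms anchor zero and count sign classes", {
  h <- condition_histogram(c(-7, -2, 4, 9, 14, 16))
  expect_true(0 %in% h$histogram$breaks)
  expect_identical(h$n_negative, 2L)
  expect_identical(h$n_positive, 4L)
  expect_equal(h$mean, mean(c(-7, -2, 4, 9, 14, 16)))
  expect_error(condition_histogram(5), "at least 2")
})

test_that("mirroring the phase image negates the mean nematic angle", {
  g <- make_microculture(14, seed = 3, noise_sd = 0, n_nuclei = 60)
  r1 <- analyze_microculture(g$phase)
  flp <- ImageFrame(g$phase$pixels[, ncol(g$phase$pixels):1], 0.5, "phase")
  r2 <- analyze_microculture(flp)
  expect_equal(r1$director_alignment$mean_angle_deg,
               -r2$director_alignment$mean_angle_deg, tolerance = 0.02)
})
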