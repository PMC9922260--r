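make_disc_frame <- function(area_um2 = 1800, px = 0.138502, size = 512,
                            level = 6000, bg = 300) {
  R <- sqrt(area_um2 / pi) / px
  c0 <- (size + 1) / 2
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  img <- ifelse((rr - c0)^2 + (cc - c0)^2 <= R^2, level, bg)
  ImageFrame(img, px, "actin")
}

test_that("a clean disc segments to its drawn area with a single component", {
  cell <- segment_cell(make_disc_frame(1800))
  expect_s3_class(cell, "CellMask")
  # inflation from blur + fractional-Otsu thresholding stays small
  expect_lt(abs(cell$area_um2 - 1800) / 1800, 0.05)
  lab <- EBImage::bwlabel(cell$mask * 1)
  expect_identical(max(lab), 1L)
  expect_equal(cell$centroid_px, c(256.5, 256.5), tolerance = 0.5)
  # corrected radius follows the area-inflation formula exactly
  expect_equal(cell$R_um, sqrt((cell$area_um2 - 63.353) / pi), tolerance = 1e-12)
})

test_that("an empty image is a segmentation error", {
  expect_error(segment_cell(ImageFrame(matrix(0, 64, 64), 0.138502, "actin")),
               "empty foreground")
  expect_error(segment_cell(ImageFrame(matrix(5, 64, 64), 0.5, "phase")),
               "actin")
})

test_that("the corrected radius for a 1800 um2 cell is ~23.51 um", {
  # closed-form evaluation of R = sqrt((area - 63.353)/pi)
  expect_equal(sqrt((1800 - 63.353) / pi), 23.51, tolerance = 1e-4)
})

test_that("area QC uses inclusive bounds", {
  cfg <- pipeline_config()
  fake <- function(a) structure(list(area_um2 = a), class = "CellMask")
  expect_true(qc_cell_area(fake(1850), cfg))
  expect_true(qc_cell_area(fake(1700), cfg))
  expect_true(qc_cell_area(fake(2000), cfg))
  expect_false(suppressMessages(qc_cell_area(fake(1699.9), cfg)))
  expect_false(suppressMessages(qc_cell_area(fake(2000.1), cfg)))
})

test_that("annuli have the stated boundaries and tile the 18-um rim", {
  cell <- segment_cell(make_disc_frame(1800))
  ann <- build_annuli(cell)
  expect_length(ann, 8)
  expect_equal(vapply(ann, function(a) a$inner_um, numeric(1)),
               seq(0, 14, by = 2))
  expect_equal(vapply(ann, function(a) a$outer_um, numeric(1)),
               seq(4, 18, by = 2))
  expect_equal(ann[[4]]$inner_um, 6)
  expect_equal(ann[[4]]$outer_um, 10)
  # only neighbouring rings overlap (width 4, step 2)
  for (i in 1:8) for (j in 1:8) {
    ov <- any(ann[[i]]$ring_mask & ann[[j]]$ring_mask)
    expect_identical(ov, abs(i - j) <= 1,
                     label = sprintf("overlap between annuli %d and %d", i, j))
  }
  # union of annuli = mask pixels nearer than 18 um to the edge
  u <- Reduce(`|`, lapply(ann, function(a) a$ring_mask))
  d <- attr(ann, "edge_dist_um")
  expect_identical(u, cell$mask & d < 18)
})

test_that("annulus areas match the closed-form ring area within pixelation", {
  cell <- segment_cell(make_disc_frame(1800))
  ann <- build_annuli(cell)
  px2 <- cell$pixel_size_um^2
  R_out <- sqrt(cell$area_um2 / pi)  # uncorrected mask radius
  a0 <- sum(ann[[1]]$ring_mask) * px2
  expect_equal(a0, pi * (R_out^2 - (R_out - 4)^2), tolerance = 0.05)
})

test_that("area and corrected radius are rotation invariant", {
  f <- make_disc_frame(1800)
  cell <- segment_cell(f)
  rot <- ImageFrame(t(f$pixels)[ncol(f$pixels):1, ], f$pixel_size_um, "actin")
  cell_r <- segment_cell(rot)
  expect_lt(abs(cell$area_um2 - cell_r$area_um2) / cell$area_um2, 0.01)
  expect_lt(abs(cell$R_um - cell_r$R_um) / cell$R_um, 0.01)
})
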