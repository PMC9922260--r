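test_that("Niblack thresholding handles flat, two-level and masked inputs", {
  expect_false(any(niblack_binarize(matrix(0.5, 40, 40))))
  expect_false(any(niblack_binarize(matrix(0, 40, 40))))
  # bright bar (0.9) on dark (0.1): bar on, background off
  m <- matrix(0.1, 60, 60); m[, 29:31] <- 0.9
  bin <- niblack_binarize(m)
  expect_true(all(bin[, 30]))
  expect_false(any(bin[, c(1:20, 40:60)]))
  # zeroed (masked) region can never switch on
  m2 <- m; m2[1:30, ] <- 0
  expect_false(any(niblack_binarize(m2)[1:30, ]))
})

test_that("the classical stage favours radial over circumferential fibres", {
  # one radial and one circumferential bar of equal intensity inside a disc
  px <- 0.138502; size <- 512; c0 <- (size + 1) / 2
  R_um <- sqrt(1800 / pi)
  rr <- matrix(seq_len(size), size, size); cc <- t(rr)
  rho_um <- sqrt((rr - c0)^2 + (cc - c0)^2) * px
  img <- 300 + 5700 / (1 + exp((rho_um - R_um) / 0.3))
  # radial bar along +x from r=6 to 20 um; circumferential arc at r=13 um
  for (t_um in seq(6, 20, by = 0.05)) {
    r <- round(c0); c <- round(c0 + t_um / px)
    img[r + (-1:1), c] <- img[r + (-1:1), c] + 24000
  }
  for (a in seq(20, 70, by = 0.05) * pi / 180) {
    r <- round(c0 - 13 / px * sin(a)); c <- round(c0 + 13 / px * cos(a))
    img[r, c + (-1:1)] <- img[r, c + (-1:1)] + 24000
  }
  frame <- ImageFrame(pmin(img, 65535), px, "actin")
  cell <- segment_cell(frame)
  prob <- classical_fibre_probability(frame, cell)
  radial_px <- cbind(round(c0), round(c0 + seq(8, 18, by = 0.2) / px))
  circ_px <- t(vapply(seq(30, 60, by = 1) * pi / 180, function(a)
    c(round(c0 - 13 / px * sin(a)), round(c0 + 13 / px * cos(a))), numeric(2)))
  m_rad <- mean(prob$map[radial_px])
  m_circ <- mean(prob$map[circ_px])
  expect_gt(m_rad, 3 * m_circ)
})

test_that("a constant image yields an all-zero probability map", {
  f <- ImageFrame(matrix(1000, 128, 128), 0.138502, "actin")
  cell <- structure(list(mask = matrix(TRUE, 128, 128),
                         centroid_px = c(64.5, 64.5), area_um2 = 300,
                         R_um = 8, pixel_size_um = 0.138502),
                    class = "CellMask")
  prob <- classical_fibre_probability(f, cell)
  expect_true(all(prob$map == 0))
})

test_that("skeletonisation splits an X into four chains at the branch point", {
  b <- matrix(FALSE, 81, 81)
  for (i in -35:35) {
    b[41 + i, 41 + i] <- TRUE
    b[41 + i, 41 - i] <- TRUE
  }
  chains <- skeletonize_and_split(b)
  expect_length(chains, 4)
  expect_true(all(vapply(chains, nrow, integer(1)) >= 3))
})

test_that("a straight bar yields one chain with matching endpoints", {
  b <- matrix(FALSE, 40, 120); b[19:21, 10:110] <- TRUE
  chains <- skeletonize_and_split(b)
  expect_length(chains, 1)
  ends <- chains[[1]][c(1, nrow(chains[[1]])), ]
  expect_true(all(abs(sort(ends[, 2]) - c(10, 110)) <= 2))
  expect_true(all(abs(ends[, 1] - 20) <= 1))
  # interior chain pixels have exactly two chain neighbours (branch-free)
  pix <- chains[[1]]
  d <- as.matrix(stats::dist(pix))
  nb <- rowSums(d > 0 & d < 1.5)
  expect_true(all(nb[2:(nrow(pix) - 1)] == 2))
  expect_identical(skeletonize_and_split(matrix(FALSE, 20, 20)), list())
})

test_that("segment linking follows the angle, distance and collinearity rules", {
  cfg <- pipeline_config()
  mk <- function(r0, c0, dr, dc, n) cbind(r0 + (0:(n - 1)) * dr,
                                          c0 + (0:(n - 1)) * dc)
  # two collinear chains with a 10 px gap -> one fibre
  ch <- list(mk(50, 10, 0, 1, 30), mk(50, 50, 0, 1, 30))
  expect_length(link_segments(ch, cfg), 1)
  # 40 px apart -> distance test fails -> two fibres
  ch <- list(mk(50, 10, 0, 1, 30), mk(50, 80, 0, 1, 30))
  expect_length(link_segments(ch, cfg), 2)
  # touching at 45 degrees -> angle test fails -> two fibres
  ch <- list(mk(50, 10, 0, 1, 30), mk(51, 41, 1, 1, 30))
  expect_length(link_segments(ch, cfg), 2)
  # parallel but laterally offset (not collinear) -> two fibres
  ch <- list(mk(50, 10, 0, 1, 30), mk(65, 15, 0, 1, 30))
  expect_length(link_segments(ch, cfg), 2)
})

test_that("disjoint drawn fibres come back as exactly that many segments", {
  # radial (tilt 0) fibres are pairwise disjoint for any count up to 30
  for (f in c(6, 14, 22, 30)) {
    g <- make_cell(0, n_fibres = f, noise_sd = 0, seed = f)
    res <- analyze_cell(g$frame)
    expect_identical(length(res$segments), as.integer(f),
                     label = sprintf("segment count for %d fibres", f))
  }
})

test_that("skeletons are invariant under positive intensity rescaling", {
  g <- make_cell(12, seed = 11)
  f1 <- g$frame
  f2 <- ImageFrame(f1$pixels * 0.35, f1$pixel_size_um, "actin")
  cell <- segment_cell(f1)
  b1 <- binarize_fibres(classical_fibre_probability(f1, cell))
  b2 <- binarize_fibres(classical_fibre_probability(f2, segment_cell(f2)))
  expect_gt(sum(b1 & b2) / sum(b1 | b2), 0.98)
})
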