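test_that("the edge projection matches its closed form", {
  # theta = arcsin(r sin(theta_r) / R): independent evaluation
  expect_equal(project_to_edge(30, 10, 20), asin(0.25) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(project_to_edge(30, 10, 20), 14.4775, tolerance = 1e-4)
  # identity at the cell edge
  for (th in c(-60, -15, 0, 30, 67)) {
    expect_equal(project_to_edge(th, 23.5, 23.5), th, tolerance = 1e-9)
  }
  # radial fibres map to zero; sign carries through
  expect_identical(project_to_edge(0, 12, 20), 0)
  expect_equal(sign(project_to_edge(-20, 10, 20)), -1)
  # |theta| <= |theta_r| whenever r <= R
  set.seed(42)
  th <- runif(300, -89, 89); r <- runif(300, 1, 20); R <- r + runif(300, 0, 10)
  expect_true(all(abs(project_to_edge(th, r, R)) <= abs(th) + 1e-12))
  # monotone non-increasing in R at fixed (theta_r, r)
  Rs <- seq(10, 40, by = 1)
  v <- project_to_edge(35, 10, Rs)
  expect_true(all(diff(v) <= 1e-12))
  # the saturated case clamps rather than erroring
  expect_equal(project_to_edge(80, 30, 20), 90)
  expect_error(project_to_edge(10, -1, 20))
})

test_that("the exclusion rule is sign-symmetric with an exclusive 68-degree bound", {
  ms <- data.frame(theta_r_deg = c(68, 67.9, -70, -67.9, 0, 90),
                   r_um = 10, R_um = 23.5, theta_deg = 0, included = NA)
  out <- apply_exclusions(ms)
  expect_identical(out$included, c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("measured chord geometry reproduces the analytic centroid distance", {
  # straight chord at perpendicular distance d: r * sin(theta_r) = d
  g <- make_cell(0, n_fibres = 1, noise_sd = 0, seed = 5)
  cell <- segment_cell(g$frame)
  ann <- build_annuli(cell)
  px <- cell$pixel_size_um
  c0 <- (512 + 1) / 2
  # synthetic straight segment at perpendicular distance 6 um, crossing rings
  d_px <- 6 / px
  rows <- seq(60, 452)
  pix <- cbind(rows, round(c0 + d_px))
  seg <- structure(list(segment_id = 1L, pixels = pix,
                        centre = c(mean(rows), c0 + d_px),
                        dir = c(dx = 0, dyu = 1), angle_deg = 90,
                        length_px = length(rows), n_chains = 1L),
                   class = "FibreSegment")
  edge <- attr(ann, "edge_dist_um")
  for (k in c(1, 3, 5)) {
    m <- measure_theta_r(seg, ann[[k]], cell, edge)
    expect_false(is.null(m))
    d_meas <- m$r_um * sin(abs(deg2rad_test(m$theta_r_deg)))
    expect_equal(d_meas, 6, tolerance = 0.15,
                 label = sprintf("chord distance in annulus %d", k - 1))
  }
})

test_that("radial fibres measure zero tilt; tangential segments are excluded", {
  g <- make_cell(0, n_fibres = 12, noise_sd = 0, seed = 2)
  res <- analyze_cell(g$frame)
  inc <- res$measurements[res$measurements$included, ]
  expect_gt(nrow(inc), 20)
  expect_lt(abs(mean(inc$theta_deg)), 1)
  expect_lt(max(abs(inc$theta_deg)), 5)
  # tangential chain: near-90 local angle, excluded by the 68-degree rule
  cell <- res$cell
  ann <- build_annuli(cell)
  c0 <- (512 + 1) / 2
  r_px <- 16 / cell$pixel_size_um
  ang <- seq(80, 100, by = 0.25) * pi / 180
  pix <- unique(cbind(round(c0 - r_px * sin(ang)), round(c0 + r_px * cos(ang))))
  fit <- chiralcell:::tls_line(pix)
  seg <- structure(list(segment_id = 99L, pixels = pix, centre = fit$centre,
                        dir = fit$dir, angle_deg = fit$angle_deg,
                        length_px = nrow(pix), n_chains = 1L),
                   class = "FibreSegment")
  # measured against its own ring (depth ~8.2 um -> the 8-12 um annulus),
  # the tangential chain's local angle approaches 90 degrees
  ms <- measure_cell_tilts(list(seg), ann, cell)
  own <- ms[ms$annulus == 4, ]
  expect_true(nrow(own) > 0)
  expect_true(all(!own$included))
  expect_true(all(abs(own$theta_r_deg) > 68))
})

test_that("per-cell profiles average included measurements and flag empty annuli", {
  cfg <- pipeline_config()
  ms <- data.frame(cell_id = "c", segment_id = c(1, 2, 3),
                   annulus = c(3, 3, 5),
                   theta_r_deg = c(10, 20, 80), r_um = 10, R_um = 23.5,
                   theta_deg = c(10, 20, 85), included = NA)
  prof <- per_cell_profile(apply_exclusions(ms, cfg), cfg)
  expect_equal(prof$mean_theta_deg[4], 15)
  expect_identical(prof$n[4], 2L)
  # annulus 5 had only an excluded measurement: missing, never 0
  expect_true(is.na(prof$mean_theta_deg[6]))
  expect_equal(prof$report_value, 15)
  cfg2 <- pipeline_config(report_annulus = "8-12")
  expect_true(is.na(per_cell_profile(apply_exclusions(ms, cfg2), cfg2)$report_value))
})

test_that("population profiles aggregate across cells with SEM and histogram", {
  cfg <- pipeline_config()
  mk_prof <- function(v, id) structure(
    list(cell_id = id, mean_theta_deg = rep(v, 8), n = rep(5L, 8),
         report_value = v), class = "CellTiltProfile")
  pop <- population_profile(list(mk_prof(10, "a"), mk_prof(20, "b")), cfg)
  expect_equal(pop$mean[4], 15)
  expect_equal(pop$sem[4], 5)
  expect_identical(pop$n_cells[4], 2L)
  # zero is a histogram bin edge
  expect_true(0 %in% pop$histogram$breaks ||
                all(pop$histogram$breaks %% cfg$hist_bin_deg == 0))
  expect_error(population_profile(list(mk_prof(10, "a")), cfg), "at least 2")
  # degenerate all-zero population
  pop0 <- population_profile(list(mk_prof(0, "a"), mk_prof(0, "b")), cfg)
  expect_true(all(pop0$mean == 0))
  expect_true(all(pop0$sem == 0))
})

test_that("straight-fibre tilt is consistent across annuli (chord property)", {
  res <- cell15()$res
  prof <- res$profile$mean_theta_deg
  expect_true(all(is.finite(prof)))
  expect_lt(diff(range(prof)), 1.5)
})

test_that("mirroring the image negates the tilt profile", {
  fx <- cell15()
  flipped <- ImageFrame(fx$gen$frame$pixels[, ncol(fx$gen$frame$pixels):1],
                        fx$gen$frame$pixel_size_um, "actin")
  res_m <- analyze_cell(flipped)
  expect_equal(res_m$profile$report_value, -fx$res$profile$report_value,
               tolerance = 0.5)
})

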