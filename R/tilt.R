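# Measurement of radial-fibre tilt per annulus, projection to the cell edge,
# exclusion rules and per-cell / population aggregation.
#
# Sign convention: theta_r is the signed acute angle from the outward radial
# vector r (centroid -> annulus-boundary intersection) to the fibre direction,
# positive for an anticlockwise rotation as the image is displayed.  The
# projected edge angle theta keeps the sign of theta_r.

#' Measure a fibre segment's local angle in one annulus
#'
#' The segment's pixel chain is clipped to the annulus ring mask and a
#' total-least-squares line fitted to the clipped pixels.  The continuation of
#' that line is intersected with the annulus outer-edge contour (the
#' iso-distance-from-edge contour at `inner_um`, i.e. the annulus boundary
#' nearer the cell edge; for annulus 0 this is the cell-mask edge itself),
#' choosing the intersection nearest the clipped sub-chain; the r vector runs
#' from the cell centroid to that intersection.  Because the intersection lies
#' on the fitted line, `r * sin(theta_r)` equals the line's perpendicular
#' distance from the centroid, making the projected edge angle independent of
#' the annulus for straight fibres.  If the line never reaches the contour
#' (a degenerate fit) the deepest point of the line is used, which drives
#' `|theta_r|` towards 90 degrees and hence into the exclusion filter.
#'
#' @param segment A `FibreSegment`.
#' @param annulus One annulus from [build_annuli()].
#' @param cell The `CellMask`.
#' @param edge_dist_um Distance-from-edge map (um) as attached to the annuli.
#' @param min_px Minimum clipped sub-chain length in pixels (at least 3; the
#'   default of 7 keeps the fitted direction well away from the 45-degree
#'   quantisation of very short pixel chains).
#' @return List `(theta_r_deg, r_um)`, or `NULL` when the clipped chain is
#'   shorter than `min_px` or the geometry degenerates.
#' @export
measure_theta_r <- function(segment, annulus, cell, edge_dist_um, min_px = 7) {
  px <- cell$pixel_size_um
  pix <- segment$pixels
  # trim the few pixels adjacent to the segment's free ends: skeleton lines
  # hook sideways at their endpoints (thinning end artefact), which would
  # rotate short clipped fits
  proj <- (pix[, 2] - segment$centre[2]) * segment$dir["dx"] -
    (pix[, 1] - segment$centre[1]) * segment$dir["dyu"]
  e1 <- pix[which.min(proj), ]
  e2 <- pix[which.max(proj), ]
  dend <- pmin(sqrt((pix[, 1] - e1[1])^2 + (pix[, 2] - e1[2])^2),
               sqrt((pix[, 1] - e2[1])^2 + (pix[, 2] - e2[2])^2))
  keep <- dend >= 4
  inring <- annulus$ring_mask[cbind(pix[, 1], pix[, 2])] & keep
  if (sum(inring) < max(min_px, 3)) return(NULL)
  sub <- pix[inring, , drop = FALSE]
  fit <- tls_line(sub)
  ctr <- fit$centre
  u <- fit$dir  # (dx, dyu)
  # a meaningful segment angle needs collinear pixels; clips that straddle a
  # fibre crossing (V-shaped pixel sets) have no single orientation
  resid <- (sub[, 2] - ctr[2]) * u["dyu"] + (sub[, 1] - ctr[1]) * u["dx"]
  if (sqrt(mean(resid^2)) > 1.5) return(NULL)
  # sample the line; t in px, positive/negative both directions
  tmax <- 1.5 * max(dim(edge_dist_um))
  ts <- seq(-tmax, tmax, by = 0.25)
  rows <- ctr[1] - ts * u["dyu"]
  cols <- ctr[2] + ts * u["dx"]
  d <- bilinear(edge_dist_um, rows, cols, outside = 0)
  f <- d - annulus$inner_um
  sgn <- f > 0
  cross_idx <- which(sgn[-length(sgn)] != sgn[-1])
  if (length(cross_idx)) {
    # linear interpolation of the crossing parameter, nearest the sub-chain
    tc <- ts[cross_idx] + (ts[cross_idx + 1] - ts[cross_idx]) *
      (0 - f[cross_idx]) / (f[cross_idx + 1] - f[cross_idx])
    tstar <- tc[which.min(abs(tc))]
  } else {
    tstar <- ts[which.max(d)]  # deepest reachable point (near-tangential case)
  }
  p_row <- ctr[1] - tstar * u["dyu"]
  p_col <- ctr[2] + tstar * u["dx"]
  rx <- p_col - cell$centroid_px[2]
  ryu <- -(p_row - cell$centroid_px[1])
  r_px <- sqrt(rx^2 + ryu^2)
  if (r_px < 1e-9) return(NULL)
  # orient the fibre direction outward along r
  if (rx * u["dx"] + ryu * u["dyu"] < 0) u <- -u
  theta_r <- rad2deg(atan2(rx * u["dyu"] - ryu * u["dx"],
                           rx * u["dx"] + ryu * u["dyu"]))
  list(theta_r_deg = unname(theta_r), r_um = unname(r_px * px))
}

#' Project a local fibre angle to the cell edge
#'
#' `theta = sign(theta_r) * arcsin(min(|r * sin(theta_r)| / R, 1))`: the angle
#' the fibre's continuation makes with the cell radius at the cell edge.  For
#' a straight fibre, `r * sin(theta_r)` equals the fibre line's perpendicular
#' distance from the centroid, so theta is independent of the annulus in which
#' it was measured.
#'
#' @param theta_r_deg Signed local angle (degrees).
#' @param r_um Distance from the centroid to the annulus-boundary
#'   intersection (um, > 0).
#' @param R_um Corrected cell radius (um, > 0).
#' @return Projected signed angle in degrees.
#' @export
project_to_edge <- function(theta_r_deg, r_um, R_um) {
  stopifnot(all(r_um > 0), all(R_um > 0))
  arg <- pmin(abs(r_um * sin(deg2rad(theta_r_deg))) / R_um, 1)
  sign(theta_r_deg) * rad2deg(asin(arg))
}

#' Apply the tilt-measurement exclusion rule
#'
#' A measurement is excluded when `|theta_r| >= theta_r_max_deg` (68 degrees:
#' near-tangential segments are unlikely to be radial fibres).  All records
#' are retained with their `included` flag set, for audit.  Note that `r` may
#' slightly exceed the corrected radius `R` in the outermost annulus (where
#' the intersection lies on the cell-mask edge, whose radius the
#' area-inflation correction deliberately shrinks); the projection formula
#' stays valid there because `r * sin(theta_r)` equals the fibre line's
#' perpendicular distance from the centroid, which is below `R` for any
#' segment surviving the 68-degree filter.
#'
#' @param ms Data frame of tilt measurements.
#' @param cfg A [pipeline_config()].
#' @return The same data frame with `included` filled in.
#' @export
apply_exclusions <- function(ms, cfg = pipeline_config()) {
  ms$included <- abs(ms$theta_r_deg) < cfg$theta_r_max_deg
  ms
}

#' Measure all fibre segments of one cell across all annuli
#'
#' @param segments List of `FibreSegment`s.
#' @param annuli Annuli from [build_annuli()].
#' @param cell The `CellMask`.
#' @param cfg A [pipeline_config()].
#' @param cell_id Identifier copied into the records.
#' @return Data frame of `TiltMeasurement` records (`cell_id`, `segment_id`,
#'   `annulus`, `theta_r_deg`, `r_um`, `R_um`, `theta_deg`, `included`).
#' @export
measure_cell_tilts <- function(segments, annuli, cell, cfg = pipeline_config(),
                               cell_id = "cell") {
  edge_dist_um <- attr(annuli, "edge_dist_um")
  rows <- list()
  for (seg in segments) {
    for (ann in annuli) {
      if (ann$empty) next
      m <- measure_theta_r(seg, ann, cell, edge_dist_um, cfg$min_clip_px)
      if (is.null(m)) next
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = cell_id, segment_id = seg$segment_id, annulus = ann$index,
        theta_r_deg = m$theta_r_deg, r_um = m$r_um, R_um = cell$R_um,
        theta_deg = project_to_edge(m$theta_r_deg, m$r_um, cell$R_um),
        included = NA, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(cell_id = character(), segment_id = integer(),
                      annulus = integer(), theta_r_deg = numeric(),
                      r_um = numeric(), R_um = numeric(), theta_deg = numeric(),
                      included = logical(), stringsAsFactors = FALSE))
  }
  apply_exclusions(do.call(rbind, rows), cfg)
}

#' Per-cell tilt profile
#'
#' Arithmetic mean of the projected tilt over included measurements in each
#' annulus; annuli without measurements carry `NA`, never 0.  The report value
#' is the mean in the configured report annulus (6-10 um by default).
#'
#' @param ms Measurements of one cell (from [measure_cell_tilts()]).
#' @param cfg A [pipeline_config()].
#' @param cell_id Identifier (defaults to the one in `ms`).
#' @return A `CellTiltProfile`: list with `cell_id`, `mean_theta_deg`
#'   (length `n_annuli`, NA where empty), `n` per annulus, `report_value`.
#' @export
per_cell_profile <- function(ms, cfg = pipeline_config(), cell_id = NULL) {
  if (is.null(cell_id))
    cell_id <- if (nrow(ms)) ms$cell_id[1] else "cell"
  mt <- rep(NA_real_, cfg$n_annuli)
  n <- integer(cfg$n_annuli)
  inc <- ms[!is.na(ms$included) & ms$included, , drop = FALSE]
  for (i in seq_len(cfg$n_annuli)) {
    v <- inc$theta_deg[inc$annulus == i - 1]
    n[i] <- length(v)
    if (n[i] > 0) mt[i] <- mean(v)
  }
  ri <- report_annulus_index(cfg)
  structure(
    list(cell_id = cell_id, mean_theta_deg = mt, n = n,
         report_value = mt[ri + 1]),
    class = "CellTiltProfile"
  )
}

#' Population tilt profile across cells
#'
#' Across-cell mean and SEM of the per-cell annulus means, plus a
#' zero-anchored histogram (bin width `hist_bin_deg`) of the per-cell report
#' values.  Cells without a report value are dropped from the histogram with
#' a logged count.
#'
#' @param profiles List of `CellTiltProfile`s (>= 2).
#' @param cfg A [pipeline_config()].
#' @param condition Condition label.
#' @return A `PopulationProfile`: list with `condition`, `annulus_mid_um`,
#'   `mean`, `sem`, `n_cells` per annulus, `report_values`, `histogram`.
#' @export
population_profile <- function(profiles, cfg = pipeline_config(),
                               condition = "condition") {
  if (length(profiles) < 2)
    stop("population_profile needs at least 2 cell profiles (SEM undefined)")
  mat <- do.call(rbind, lapply(profiles, function(p) p$mean_theta_deg))
  mean_ann <- apply(mat, 2, function(col) {
    v <- col[is.finite(col)]
    if (length(v)) mean(v) else NA_real_
  })
  sem_ann <- apply(mat, 2, sem)
  n_ann <- apply(mat, 2, function(col) sum(is.finite(col)))
  rv <- vapply(profiles, function(p) p$report_value, numeric(1))
  dropped <- sum(!is.finite(rv))
  if (dropped > 0)
    message(dropped, " cell(s) without a report-annulus value dropped from the histogram")
  rv <- rv[is.finite(rv)]
  hg <- if (length(rv)) hist_zero_anchored(rv, cfg$hist_bin_deg) else NULL
  mids <- (seq_len(cfg$n_annuli) - 1) * cfg$annulus_step_um +
    cfg$annulus_width_um / 2
  structure(
    list(condition = condition, annulus_mid_um = mids, mean = mean_ann,
         sem = sem_ann, n_cells = n_ann, report_values = rv, histogram = hg),
    class = "PopulationProfile"
  )
}

#' Run the full single-cell tilt pipeline on one actin image
#'
#' Segments the cell, applies area QC, produces the fibre probability map
#' (classical ridge stage unless an external map is supplied), binarises,
#' skeletonises, links segments, measures tilts in all annuli and aggregates
#' the per-cell profile.
#'
#' @param actin An [ImageFrame] (actin channel).
#' @param cfg A [pipeline_config()].
#' @param cell_id Identifier for the records.
#' @param fibre_prob Optional `FibreProbability` overriding the classical
#'   stage (e.g. from [fibre_probability_from_map()]).
#' @return List with `cell`, `qc_pass`, `segments`, `measurements`, `profile`
#'   (`measurements`/`profile` are `NULL` when QC fails).
#' @export
analyze_cell <- function(actin, cfg = pipeline_config(), cell_id = "cell",
                         fibre_prob = NULL) {
  cell <- segment_cell(actin, cfg)
  qc <- qc_cell_area(cell, cfg)
  if (!qc)
    return(list(cell = cell, qc_pass = FALSE, segments = NULL,
                measurements = NULL, profile = NULL))
  if (is.null(fibre_prob)) fibre_prob <- classical_fibre_probability(actin, cell)
  bin <- binarize_fibres(fibre_prob, cfg)
  bin[!cell$mask] <- FALSE
  chains <- skeletonize_and_split(bin)
  segments <- link_segments(chains, cfg)
  # the fibre stage identifies radial fibres: discard segments lying
  # essentially along the circumference (the 68-degree rule would exclude
  # all their measurements anyway)
  keep <- vapply(segments, function(s) {
    phi <- rad2deg(atan2(-(s$centre[1] - cell$centroid_px[1]),
                         s$centre[2] - cell$centroid_px[2]))
    axial_diff(s$angle_deg, phi) < 80
  }, logical(1))
  segments <- segments[keep]
  for (i in seq_along(segments)) segments[[i]]$segment_id <- i
  annuli <- build_annuli(cell, cfg)
  ms <- measure_cell_tilts(segments, annuli, cell, cfg, cell_id)
  prof <- per_cell_profile(ms, cfg, cell_id)
  list(cell = cell, qc_pass = TRUE, segments = segments,
       measurements = ms, profile = prof)
}
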