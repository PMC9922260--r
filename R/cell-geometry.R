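# Segmentation of the micropattern-confined cell and construction of the
# concentric annuli in which radial-fibre tilt is measured.

#' Segment a circular micropattern-confined cell from its actin image
#'
#' The actin image is Gaussian-smoothed (sigma `gaussian_sigma_px`), thresholded
#' at `otsu_fraction` times the automatic Otsu threshold, then cleaned by
#' morphological closing (disc radius 3), hole filling and a single erosion
#' (disc radius 1).  The largest connected component is kept.  The corrected
#' cell radius `R_um` subtracts the calibrated segmentation area inflation
#' (`area_inflation_um2`) before converting area to the best-fit circle radius.
#'
#' @param actin An [ImageFrame] with `channel_tag = "actin"`.
#' @param cfg A [pipeline_config()].
#' @return An object of class `CellMask`: list with `mask` (logical matrix),
#'   `centroid_px` (row, col), `area_um2`, `R_um`, `pixel_size_um`.
#' @export
segment_cell <- function(actin, cfg = pipeline_config()) {
  stopifnot(inherits(actin, "ImageFrame"))
  if (actin$channel_tag != "actin")
    stop("segment_cell expects the actin channel")
  px <- actin$pixel_size_um
  v <- norm01(actin$pixels)
  g <- gauss_smooth(v, cfg$gaussian_sigma_px)
  thr <- cfg$otsu_fraction * EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  bw <- g > thr
  if (!any(bw)) stop("cell segmentation failed: empty foreground")
  bw <- im2mat(EBImage::closing(bw * 1, EBImage::makeBrush(7, "disc"))) > 0.5
  bw <- im2mat(EBImage::fillHull(bw * 1)) > 0.5
  bw <- im2mat(EBImage::erode(bw * 1, EBImage::makeBrush(3, "disc"))) > 0.5
  lab <- im2mat(EBImage::bwlabel(bw * 1))
  if (max(lab) == 0) stop("cell segmentation failed: empty foreground")
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  if (any(mask[1, ]) && any(mask[nrow(mask), ]) &&
      any(mask[, 1]) && any(mask[, ncol(mask)]))
    warning("cell mask touches all four image borders (pattern overflow?)")
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  area_um2 <- nrow(idx) * px^2
  R_um <- sqrt(max(area_um2 - cfg$area_inflation_um2, 0) / pi)
  structure(
    list(mask = mask, centroid_px = centroid, area_um2 = area_um2,
         R_um = R_um, pixel_size_um = px),
    class = "CellMask"
  )
}

#' Cell-area quality control
#'
#' @param cell A `CellMask`.
#' @param cfg A [pipeline_config()].
#' @return `TRUE` iff the uncorrected spread area lies within
#'   \[`cell_area_min_um2`, `cell_area_max_um2`\] (inclusive bounds).
#' @export
qc_cell_area <- function(cell, cfg = pipeline_config()) {
  ok <- cell$area_um2 >= cfg$cell_area_min_um2 &&
    cell$area_um2 <= cfg$cell_area_max_um2
  if (!ok)
    message(sprintf("cell area QC failed: %.1f um2 outside [%g, %g]",
                    cell$area_um2, cfg$cell_area_min_um2, cfg$cell_area_max_um2))
  ok
}

#' Concentric annuli at fixed distances from the cell edge
#'
#' Builds `n_annuli` overlapping rings of width `annulus_width_um` starting at
#' the cell edge with `annulus_step_um` increments (default boundaries
#' \[0,4\], \[2,6\], ..., \[14,18\] micrometres).  The distance from the edge is
#' the Euclidean distance transform of the mask interior scaled to
#' micrometres; rings deeper than the cell supports come back as empty masks
#' with `empty = TRUE`.
#'
#' @param cell A `CellMask`.
#' @param cfg A [pipeline_config()].
#' @return List of annuli (each: `index` 0-based, `inner_um`, `outer_um`,
#'   `ring_mask`, `empty`), with the distance map (um) attached as attribute
#'   `edge_dist_um`.
#' @export
build_annuli <- function(cell, cfg = pipeline_config()) {
  stopifnot(inherits(cell, "CellMask"))
  px <- cell$pixel_size_um
  d_um <- im2mat(EBImage::distmap(cell$mask * 1)) * px
  annuli <- vector("list", cfg$n_annuli)
  for (i in seq_len(cfg$n_annuli)) {
    inner <- (i - 1) * cfg$annulus_step_um
    outer <- inner + cfg$annulus_width_um
    ring <- cell$mask & d_um >= inner & d_um < outer
    annuli[[i]] <- list(index = i - 1L, inner_um = inner, outer_um = outer,
                        ring_mask = ring, empty = !any(ring))
  }
  attr(annuli, "edge_dist_um") <- d_um
  annuli
}
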