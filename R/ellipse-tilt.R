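# Stress-fibre tilt of single cells on elliptical micropatterns, measured as
# the dominant orientation of a single whole-mask structure tensor relative
# to the ellipse long axis (vertical by convention).

ellipse_pattern_dims <- function(aspect) {
  switch(aspect,
         "1:2" = c(width_um = 34, height_um = 68),
         "1:3" = c(width_um = 27.5, height_um = 84),
         stop("aspect must be \"1:2\" or \"1:3\""))
}

#' Mean stress-fibre tilt of a cell on an elliptical micropattern
#'
#' An elliptical mask of the pattern's nominal dimensions (1:2 = 34 x 68 um,
#' 1:3 = 27.5 x 84 um), centred on the intensity centroid with its long axis
#' vertical, restricts a single global structure tensor (gradient-energy
#' weighting over all mask pixels).  The mean tilt is the tensor's dominant
#' orientation relative to the long axis, positive anticlockwise as
#' displayed; coherence quantifies how one-sided the orientation
#' distribution is.
#'
#' @param actin An [ImageFrame] (actin channel), long axis vertical.
#' @param aspect `"1:2"` or `"1:3"`.
#' @param cfg A [pipeline_config()].
#' @return An `EllipseCellResult`: list with `aspect`, `mean_tilt_deg`,
#'   `coherence`, `centroid_px`, `n_mask_px`.
#' @export
ellipse_mean_tilt <- function(actin, aspect = c("1:2", "1:3"),
                              cfg = pipeline_config()) {
  aspect <- match.arg(aspect)
  stopifnot(inherits(actin, "ImageFrame"))
  dims <- ellipse_pattern_dims(aspect)
  px <- actin$pixel_size_um
  m <- norm01(actin$pixels)
  nr <- nrow(m); nc <- ncol(m)
  tot <- sum(m)
  if (tot <= 0) stop("empty image")
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  cr <- sum(rows * m) / tot
  cc <- sum(cols * m) / tot
  a_px <- dims[["height_um"]] / 2 / px  # semi-axis along rows (long, vertical)
  b_px <- dims[["width_um"]] / 2 / px
  mask <- ((rows - cr) / a_px)^2 + ((cols - cc) / b_px)^2 <= 1
  g <- gauss_smooth(m, 1)
  gr <- gradients_yup(g)
  sxx <- sum((gr$gx * gr$gx)[mask])
  syy <- sum((gr$gy * gr$gy)[mask])
  sxy <- sum((gr$gx * gr$gy)[mask])
  if (sxx + syy <= 1e-10 * sum(mask))
    stop("zero gradient energy inside the ellipse mask")
  ac <- tensor_angle_coherence(sxx, sxy, syy)
  structure(list(aspect = aspect,
                 mean_tilt_deg = wrap_axial(ac[["angle"]] - 90),
                 coherence = ac[["coherence"]],
                 centroid_px = c(cr, cc), n_mask_px = sum(mask)),
            class = "EllipseCellResult")
}

#' Smoothed stress-fibre tilt time course
#'
#' Per-frame [ellipse_mean_tilt()] followed by a trailing moving average over
#' 4 sequential measurements (output length `n - 3`).  With fewer than 4
#' frames the unsmoothed series is returned with a warning.
#'
#' @param frames List of [ImageFrame]s (time-ordered).
#' @param aspect `"1:2"` or `"1:3"`.
#' @param cfg A [pipeline_config()].
#' @return Data frame with `t` (frame index of the window end), `mean_tilt_deg`.
#' @export
tilt_timecourse <- function(frames, aspect = c("1:2", "1:3"),
                            cfg = pipeline_config()) {
  aspect <- match.arg(aspect)
  raw <- vapply(frames, function(f) ellipse_mean_tilt(f, aspect, cfg)$mean_tilt_deg,
                numeric(1))
  n <- length(raw)
  if (n < 4) {
    warning("fewer than 4 frames: returning the unsmoothed series")
    return(data.frame(t = seq_len(n), mean_tilt_deg = raw))
  }
  sm <- stats::filter(raw, rep(1 / 4, 4), sides = 1)
  data.frame(t = 4:n, mean_tilt_deg = as.numeric(sm[4:n]))
}
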