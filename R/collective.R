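# Collective chirality of rectangular microcultures: culture segmentation and
# QC, nematic director field from phase contrast, nuclei orientation from the
# nuclear stain, and alignment classification by the mean resultant length of
# doubled (axial) angles.
#
# Convention: the rectangle's long axis is the image's vertical axis; all
# orientation angles are reported relative to it, positive anticlockwise as
# displayed, axial in (-90, 90].

#' Segment a rectangular microculture from its phase-contrast image
#'
#' Wiener adaptive denoising (`wiener_culture_px`), local-entropy texture map
#' (`entropy_px` neighbourhood), grayscale opening (`opening_px`), Otsu
#' binarisation, then selection of the segmented component containing the
#' image centre.  The bounding box and its coverage give the QC decision;
#' the region of interest is the centred `roi_um` (200 x 500 um) rectangle.
#'
#' @param phase An [ImageFrame] with `channel_tag = "phase"`.
#' @param cfg A [pipeline_config()].
#' @return A `MicrocultureROI`: list with `mask`, `bbox_px`
#'   (row0, row1, col0, col1), `width_um`, `height_um`, `coverage`, `roi_px`,
#'   `qc_pass`, `qc_reason`, `pixel_size_um`.
#' @export
segment_microculture <- function(phase, cfg = pipeline_config()) {
  stopifnot(inherits(phase, "ImageFrame"))
  if (phase$channel_tag != "phase")
    stop("segment_microculture expects the phase channel")
  px <- phase$pixel_size_um
  v <- norm01(phase$pixels)
  w <- wiener_filter(v, cfg$wiener_culture_px)
  e <- entropy_filter(w, cfg$entropy_px)
  e <- norm01(e)
  o <- im2mat(EBImage::opening(e, EBImage::makeBrush(cfg$opening_px, "disc")))
  thr <- EBImage::otsu(EBImage::Image(norm01(o)), range = c(0, 1))
  bw <- norm01(o) > thr
  lab <- im2mat(EBImage::bwlabel(bw * 1))
  ctr <- round(dim(lab) / 2)
  # majority label over a small central box (robust to local texture holes)
  half <- max(1, round(30 / px))
  box <- lab[max(1, ctr[1] - half):min(nrow(lab), ctr[1] + half),
             max(1, ctr[2] - half):min(ncol(lab), ctr[2] + half)]
  centre_label <- if (any(box > 0)) {
    sizes <- tabulate(lab)
    cand <- unique(box[box > 0])
    cand[which.max(sizes[cand])]  # largest component reaching the centre box
  } else 0L
  fail <- function(reason) {
    message("microculture QC failed: ", reason)
    structure(list(mask = NULL, bbox_px = NULL, width_um = NA_real_,
                   height_um = NA_real_, coverage = NA_real_, roi_px = NULL,
                   qc_pass = FALSE, qc_reason = reason, pixel_size_um = px),
              class = "MicrocultureROI")
  }
  if (centre_label == 0)
    return(fail("no segmented culture at the image centre"))
  mask <- lab == centre_label
  mask <- im2mat(EBImage::fillHull(mask * 1)) > 0.5
  idx <- which(mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  width_um <- (c1 - c0 + 1) * px
  height_um <- (r1 - r0 + 1) * px
  coverage <- nrow(idx) / ((r1 - r0 + 1) * (c1 - c0 + 1))
  reason <- NULL
  if (width_um < cfg$bbox_width_min_um || width_um > cfg$bbox_width_max_um)
    reason <- sprintf("bounding-box width %.0f um outside [%g, %g]",
                      width_um, cfg$bbox_width_min_um, cfg$bbox_width_max_um)
  else if (height_um <= cfg$bbox_height_min_um)
    reason <- sprintf("bounding-box height %.0f um not above %g",
                      height_um, cfg$bbox_height_min_um)
  else if (coverage <= cfg$bbox_cover_min)
    reason <- sprintf("mask covers %.2f of the bounding box (need > %g)",
                      coverage, cfg$bbox_cover_min)
  if (!is.null(reason)) message("microculture QC failed: ", reason)
  # centred ROI within the bounding box
  rw_px <- cfg$roi_um[1] / px   # width (cols)
  rh_px <- cfg$roi_um[2] / px   # height (rows)
  rc <- (r0 + r1) / 2; cc <- (c0 + c1) / 2
  roi <- c(row0 = max(1, round(rc - rh_px / 2)),
           row1 = min(nrow(mask), round(rc + rh_px / 2) - 1),
           col0 = max(1, round(cc - rw_px / 2)),
           col1 = min(ncol(mask), round(cc + rw_px / 2) - 1))
  structure(list(mask = mask, bbox_px = c(r0, r1, c0, c1),
                 width_um = width_um, height_um = height_um,
                 coverage = coverage, roi_px = roi,
                 qc_pass = is.null(reason),
                 qc_reason = if (is.null(reason)) "" else reason,
                 pixel_size_um = px),
            class = "MicrocultureROI")
}

#' Nematic director field of a region of interest
#'
#' Structure-tensor orientation per window: Gaussian-derivative gradients are
#' accumulated over square windows of side `director_window_um` tiling the
#' ROI with `director_overlap` overlap (stride = window x (1 - overlap),
#' placed in micrometre coordinates).  Each window yields the dominant axial
#' orientation relative to the rectangle's long (vertical) axis and the
#' tensor coherence; zero-gradient windows are dropped.
#'
#' @param phase An [ImageFrame] (phase channel).
#' @param roi_px ROI rectangle (row0, row1, col0, col1) from
#'   [segment_microculture()], or `NULL` for the full frame.
#' @param cfg A [pipeline_config()].
#' @return A `DirectorField` data frame: `ix`, `iy` (window grid indices),
#'   `x_um`, `y_um` (window centres within the ROI), `angle_deg`, `coherence`.
#' @export
director_field <- function(phase, roi_px = NULL, cfg = pipeline_config()) {
  stopifnot(inherits(phase, "ImageFrame"))
  px <- phase$pixel_size_um
  m <- phase$pixels
  if (!is.null(roi_px))
    m <- m[roi_px[1]:roi_px[2], roi_px[3]:roi_px[4], drop = FALSE]
  win_um <- cfg$director_window_um
  stride_um <- win_um * (1 - cfg$director_overlap)
  roi_w_um <- ncol(m) * px
  roi_h_um <- nrow(m) * px
  if (roi_w_um < win_um || roi_h_um < win_um)
    stop("ROI smaller than the director window")
  nx <- floor((roi_w_um - win_um) / stride_um) + 1
  ny <- floor((roi_h_um - win_um) / stride_um) + 1
  win_px <- round(win_um / px)
  g <- gauss_smooth(norm01(m), 1)
  gr <- gradients_yup(g)
  # summed-area tables for fast window sums of the tensor components
  sat <- function(z) {
    z <- apply(z, 2, cumsum)
    t(apply(z, 1, cumsum))
  }
  Sxx <- sat(gr$gx * gr$gx); Syy <- sat(gr$gy * gr$gy); Sxy <- sat(gr$gx * gr$gy)
  wsum <- function(S, r0, c0, r1, c1) {
    S[r1, c1] - (if (r0 > 1) S[r0 - 1, c1] else 0) -
      (if (c0 > 1) S[r1, c0 - 1] else 0) +
      (if (r0 > 1 && c0 > 1) S[r0 - 1, c0 - 1] else 0)
  }
  # centre the window grid in the ROI so the tiling is mirror-symmetric
  row_off <- floor((nrow(m) - (round((ny - 1) * stride_um / px) + win_px)) / 2)
  col_off <- floor((ncol(m) - (round((nx - 1) * stride_um / px) + win_px)) / 2)
  out <- vector("list", nx * ny)
  k <- 0
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      r0 <- 1 + max(row_off, 0) + round((iy - 1) * stride_um / px)
      c0 <- 1 + max(col_off, 0) + round((ix - 1) * stride_um / px)
      r1 <- min(nrow(m), r0 + win_px - 1)
      c1 <- min(ncol(m), c0 + win_px - 1)
      sxx <- wsum(Sxx, r0, c0, r1, c1)
      syy <- wsum(Syy, r0, c0, r1, c1)
      sxy <- wsum(Sxy, r0, c0, r1, c1)
      k <- k + 1
      if (sxx + syy <= 1e-12) {
        out[[k]] <- NULL  # zero-gradient window: no orientation
        next
      }
      ac <- tensor_angle_coherence(sxx, sxy, syy)
      out[[k]] <- data.frame(
        ix = ix, iy = iy,
        x_um = (c0 - 1 + win_px / 2) * px,
        y_um = (r0 - 1 + win_px / 2) * px,
        angle_deg = wrap_axial(ac[["angle"]] - 90),  # relative to long axis
        coherence = ac[["coherence"]])
    }
  }
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  class(df) <- c("DirectorField", class(df))
  df
}

#' Axial alignment statistics (mean resultant length)
#'
#' Angles are doubled, averaged as unit vectors, and the mean resultant
#' length `R = |mean(exp(2i theta))|` classifies the sample as aligned
#' against the source-specific cutoff (0.5 for nematic directors, 0.35 for
#' nuclei orientations).  The mean angle is the axial circular mean, in
#' (-90, 90].
#'
#' @param angles_deg Orientation sample in degrees (axial, period 180).
#' @param source `"directors"` or `"nuclei"` (selects the cutoff).
#' @param cfg A [pipeline_config()].
#' @return An `AlignmentResult`: list with `n`, `mean_resultant_length`,
#'   `mean_angle_deg`, `aligned`, `source`, `cutoff`.
#' @export
alignment <- function(angles_deg, source = c("directors", "nuclei"),
                      cfg = pipeline_config()) {
  source <- match.arg(source)
  angles_deg <- angles_deg[is.finite(angles_deg)]
  if (length(angles_deg) == 0) stop("alignment needs at least one angle")
  a2 <- deg2rad(2 * angles_deg)
  C <- mean(cos(a2)); S <- mean(sin(a2))
  mrl <- sqrt(C^2 + S^2)
  mean_angle <- wrap_axial(rad2deg(atan2(S, C)) / 2)
  cutoff <- switch(source, directors = cfg$mrl_cutoff_director,
                   nuclei = cfg$mrl_cutoff_nuclei)
  structure(list(n = length(angles_deg), mean_resultant_length = mrl,
                 mean_angle_deg = mean_angle, aligned = mrl > cutoff,
                 source = source, cutoff = cutoff),
            class = "AlignmentResult")
}

#' Segment nuclei and measure their axial orientations
#'
#' Wiener denoising (`wiener_nuclei_px`), NICK adaptive binarisation
#' (`nick_window_px`, `nick_k`), removal of components above
#' `nucleus_area_max_px` (background regions), concave-point splitting of
#' touching nuclei, size filtering to \[`nucleus_area_min_px`,
#' `nucleus_area_max_px`\], restriction to centroids inside the culture
#' bounding box, and ellipse-fit orientation from second image moments.
#'
#' @param nuclei An [ImageFrame] with `channel_tag = "nuclei"`.
#' @param bbox_px Culture bounding box (row0, row1, col0, col1), or `NULL`
#'   for the whole frame.
#' @param cfg A [pipeline_config()].
#' @return Data frame of `NucleusRecord`s: `row_px`, `col_px`, `area_px`,
#'   `major_px`, `minor_px`, `orientation_deg` (relative to the vertical long
#'   axis, axial).
#' @export
segment_nuclei <- function(nuclei, bbox_px = NULL, cfg = pipeline_config()) {
  stopifnot(inherits(nuclei, "ImageFrame"))
  if (nuclei$channel_tag != "nuclei")
    stop("segment_nuclei expects the nuclei channel")
  v <- norm01(nuclei$pixels)
  w <- wiener_filter(v, cfg$wiener_nuclei_px)
  fg <- nick_binarize(w, cfg$nick_window_px, cfg$nick_k)
  lab <- im2mat(EBImage::bwlabel(fg * 1))
  if (max(lab) == 0) return(empty_nucleus_df())
  sizes <- tabulate(lab)
  # background-sized components cannot be nuclei; drop before splitting
  too_big <- which(sizes > cfg$nucleus_area_max_px)
  keep <- fg & !(lab %in% too_big)
  keep <- split_touching(keep, min_area = cfg$nucleus_area_min_px)
  lab <- im2mat(EBImage::bwlabel(keep * 1))
  if (max(lab) == 0) return(empty_nucleus_df())
  fm <- EBImage::computeFeatures.moment(lab)
  fs <- tabulate(lab)
  # computeFeatures.moment: m.cx along dim1 (rows), m.cy along dim2 (cols);
  # m.theta is the long-axis angle from the vertical (dim1) axis, positive
  # anticlockwise as displayed (verified against analytic ellipses)
  rows_c <- fm[, "m.cx"]; cols_c <- fm[, "m.cy"]
  ok <- fs >= cfg$nucleus_area_min_px & fs <= cfg$nucleus_area_max_px
  if (!is.null(bbox_px))
    ok <- ok & rows_c >= bbox_px[1] & rows_c <= bbox_px[2] &
      cols_c >= bbox_px[3] & cols_c <= bbox_px[4]
  if (!any(ok)) return(empty_nucleus_df())
  major <- fm[ok, "m.majoraxis"]
  ecc <- fm[ok, "m.eccentricity"]
  data.frame(
    row_px = rows_c[ok], col_px = cols_c[ok], area_px = fs[ok],
    major_px = major, minor_px = major * sqrt(pmax(1 - ecc^2, 0)),
    orientation_deg = wrap_axial(rad2deg(fm[ok, "m.theta"])))
}

empty_nucleus_df <- function() {
  data.frame(row_px = numeric(), col_px = numeric(), area_px = numeric(),
             major_px = numeric(), minor_px = numeric(),
             orientation_deg = numeric())
}

# --- concave-point splitting -------------------------------------------------

# Split touching objects in a binary image by cutting between paired concave
# contour points (contour turning opposite the object's winding by more than
# 60 degrees), recursively, one cut per object per pass.
split_touching <- function(binary, min_area = 500, max_depth = 4) {
  b <- binary > 0
  if (max_depth <= 0 || !any(b)) return(b)
  lab <- im2mat(EBImage::bwlabel(b * 1))
  n <- max(lab)
  changed <- FALSE
  for (i in seq_len(n)) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < 2 * min_area) next  # cannot hold two valid objects
    cut <- concave_cut(lab == i)
    if (is.null(cut)) next
    b[cut] <- FALSE
    changed <- TRUE
  }
  if (changed) split_touching(b, min_area, max_depth - 1) else b
}

# find one cut (pixel index matrix) between the two closest concave contour
# points of a single-object mask; NULL when fewer than two concavities
concave_cut <- function(mask, step = 5, min_turn_deg = 60) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask * 1))
  if (length(oc) == 0) return(NULL)
  ct <- oc[[which.max(vapply(oc, nrow, integer(1)))]] + 1  # (row, col), 1-based
  np <- nrow(ct)
  if (np < 4 * step) return(NULL)
  im1 <- ((seq_len(np) - 1 - step) %% np) + 1
  ip1 <- ((seq_len(np) - 1 + step) %% np) + 1
  v1r <- ct[, 1] - ct[im1, 1]; v1c <- ct[, 2] - ct[im1, 2]
  v2r <- ct[ip1, 1] - ct[, 1]; v2c <- ct[ip1, 2] - ct[, 2]
  turn <- rad2deg(atan2(v1r * v2c - v1c * v2r, v1r * v2r + v1c * v2c))
  wind <- sum(turn)  # ~ +-360 depending on contour orientation
  conc <- -sign(wind) * turn  # positive where the contour bends inwards
  cand <- which(conc > min_turn_deg)
  if (length(cand) < 2) return(NULL)
  # local maxima of concavity within runs of consecutive candidates
  runs <- split(cand, cumsum(c(1, diff(cand) > step)))
  peaks <- vapply(runs, function(r) r[which.max(conc[r])], numeric(1))
  if (length(peaks) < 2) return(NULL)
  pr <- ct[peaks, , drop = FALSE]
  dd <- as.matrix(stats::dist(pr))
  diag(dd) <- Inf
  # contour-index separation guard: the pair must not be neighbours
  sep <- outer(peaks, peaks, function(a, b) pmin(abs(a - b), np - abs(a - b)))
  dd[sep <= 2 * step] <- Inf
  if (!any(is.finite(dd))) return(NULL)
  k <- which(dd == min(dd), arr.ind = TRUE)[1, ]
  p1 <- pr[k[1], ]; p2 <- pr[k[2], ]
  nstep <- max(abs(p2 - p1)) + 1
  line_r <- round(seq(p1[1], p2[1], length.out = nstep))
  line_c <- round(seq(p1[2], p2[2], length.out = nstep))
  # thicken the cut by one pixel to break 8-connectivity
  cut <- unique(rbind(
    cbind(line_r, line_c), cbind(line_r + 1, line_c), cbind(line_r - 1, line_c),
    cbind(line_r, line_c + 1), cbind(line_r, line_c - 1)))
  cut <- cut[cut[, 1] >= 1 & cut[, 1] <= nrow(mask) &
               cut[, 2] >= 1 & cut[, 2] <= ncol(mask), , drop = FALSE]
  cut
}

#' Full microculture analysis on a phase/nuclei image pair
#'
#' @param phase,nuclei [ImageFrame]s of the same microculture (same size and
#'   pixel size).
#' @param cfg A [pipeline_config()].
#' @return List with `roi` (`MicrocultureROI`), `directors` (data frame),
#'   `director_alignment`, `nuclei` (data frame), `nuclei_alignment`
#'   (`AlignmentResult`s or `NULL` when unavailable), `n_nuclei`,
#'   `enough_nuclei`.
#' @export
analyze_microculture <- function(phase, nuclei = NULL, cfg = pipeline_config()) {
  roi <- segment_microculture(phase, cfg)
  if (!roi$qc_pass)
    return(list(roi = roi, directors = NULL, director_alignment = NULL,
                nuclei = NULL, nuclei_alignment = NULL, n_nuclei = 0L,
                enough_nuclei = FALSE))
  df <- director_field(phase, roi$roi_px, cfg)
  dal <- alignment(df$angle_deg, "directors", cfg)
  nuc <- NULL; nal <- NULL; n_nuclei <- 0L; enough <- FALSE
  if (!is.null(nuclei)) {
    nuc <- segment_nuclei(nuclei, roi$bbox_px, cfg)
    n_nuclei <- nrow(nuc)
    enough <- n_nuclei >= cfg$min_nuclei
    if (!enough)
      message(sprintf("microculture has %d nuclei (< %d); nuclei readout dropped",
                      n_nuclei, cfg$min_nuclei))
    else nal <- alignment(nuc$orientation_deg, "nuclei", cfg)
  }
  list(roi = roi, directors = df, director_alignment = dal, nuclei = nuc,
       nuclei_alignment = nal, n_nuclei = n_nuclei, enough_nuclei = enough)
}

#' Condition-level histogram of per-microculture mean angles
#'
#' Zero-anchored histogram (bin width `hist_bin_deg`) of the mean angles of
#' aligned microcultures, with mean, SEM and the negative/positive class
#' counts.
#'
#' @param per_culture_means Numeric vector of per-microculture mean angles
#'   (degrees), at least 2 finite values.
#' @param cfg A [pipeline_config()].
#' @return List with `histogram`, `mean`, `sem`, `n`, `n_negative`,
#'   `n_positive`.
#' @export
condition_histogram <- function(per_culture_means, cfg = pipeline_config()) {
  v <- per_culture_means[is.finite(per_culture_means)]
  if (length(v) < 2)
    stop("condition_histogram needs at least 2 aligned microcultures")
  list(histogram = hist_zero_anchored(v, cfg$hist_bin_deg),
       mean = mean(v), sem = sem(v), n = length(v),
       n_negative = sum(v < 0), n_positive = sum(v > 0))
}
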