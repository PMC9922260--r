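# Synthetic image generators with ground-truth manifests.  Every generator is
# a pure function of (parameters, seed): the caller's RNG stream is untouched
# and regeneration with the same arguments reproduces the same output.
#
# Rendering model: curvilinear structures are drawn with an anti-aliased
# Gaussian cross-section (FWHM ~0.5 um, a typical stress-fibre width at this
# resolution) at roughly 4x the cytoplasmic intensity, which itself sits well
# above camera background; Gaussian read noise (and optionally Poisson shot
# noise) is added before quantisation to 16-bit counts.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

# add a Gaussian-profile straight segment to an intensity matrix
# p1, p2: (row, col); sigma_px: cross-section sigma; amp: peak intensity
render_segment <- function(img, p1, p2, sigma_px, amp) {
  mar <- ceiling(4 * sigma_px)
  r0 <- max(1, floor(min(p1[1], p2[1])) - mar)
  r1 <- min(nrow(img), ceiling(max(p1[1], p2[1])) + mar)
  c0 <- max(1, floor(min(p1[2], p2[2])) - mar)
  c1 <- min(ncol(img), ceiling(max(p1[2], p2[2])) + mar)
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  vr <- p2[1] - p1[1]; vc <- p2[2] - p1[2]
  len2 <- vr^2 + vc^2
  t <- if (len2 > 0) pmin(pmax(((rr - p1[1]) * vr + (cc - p1[2]) * vc) / len2, 0), 1) else 0
  dr <- rr - (p1[1] + t * vr)
  dc <- cc - (p1[2] + t * vc)
  img[rows, cols] <- img[rows, cols] + amp * exp(-(dr^2 + dc^2) / (2 * sigma_px^2))
  img
}

# single Gaussian profile over the minimum distance to the whole polyline,
# so overlapping cross-sections of consecutive short segments do not add up
render_polyline <- function(img, pts, sigma_px, amp) {
  mar <- ceiling(4 * sigma_px)
  r0 <- max(1, floor(min(pts[, 1])) - mar); r1 <- min(nrow(img), ceiling(max(pts[, 1])) + mar)
  c0 <- max(1, floor(min(pts[, 2])) - mar); c1 <- min(ncol(img), ceiling(max(pts[, 2])) + mar)
  rows <- r0:r1; cols <- c0:c1
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  d2 <- matrix(Inf, length(rows), length(cols))
  for (i in seq_len(nrow(pts) - 1)) {
    p1 <- pts[i, ]; p2 <- pts[i + 1, ]
    vr <- p2[1] - p1[1]; vc <- p2[2] - p1[2]
    len2 <- vr^2 + vc^2
    t <- if (len2 > 0) pmin(pmax(((rr - p1[1]) * vr + (cc - p1[2]) * vc) / len2, 0), 1) else 0
    d2 <- pmin(d2, (rr - (p1[1] + t * vr))^2 + (cc - (p1[2] + t * vc))^2)
  }
  img[rows, cols] <- img[rows, cols] + amp * exp(-d2 / (2 * sigma_px^2))
  img
}

# bright elliptical outline (phase-contrast halo): Gaussian profile around
# the ellipse boundary; centre (row, col) px, orientation from vertical
render_ellipse_halo <- function(img, centre, a_px, b_px, orient_deg, amp,
                                width_px = 1.5) {
  mar <- ceiling(max(a_px, b_px) + 4 * width_px)
  r0 <- max(1, floor(centre[1]) - mar); r1 <- min(nrow(img), ceiling(centre[1]) + mar)
  c0 <- max(1, floor(centre[2]) - mar); c1 <- min(ncol(img), ceiling(centre[2]) + mar)
  rows <- r0:r1; cols <- c0:c1
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  x <- cc - centre[2]
  yu <- -(rr - centre[1])
  th <- deg2rad(orient_deg)
  la <- x * (-sin(th)) + yu * cos(th)
  sa <- x * cos(th) + yu * sin(th)
  rho <- sqrt((la / a_px)^2 + (sa / b_px)^2)
  mean_ax <- (a_px + b_px) / 2
  img[rows, cols] <- img[rows, cols] +
    amp * exp(-((rho - 1) * mean_ax / width_px)^2)
  img
}

# soft-edged filled ellipse; centre (row, col) px, semi-axes px, orientation in
# degrees anticlockwise-as-displayed from vertical, edge softness in px
render_ellipse <- function(img, centre, a_px, b_px, orient_deg, amp, soft_px = 1.5) {
  mar <- ceiling(max(a_px, b_px) + 4 * soft_px)
  r0 <- max(1, floor(centre[1]) - mar); r1 <- min(nrow(img), ceiling(centre[1]) + mar)
  c0 <- max(1, floor(centre[2]) - mar); c1 <- min(ncol(img), ceiling(centre[2]) + mar)
  rows <- r0:r1; cols <- c0:c1
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  x <- cc - centre[2]
  yu <- -(rr - centre[1])
  th <- deg2rad(orient_deg)
  # long axis = vertical rotated by orient (y-up): (-sin, cos)
  la <- x * (-sin(th)) + yu * cos(th)
  sa <- x * cos(th) + yu * sin(th)
  rho <- sqrt((la / a_px)^2 + (sa / b_px)^2)
  mean_ax <- (a_px + b_px) / 2
  prof <- 1 / (1 + exp((rho - 1) * mean_ax / soft_px))
  img[rows, cols] <- img[rows, cols] + amp * prof
  img
}

finalize_frame <- function(img, noise_sd, seed_used, pixel_size_um, channel_tag,
                           poisson = FALSE) {
  if (poisson) img <- img * 0 + stats::rpois(length(img), pmax(img, 0))
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  img <- round(pmin(pmax(img, 0), 65535))
  ImageFrame(img, pixel_size_um, channel_tag)
}

#' Synthetic single cell on a circular micropattern
#'
#' Renders a soft-edged disc of the given spread area bearing `n_fibres`
#' bright radial fibres, each crossing the disc edge at the signed angle
#' `tilt_deg` to the local radius (positive = anticlockwise as displayed).
#' The `chord` model draws straight chords, for which the edge-projection
#' formula is exact; the `spiral` model draws constant-angle (logarithmic
#' spiral) fibres whose local angle equals `tilt_deg` at every radius.
#' Optional circumferential arcs emulate transverse-fibre clutter.
#'
#' @param tilt_deg Signed ground-truth edge tilt, `|tilt_deg| < 68`.
#' @param n_fibres Number of radial fibres (<= 60).
#' @param fibre_model `"chord"` or `"spiral"`.
#' @param clutter Number of transverse (circumferential) clutter arcs.
#' @param noise_sd Gaussian read-noise SD in counts.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param pixel_size_um Pixel size (um); default the acquisition value.
#' @param size_px Square image side (px).
#' @param area_um2 Pattern area (um^2).
#' @param poisson Add Poisson shot noise as well.
#' @return List with `frame` (an [ImageFrame], actin channel) and `truth`
#'   (a `SyntheticTruth` manifest with per-fibre analytic geometry).
#' @export
make_cell <- function(tilt_deg, n_fibres = 20, fibre_model = c("chord", "spiral"),
                      clutter = 0, noise_sd = 150, seed = 1,
                      pixel_size_um = 0.138502, size_px = 512L,
                      area_um2 = 1800, poisson = FALSE) {
  fibre_model <- match.arg(fibre_model)
  if (abs(tilt_deg) >= 68) stop("|tilt_deg| must be below 68")
  if (n_fibres > 60) stop("more than 60 fibres would merge into a solid ring")
  px <- pixel_size_um
  R_um <- sqrt(area_um2 / pi)
  c0 <- (size_px + 1) / 2
  bg <- 300; body_amp <- 5700; fibre_amp <- 24000
  sigma_f <- 0.5 * FWHM_TO_SIGMA / px
  with_seed(seed, {
    psi <- (seq_len(n_fibres) - 1) * 360 / n_fibres +
      stats::runif(n_fibres, -0.3, 0.3) * 360 / n_fibres
    lens <- stats::runif(n_fibres, 18, 21)
    amps <- stats::runif(n_fibres, 0.85, 1.15) * fibre_amp
    arc_rad <- stats::runif(max(clutter, 1), 0.30, 0.85) * R_um
    arc_ctr <- stats::runif(max(clutter, 1), 0, 360)
    arc_span <- stats::runif(max(clutter, 1), 30, 80)
    # mirror rule: a negative tilt scene is the exact mirror of the positive one
    if (tilt_deg < 0) {
      psi <- 180 - psi
      arc_ctr <- 180 - arc_ctr
    }
    img <- matrix(bg, size_px, size_px)
    # soft-edged cell body
    rr <- matrix(seq_len(size_px), size_px, size_px)
    cc <- t(rr)
    rho_um <- sqrt((rr - c0)^2 + (cc - c0)^2) * px
    img <- img + body_amp / (1 + exp((rho_um - R_um) / 0.3))
    fibres <- vector("list", n_fibres)
    for (i in seq_len(n_fibres)) {
      a <- deg2rad(psi[i])
      rhat <- c(cos(a), sin(a))                       # (x, y-up), um
      if (fibre_model == "chord") {
        tl <- deg2rad(tilt_deg)
        vout <- c(cos(tl) * rhat[1] - sin(tl) * rhat[2],
                  sin(tl) * rhat[1] + cos(tl) * rhat[2])
        e_um <- R_um * rhat
        s_um <- e_um - lens[i] * vout
        to_px <- function(p) c(c0 - p[2] / px, c0 + p[1] / px)  # (row, col)
        img <- render_segment(img, to_px(s_um), to_px(e_um), sigma_f, amps[i])
        fibres[[i]] <- data.frame(
          anchor_angle_deg = psi[i], length_um = lens[i], model = "chord",
          x0_um = s_um[1], y0_um = s_um[2], x1_um = e_um[1], y1_um = e_um[2])
      } else {
        depth <- lens[i] * cos(deg2rad(tilt_deg))
        rs <- seq(R_um, max(R_um - depth, 2), by = -0.25)
        phis <- a + tan(deg2rad(tilt_deg)) * log(rs / R_um)
        pts <- cbind(c0 - rs * sin(phis) / px, c0 + rs * cos(phis) / px)
        img <- render_polyline(img, pts, sigma_f, amps[i])
        fibres[[i]] <- data.frame(
          anchor_angle_deg = psi[i], length_um = lens[i], model = "spiral",
          x0_um = rs[length(rs)] * cos(phis[length(phis)]),
          y0_um = rs[length(rs)] * sin(phis[length(phis)]),
          x1_um = R_um * cos(a), y1_um = R_um * sin(a))
      }
    }
    if (clutter > 0) {
      for (j in seq_len(clutter)) {
        ang <- deg2rad(seq(arc_ctr[j] - arc_span[j] / 2,
                           arc_ctr[j] + arc_span[j] / 2, length.out = 40))
        pts <- cbind(c0 - arc_rad[j] * sin(ang) / px,
                     c0 + arc_rad[j] * cos(ang) / px)
        img <- render_polyline(img, pts, sigma_f, 0.8 * fibre_amp)
      }
    }
    frame <- finalize_frame(img, noise_sd, seed, px, "actin", poisson)
    truth <- structure(list(
      kind = "cell", true_angle_deg = tilt_deg, fibre_model = fibre_model,
      fibres = do.call(rbind, fibres), n_fibres = n_fibres, clutter = clutter,
      radius_um = R_um, area_um2 = area_um2, noise_sd = noise_sd, seed = seed,
      pixel_size_um = px), class = "SyntheticTruth")
    list(frame = frame, truth = truth)
  })
}

#' Synthetic rectangular microculture (phase + nuclei channels)
#'
#' Renders a 300 x 600 um (default) rectangle with its long axis vertical:
#' the phase channel carries an oriented texture (sinusoidal stripes or
#' elongated blobs) at `angle_deg` to the long axis, the nuclei channel a
#' field of soft-edged ellipses whose axial orientations are normally
#' distributed around `angle_deg`.
#'
#' @param angle_deg Signed ground-truth orientation relative to the long
#'   (vertical) axis; `|angle_deg| <= 90`.
#' @param texture `"stripes"`, `"elongated_blobs"` or `"isotropic_blobs"`.
#' @param width_um,height_um Rectangle dimensions (um).
#' @param n_nuclei Number of nuclei to place.
#' @param orient_sd_deg SD of the nuclei orientation distribution (deg).
#' @param noise_sd Gaussian read-noise SD in counts.
#' @param seed Integer seed.
#' @param pixel_size_um Pixel size (um).
#' @return List with `phase`, `nuclei` (both [ImageFrame]s) and `truth`.
#' @export
make_microculture <- function(angle_deg = 15,
                              texture = c("stripes", "elongated_blobs", "isotropic_blobs"),
                              width_um = 300, height_um = 600, n_nuclei = 250,
                              orient_sd_deg = 15, noise_sd = 150, seed = 1,
                              pixel_size_um = 0.5) {
  texture <- match.arg(texture)
  if (abs(angle_deg) > 90) stop("|angle_deg| must be <= 90")
  px <- pixel_size_um
  if (width_um > 1200 || height_um > 1200)
    stop("rectangle larger than frame (max 1200 um per side)")
  nr <- round((height_um + 100) / px)
  nc <- round((width_um + 100) / px)
  rc <- (nr + 1) / 2; cc0 <- (nc + 1) / 2
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  x_um <- (cc - cc0) * px
  yu_um <- -(rr - rc) * px
  soft <- 1.5  # um edge softness
  rect <- 1 / (1 + exp((abs(x_um) - width_um / 2) / soft)) *
    1 / (1 + exp((abs(yu_um) - height_um / 2) / soft))
  s <- if (angle_deg < 0) -1 else 1
  amag <- abs(angle_deg)
  with_seed(seed, {
    # phase channel
    a <- deg2rad(angle_deg)
    phase <- matrix(8000, nr, nc)
    # fine-grained speckle: phase-contrast cell texture is grainy at the
    # organelle scale, which is what the entropy filter keys on
    speckle <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), 1) * 5000
    if (texture == "stripes") {
      u <- x_um * cos(a) + yu_um * sin(a)   # coordinate across the stripes
      phase <- phase + rect * (12000 + 6000 * cos(2 * pi * u / 10) + speckle)
    } else {
      # confluent pseudo-cells drawn as bright boundary halos: phase
      # contrast shows cell outlines as a fine bright network, which is
      # exactly the texture the entropy filter and the structure tensor read
      iso <- texture == "isotropic_blobs"
      cell_area <- if (iso) 115 else 150  # um^2 per pseudo-cell
      nb <- round(width_um * height_um / cell_area * 1.5)
      bx0 <- stats::runif(nb, -width_um / 2 + 5, width_um / 2 - 5)
      by <- stats::runif(nb, -height_um / 2 + 5, height_um / 2 - 5)
      bdev <- stats::rnorm(nb, 0, 5)
      bsize <- stats::runif(nb, 0.8, 1.2)
      bx <- s * bx0
      bang <- if (iso) stats::runif(nb, -90, 90) else s * (amag + bdev)
      al <- if (iso) 6 else 12
      as_ <- if (iso) 6 else 4
      blobs <- matrix(0, nr, nc)
      for (b in seq_len(nb)) {
        blobs <- render_ellipse_halo(blobs, c(rc - by[b] / px, cc0 + bx[b] / px),
                                     al * bsize[b] / px, as_ * bsize[b] / px,
                                     bang[b], 1, width_px = 1.5)
      }
      phase <- phase + rect * (8000 + 9000 * pmin(blobs, 1.5) + speckle)
    }
    phase_frame <- finalize_frame(phase, noise_sd, seed, px, "phase")
    # nuclei channel: rejection-sampled non-crowded ellipse field
    nuc <- matrix(400, nr, nc)
    margin <- 12
    pos <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(pos) < n_nuclei && tries < n_nuclei * 400) {
      tries <- tries + 1
      cand <- c(stats::runif(1, -width_um / 2 + margin, width_um / 2 - margin),
                stats::runif(1, -height_um / 2 + margin, height_um / 2 - margin))
      if (nrow(pos) == 0 ||
          min(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2)) > 16)
        pos <- rbind(pos, cand)
    }
    nk <- nrow(pos)
    devs <- stats::rnorm(nk, 0, orient_sd_deg)
    a_um <- 10 * stats::runif(nk, 0.9, 1.1)
    b_um <- 6 * stats::runif(nk, 0.9, 1.1)
    orient <- wrap_axial(s * (amag + devs))
    xs <- s * pos[, 1]
    for (i in seq_len(nk)) {
      nuc <- render_ellipse(nuc, c(rc - pos[i, 2] / px, cc0 + xs[i] / px),
                            a_um[i] / px, b_um[i] / px, orient[i], 20000,
                            soft_px = 0.08 * (a_um[i] + b_um[i]) / 2 / px)
    }
    nuclei_frame <- finalize_frame(nuc, noise_sd, seed, px, "nuclei")
    truth <- structure(list(
      kind = "microculture", true_angle_deg = angle_deg, texture = texture,
      width_um = width_um, height_um = height_um,
      nuclei = data.frame(x_um = xs, y_um = pos[, 2], a_um = a_um, b_um = b_um,
                          orientation_deg = orient),
      n_nuclei = nk, orient_sd_deg = orient_sd_deg, noise_sd = noise_sd,
      seed = seed, pixel_size_um = px), class = "SyntheticTruth")
    list(phase = phase_frame, nuclei = nuclei_frame, truth = truth)
  })
}

#' Synthetic field of nucleus pairs for the splitting step
#'
#' Places `n_pairs` pairs of soft-edged ellipses on a jittered grid; a stated
#' fraction of the pairs is drawn overlapping (dumbbell profiles), the rest
#' well separated.
#'
#' @param overlap_fraction Fraction of pairs drawn overlapping, in \[0, 0.5).
#' @param n_pairs Number of pairs.
#' @param seed Integer seed.
#' @param pixel_size_um Pixel size (um).
#' @param nucleus_scale Scale factor on the nucleus axes (e.g. to generate
#'   sub-minimum-size specks).
#' @param noise_sd Gaussian read-noise SD in counts.
#' @return List with `frame` (nuclei channel) and `truth` (true object count).
#' @export
make_nuclei_pairs <- function(overlap_fraction = 0.3, n_pairs = 30, seed = 1,
                              pixel_size_um = 0.5, nucleus_scale = 1,
                              noise_sd = 100) {
  if (overlap_fraction < 0 || overlap_fraction >= 0.5)
    stop("overlap_fraction must be in [0, 0.5)")
  px <- pixel_size_um
  ngrid <- ceiling(sqrt(n_pairs))
  spacing <- 80
  side_um <- ngrid * spacing + 40
  nr <- round(side_um / px); nc <- nr
  n_overlap <- round(overlap_fraction * n_pairs)
  with_seed(seed, {
    img <- matrix(400, nr, nc)
    recs <- list()
    for (i in seq_len(n_pairs)) {
      gx <- ((i - 1) %% ngrid) + 0.5
      gy <- ((i - 1) %/% ngrid) + 0.5
      ctr_um <- c(20 + gx * spacing + stats::runif(1, -8, 8),
                  20 + gy * spacing + stats::runif(1, -8, 8))
      w <- deg2rad(stats::runif(1, -90, 90))
      a_um <- 10 * nucleus_scale * stats::runif(2, 0.95, 1.05)
      b_um <- 6 * nucleus_scale * stats::runif(2, 0.95, 1.05)
      overlapping <- i <= n_overlap
      sep_um <- if (overlapping) 1.5 * mean(b_um) else 30
      # offset perpendicular to the shared major axis
      off <- sep_um / 2 * c(cos(w), sin(w))
      for (k in 1:2) {
        p_um <- ctr_um + (if (k == 1) off else -off)
        centre <- c(nr - p_um[2] / px, p_um[1] / px)
        img <- render_ellipse(img, centre, a_um[k] / px, b_um[k] / px,
                              rad2deg(w), 20000,
                              soft_px = 0.08 * (a_um[k] + b_um[k]) / 2 / px)
        recs[[length(recs) + 1]] <- data.frame(
          x_um = p_um[1], y_um = p_um[2], a_um = a_um[k], b_um = b_um[k],
          overlapping = overlapping)
      }
    }
    frame <- finalize_frame(img, noise_sd, seed, px, "nuclei")
    truth <- structure(list(
      kind = "nuclei_field", true_count = as.integer(2 * n_pairs),
      n_overlapping_pairs = n_overlap, records = do.call(rbind, recs),
      nucleus_scale = nucleus_scale, seed = seed, pixel_size_um = px),
      class = "SyntheticTruth")
    list(frame = frame, truth = truth)
  })
}

#' Synthetic single cell on an elliptical micropattern
#'
#' An ellipse of the given aspect (1:2 = 34 x 68 um, 1:3 = 27.5 x 84 um, long
#' axis vertical) filled with parallel bright fibres at `tilt_deg` to the long
#' axis.
#'
#' @param tilt_deg Signed stress-fibre tilt relative to the long axis.
#' @param aspect `"1:2"` or `"1:3"`.
#' @param seed Integer seed.
#' @param noise_sd Gaussian read-noise SD in counts.
#' @param pixel_size_um Pixel size (um).
#' @return List with `frame` (actin channel) and `truth`.
#' @export
make_ellipse_cell <- function(tilt_deg = 6, aspect = c("1:2", "1:3"), seed = 1,
                              noise_sd = 150, pixel_size_um = 0.138502) {
  aspect <- match.arg(aspect)
  dims <- switch(aspect, "1:2" = c(34, 68), "1:3" = c(27.5, 84))
  px <- pixel_size_um
  nr <- round((dims[2] + 12) / px)
  nc <- round((dims[1] + 12) / px)
  rc <- (nr + 1) / 2; cc0 <- (nc + 1) / 2
  with_seed(seed, {
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    x_um <- (cc - cc0) * px
    yu_um <- -(rr - rc) * px
    rho <- sqrt((x_um / (dims[1] / 2))^2 + (yu_um / (dims[2] / 2))^2)
    inside <- 1 / (1 + exp((rho - 1) * mean(dims) / 2 / 0.5))
    a <- deg2rad(tilt_deg)
    u <- x_um * cos(a) + yu_um * sin(a)
    img <- 300 + inside * (8000 + 6000 * cos(2 * pi * u / 3))
    frame <- finalize_frame(img, noise_sd, seed, px, "actin")
    truth <- structure(list(
      kind = "ellipse_cell", true_angle_deg = tilt_deg, aspect = aspect,
      dims_um = dims, noise_sd = noise_sd, seed = seed, pixel_size_um = px),
      class = "SyntheticTruth")
    list(frame = frame, truth = truth)
  })
}

#' Synthetic per-condition chirality summary table
#'
#' Draws condition-level (radial-fibre tilt, nematic director angle) mean
#' pairs from a bivariate normal with population correlation `true_r`,
#' emulating a pooled-experiment summary table.
#'
#' @param n_conditions Number of conditions (>= 5).
#' @param true_r Population correlation, in \[-1, 1\].
#' @param noise SD of additional independent jitter added to both readouts.
#' @param seed Integer seed.
#' @return List with `table` (a `ConditionSummary` data frame) and `truth`.
#' @export
make_condition_table <- function(n_conditions = 35, true_r = 0.8, noise = 0,
                                 seed = 1) {
  if (n_conditions < 5) stop("need at least 5 conditions")
  if (abs(true_r) > 1) stop("true_r must be in [-1, 1]")
  with_seed(seed, {
    sx <- 8; sy <- 9
    Sigma <- matrix(c(sx^2, true_r * sx * sy, true_r * sx * sy, sy^2), 2, 2)
    xy <- MASS::mvrnorm(n_conditions, mu = c(5, 6), Sigma = Sigma)
    if (noise > 0) xy <- xy + stats::rnorm(2 * n_conditions, 0, noise)
    tab <- data.frame(
      condition = sprintf("cond_%02d", seq_len(n_conditions)),
      rf_tilt_mean = xy[, 1],
      rf_tilt_sem = stats::runif(n_conditions, 0.5, 1.5),
      n_cells = sample(50:250, n_conditions, replace = TRUE),
      director_mean = xy[, 2],
      director_sem = stats::runif(n_conditions, 0.5, 1.5),
      n_cultures = sample(100:1500, n_conditions, replace = TRUE),
      stringsAsFactors = FALSE)
    truth <- structure(list(kind = "condition_table", true_r = true_r,
                            noise = noise, seed = seed),
                       class = "SyntheticTruth")
    list(table = tab, truth = truth)
  })
}
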