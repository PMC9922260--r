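# Image-filtering primitives: local thresholds, adaptive denoising, texture
# entropy, rolling-ball background subtraction, ridge response and structure
# tensors.  These operate on plain numeric matrices; EBImage supplies the
# convolution, morphology and distance-transform machinery underneath.

#' Rolling-ball background subtraction
#'
#' The slowly varying background is estimated by a grayscale opening with a
#' disc structuring element of the given radius (the morphological realisation
#' of rolling a ball under the intensity surface) and subtracted.
#'
#' @param m Numeric matrix.
#' @param radius_px Ball radius in pixels.
#' @return Matrix of the same shape, non-negative.
#' @export
rolling_ball_subtract <- function(m, radius_px) {
  brush <- EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
  bg <- im2mat(EBImage::opening(m, brush))
  pmax(m - bg, 0)
}

#' Niblack local thresholding
#'
#' Threshold `T(x) = mu_w(x) + k * sd_w(x) - c` over a square window; a pixel
#' is foreground iff its value exceeds `T`.  The offset `c` is subtracted,
#' so the default `c = -0.01` raises the threshold by 0.01 on the \[0, 1\]
#' scale.  That floor makes the degenerate flat-window case deterministic: a
#' constant image (e.g. an all-zero image after background subtraction, where
#' the local standard deviation vanishes) yields no foreground, and regions
#' zeroed by an upstream mask can never turn on.
#'
#' @param m Numeric matrix on a \[0, 1\] intensity scale.
#' @param window_px Square window size in pixels (odd).
#' @param k Niblack k (default -0.3).
#' @param offset Offset c on the \[0, 1\] scale (default -0.01), subtracted
#'   from the threshold.
#' @return Logical matrix of foreground pixels.
#' @export
niblack_binarize <- function(m, window_px = 15, k = -0.3, offset = -0.01) {
  mu <- box_mean(m, window_px)
  musq <- box_mean(m * m, window_px)
  sdw <- sqrt(pmax(musq - mu * mu, 0))
  thr <- mu + k * sdw - offset
  # zero-valued pixels are never fibre: with negative k a window holding a few
  # bright pixels in an otherwise empty region can push T below zero
  m > thr & m > 0
}

#' NICK local thresholding
#'
#' The published NICK threshold `T = m + k * sqrt((sum(p^2) - m^2) / NP)`
#' computed over a square window; a pixel is foreground iff its value exceeds
#' `T`.
#'
#' @param m Numeric matrix on a \[0, 1\] intensity scale.
#' @param window_px Square window size in pixels (odd).
#' @param k NICK k (default -0.2).
#' @return Logical matrix of foreground pixels.
#' @export
nick_binarize <- function(m, window_px = 51, k = -0.2) {
  np <- window_px^2
  mu <- box_mean(m, window_px)
  sum_sq <- box_mean(m * m, window_px) * np
  thr <- mu + k * sqrt(pmax((sum_sq - mu * mu) / np, 0))
  m > thr
}

#' Adaptive (Wiener) denoising filter
#'
#' Pixel-wise Wiener filter driven by local mean and variance over a square
#' neighbourhood, with the noise power estimated as the mean of the local
#' variances (the classic `wiener2` construction).
#'
#' @param m Numeric matrix.
#' @param window_px Neighbourhood size in pixels.
#' @return Filtered matrix.
#' @export
wiener_filter <- function(m, window_px) {
  mu <- box_mean(m, window_px)
  v <- pmax(box_mean(m * m, window_px) - mu * mu, 0)
  noise <- mean(v)
  gain <- ifelse(v > noise, (v - noise) / v, 0)
  mu + gain * (m - mu)
}

#' Local entropy filter
#'
#' Shannon entropy (bits) of the quantised intensity histogram in a square
#' neighbourhood around each pixel; flat regions score near zero, textured
#' regions high.
#'
#' @param m Numeric matrix.
#' @param window_px Neighbourhood size in pixels (the structural element).
#' @param nbins Number of grey-level bins used for the local histogram.
#' @return Matrix of local entropies.
#' @export
entropy_filter <- function(m, window_px = 3, nbins = 32) {
  q <- pmin(floor(norm01(m) * nbins), nbins - 1)
  H <- matrix(0, nrow(m), ncol(m))
  for (b in 0:(nbins - 1)) {
    p <- box_mean((q == b) * 1, window_px)
    nz <- p > 1e-12
    H[nz] <- H[nz] - p[nz] * log2(p[nz])
  }
  H
}

#' Multi-scale ridge (tubeness) response
#'
#' Bright curvilinear structures are enhanced by the scale-normalised negative
#' principal curvature of the Gaussian-smoothed intensity surface (the most
#' negative eigenvalue of the Hessian), maximised over scales.
#'
#' @param m Numeric matrix.
#' @param scales Gaussian scales (sigma, px) to probe; fibre-width scale.
#' @return Non-negative response matrix.
#' @export
ridge_response <- function(m, scales = c(1, 2, 3)) {
  best <- matrix(0, nrow(m), ncol(m))
  for (s in scales) {
    g <- gauss_smooth(m, s)
    fxx <- shift_mat(g, 0, -1) + shift_mat(g, 0, 1) - 2 * g
    fyy <- shift_mat(g, -1, 0) + shift_mat(g, 1, 0) - 2 * g
    fxy <- (shift_mat(g, -1, -1) + shift_mat(g, 1, 1) -
              shift_mat(g, -1, 1) - shift_mat(g, 1, -1)) / 4
    disc <- sqrt(pmax((fxx - fyy)^2 + 4 * fxy^2, 0))
    lam_min <- ((fxx + fyy) - disc) / 2
    resp <- s^2 * pmax(-lam_min, 0)
    best <- pmax(best, resp)
  }
  best
}

#' Dense structure-tensor orientation field
#'
#' Gaussian-derivative gradients are accumulated into a structure tensor
#' smoothed at `sigma_tensor`; the dominant local orientation (the structure
#' axis, perpendicular to the gradient axis) and the tensor coherence are
#' returned per pixel.  Angles are in degrees, axial in (-90, 90], measured
#' anticlockwise (as displayed) from the image x-axis (columns).
#'
#' @param m Numeric matrix.
#' @param sigma_grad Gaussian scale for the gradient estimate (px).
#' @param sigma_tensor Gaussian scale for tensor averaging (px).
#' @return List with matrices `angle_deg`, `coherence`, and the tensor
#'   components `jxx`, `jxy`, `jyy` (y-up gradient convention).
#' @export
structure_tensor_field <- function(m, sigma_grad = 1, sigma_tensor = 4) {
  g <- gauss_smooth(m, sigma_grad)
  gr <- gradients_yup(g)
  jxx <- gauss_smooth(gr$gx * gr$gx, sigma_tensor)
  jyy <- gauss_smooth(gr$gy * gr$gy, sigma_tensor)
  jxy <- gauss_smooth(gr$gx * gr$gy, sigma_tensor)
  # gradient axis, then +90 deg for the structure axis
  grad_axis <- 0.5 * atan2(2 * jxy, jxx - jyy)
  angle <- wrap_axial(rad2deg(grad_axis) + 90)
  tr <- jxx + jyy
  coh <- ifelse(tr > 0, sqrt((jxx - jyy)^2 + 4 * jxy^2) / tr, 0)
  list(angle_deg = angle, coherence = coh, jxx = jxx, jxy = jxy, jyy = jyy)
}

# structure axis angle (deg, axial, anticlockwise-displayed from the x-axis)
# and coherence from summed tensor components
tensor_angle_coherence <- function(sxx, sxy, syy) {
  grad_axis <- 0.5 * atan2(2 * sxy, sxx - syy)
  angle <- wrap_axial(rad2deg(grad_axis) + 90)
  tr <- sxx + syy
  coh <- if (tr > 0) sqrt((sxx - syy)^2 + 4 * sxy^2) / tr else 0
  c(angle = angle, coherence = coh)
}
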