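# Internal helpers shared across the pipeline.
#
# Angle convention used throughout the package: images are matrices indexed
# [row, col] with row increasing downwards as displayed.  Directions are
# expressed in "y-up" coordinates (x = col, y = -row) so that a positive angle
# is an anticlockwise rotation as the image is displayed.  Orientations are
# axial (period 180 deg) and reported in (-90, 90].

# wrap an angle in degrees to the axial range (-90, 90]
wrap_axial <- function(a) {
  r <- a %% 180
  r[r > 90] <- r[r > 90] - 180
  r
}

deg2rad <- function(a) a * pi / 180
rad2deg <- function(a) a * 180 / pi

# acute (axial) difference between two orientations in degrees, in [0, 90]
axial_diff <- function(a, b) {
  d <- abs(wrap_axial(a - b))
  pmin(d, 180 - d)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random number stream.  All synthetic-data generators go through this so that
# regeneration from (parameters, seed) is reproducible.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# strip EBImage's Image class back down to a plain matrix
im2mat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

# normalised box filter (local mean) with replicated borders; even
# neighbourhood sizes are rounded up to the next odd size (centred window)
box_mean <- function(m, w) {
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  k <- matrix(1 / (w * w), w, w)
  im2mat(EBImage::filter2(m, k, boundary = "replicate"))
}

gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  im2mat(EBImage::gblur(m, sigma = sigma))
}

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# central-difference gradients of a (smoothed) image, returned in y-up
# coordinates: gx along columns, gy along -rows
gradients_yup <- function(m) {
  gx <- (shift_mat(m, 0, -1) - shift_mat(m, 0, 1)) / 2
  gy <- (shift_mat(m, 1, 0) - shift_mat(m, -1, 0)) / 2
  gx[, c(1, ncol(m))] <- 0
  gy[c(1, nrow(m)), ] <- 0
  list(gx = gx, gy = gy)
}

# bilinear interpolation of matrix values at real-valued (row, col) positions;
# positions outside the matrix return `outside`
bilinear <- function(m, row, col, outside = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  out <- rep(outside, length(row))
  if (any(ok)) {
    r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    v00 <- m[cbind(r0k, c0k)]
    v10 <- m[cbind(r0k + 1, c0k)]
    v01 <- m[cbind(r0k, c0k + 1)]
    v11 <- m[cbind(r0k + 1, c0k + 1)]
    out[ok] <- v00 * (1 - frk) * (1 - fck) + v10 * frk * (1 - fck) +
      v01 * (1 - frk) * fck + v11 * frk * fck
  }
  out
}

# rescale to [0, 1]; constant input maps to all zeros
norm01 <- function(m) {
  rng <- range(m, finite = TRUE)
  if (rng[2] <= rng[1]) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

# contrast stretch with a saturated-pixel fraction (total, split between the
# two tails), mirroring the usual brightness/contrast enhancement step
contrast_stretch <- function(m, saturated = 0.0035) {
  q <- stats::quantile(m, c(saturated / 2, 1 - saturated / 2), names = FALSE)
  if (q[2] <= q[1]) return(m * 0)
  pmin(pmax((m - q[1]) / (q[2] - q[1]), 0), 1)
}

# standard error of the mean, NA-safe
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# histogram with a fixed bin width and 0 guaranteed to be a bin edge
hist_zero_anchored <- function(x, bin) {
  x <- x[is.finite(x)]
  lo <- floor(min(x) / bin) * bin
  hi <- ceiling(max(x) / bin) * bin
  if (hi <= lo) hi <- lo + bin
  breaks <- seq(lo, hi, by = bin)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE,
                      include.lowest = TRUE)
  list(breaks = h$breaks, mids = h$mids, counts = h$counts)
}
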