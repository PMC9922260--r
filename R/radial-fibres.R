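# Radial-fibre extraction: a pluggable fibre-probability stage followed by a
# fixed post-processing chain (background subtraction, Niblack binarisation,
# skeletonisation, branch-point removal, segment linking).

#' Classical radial-fibre probability map
#'
#' A desk-scale first stage of the fibre pipeline: a multi-scale ridge
#' (tubeness) response to bright curvilinear structures, weighted by
#' `cos^2` of the axial difference between the local structure-tensor
#' orientation and the radial direction towards the cell centroid, so that
#' circumferential (transverse) fibres are suppressed.  The response is zeroed
#' outside the cell mask and normalised to \[0, 1\].  Alternative sources
#' (an externally produced probability/binary mask, e.g. from a trained
#' segmentation model) can be substituted downstream via [binarize_fibres()].
#'
#' @param actin An [ImageFrame] with `channel_tag = "actin"`.
#' @param cell A `CellMask` from [segment_cell()].
#' @param scales Ridge-filter scales in pixels.
#' @param depth_max_um Support cap: response deeper than this below the cell
#'   edge is zeroed.  The tilt analysis only measures annuli out to 18 um
#'   from the edge; deeper than that the radial fibres end and converge, and
#'   their co-mingling tips carry no radial-fibre signal.
#' @return An object of class `FibreProbability`: list with `map` (matrix in
#'   \[0,1\]) and `source_tag = "classical"`.
#' @export
classical_fibre_probability <- function(actin, cell, scales = c(1, 2, 3),
                                        depth_max_um = 19) {
  stopifnot(inherits(actin, "ImageFrame"), inherits(cell, "CellMask"))
  v <- contrast_stretch(actin$pixels)
  resp <- ridge_response(v, scales)
  st <- structure_tensor_field(v, sigma_grad = 1, sigma_tensor = 3)
  # radial axis per pixel (deg, from the x-axis, anticlockwise as displayed)
  nr <- nrow(v); nc <- ncol(v)
  dx <- matrix(rep(seq_len(nc) - cell$centroid_px[2], each = nr), nr, nc)
  dyu <- matrix(rep(-(seq_len(nr) - cell$centroid_px[1]), nc), nr, nc)
  phi_rad <- rad2deg(atan2(dyu, dx))
  w <- cos(deg2rad(axial_diff(st$angle_deg, phi_rad)))^2
  map <- resp * w
  # support: cell interior minus a thin boundary band, so the cell outline's
  # own intensity step (not a fibre) cannot leak into the response
  support <- im2mat(EBImage::erode(cell$mask * 1, EBImage::makeBrush(23, "disc"))) > 0.5
  d_um <- im2mat(EBImage::distmap(cell$mask * 1)) * cell$pixel_size_um
  map[!support | d_um > depth_max_um] <- 0
  mx <- max(map)
  if (mx > 0) map <- map / mx
  # confidence floor: zero the faint response shoulders flanking bright
  # fibres (and FFT residue in flat regions), which are not fibre evidence
  map[map < 0.01] <- 0
  structure(list(map = map, source_tag = "classical"), class = "FibreProbability")
}

#' Wrap an externally produced fibre-probability or binary mask
#'
#' @param map Numeric matrix (raw response or probabilities), same shape as
#'   the actin frame it belongs to.
#' @param source_tag `"external_mask"` or `"external_model"`.
#' @return A `FibreProbability`.
#' @export
fibre_probability_from_map <- function(map, source_tag = c("external_mask", "external_model")) {
  source_tag <- match.arg(source_tag)
  if (!all(is.finite(map))) stop("fibre probability map must be finite")
  mx <- max(map)
  if (mx > 0) map <- pmax(map, 0) / mx
  structure(list(map = map, source_tag = source_tag), class = "FibreProbability")
}

#' Binarise a fibre-probability map
#'
#' Rolling-ball background subtraction (radius `rollingball_radius_px`)
#' followed by Niblack local thresholding with window `niblack_window_px`,
#' `k = niblack_k` and offset `niblack_offset` on the \[0, 1\] intensity scale.
#'
#' @param prob A `FibreProbability`.
#' @param cfg A [pipeline_config()].
#' @return Logical matrix of fibre foreground.
#' @export
binarize_fibres <- function(prob, cfg = pipeline_config()) {
  stopifnot(inherits(prob, "FibreProbability"))
  m <- rolling_ball_subtract(prob$map, cfg$rollingball_radius_px)
  niblack_binarize(m, cfg$niblack_window_px, cfg$niblack_k, cfg$niblack_offset)
}

# Guo-Hall thinning of a logical matrix to a 1-px skeleton (cleaner on
# diagonal strokes than Zhang-Suen, which braids 45-degree bands)
thin_skeleton <- function(b) {
  b <- (b > 0) * 1
  repeat {
    changed <- FALSE
    for (sub in 0:1) {
      p2 <- shift_mat(b, 1, 0);  p3 <- shift_mat(b, 1, -1)
      p4 <- shift_mat(b, 0, -1); p5 <- shift_mat(b, -1, -1)
      p6 <- shift_mat(b, -1, 0); p7 <- shift_mat(b, -1, 1)
      p8 <- shift_mat(b, 0, 1);  p9 <- shift_mat(b, 1, 1)
      C <- (1 - p2) * pmax(p3, p4) + (1 - p4) * pmax(p5, p6) +
        (1 - p6) * pmax(p7, p8) + (1 - p8) * pmax(p9, p2)
      N1 <- pmax(p9, p2) + pmax(p3, p4) + pmax(p5, p6) + pmax(p7, p8)
      N2 <- pmax(p2, p3) + pmax(p4, p5) + pmax(p6, p7) + pmax(p8, p9)
      N <- pmin(N1, N2)
      m <- if (sub == 0) pmax(p6, p7, 1 - p9) * p8 else pmax(p2, p3, 1 - p5) * p4
      kill <- b == 1 & C == 1 & N >= 2 & N <= 3 & m == 0
      if (any(kill)) {
        b[kill] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  b > 0
}

# count of 8-neighbours for each foreground pixel
neighbour_count <- function(b) {
  m <- b * 1
  shift_mat(m, 1, 0) + shift_mat(m, -1, 0) + shift_mat(m, 0, 1) +
    shift_mat(m, 0, -1) + shift_mat(m, 1, 1) + shift_mat(m, 1, -1) +
    shift_mat(m, -1, 1) + shift_mat(m, -1, -1)
}

# crossing number: 0->1 transitions in the cyclic 8-neighbourhood.  1 for line
# ends, 2 for interior line pixels (including stair steps, which have 3
# neighbours but are not branch points), > 2 at true branches.
transition_count <- function(b) {
  m <- b * 1
  seqs <- list(shift_mat(m, 1, 0), shift_mat(m, 1, -1), shift_mat(m, 0, -1),
               shift_mat(m, -1, -1), shift_mat(m, -1, 0), shift_mat(m, -1, 1),
               shift_mat(m, 0, 1), shift_mat(m, 1, 1), shift_mat(m, 1, 0))
  a <- matrix(0, nrow(b), ncol(b))
  for (i in 1:8) a <- a + (seqs[[i]] == 0 & seqs[[i + 1]] == 1)
  a
}

#' Skeletonise a binary fibre image and split it at branch points
#'
#' Morphological thinning to a 1-px skeleton, removal of branch pixels
#' (more than two skeleton neighbours, iterated until none remain), and
#' tracing of the remaining 8-connected, branch-free chains.  Chains shorter
#' than 3 px and closed loops are dropped.
#'
#' @param binary Logical (or 0/1) matrix.
#' @return List of chains, each an n-by-2 matrix of ordered (row, col) pixels.
#' @export
skeletonize_and_split <- function(binary) {
  b <- binary > 0
  if (!any(b)) return(list())
  sk <- thin_skeleton(b)
  repeat {
    branch <- sk & transition_count(sk) > 2
    if (!any(branch)) break
    sk[branch] <- FALSE
  }
  trace_chains(sk)
}

# trace branch-free skeleton pixels (all with <= 2 neighbours) into ordered
# chains; returns chains of length >= 3
trace_chains <- function(sk) {
  nr <- nrow(sk)
  idx <- which(sk)
  if (!length(idx)) return(list())
  offs <- c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1)
  inset <- logical(length(sk))
  inset[idx] <- TRUE
  visited <- logical(length(sk))
  # neighbour lookup guarded against row wrap-around
  neighbours <- function(i) {
    r <- ((i - 1) %% nr) + 1
    cand <- i + offs
    keep <- rep(TRUE, 8)
    if (r == 1) keep[c(1, 5, 7)] <- FALSE
    if (r == nr) keep[c(2, 6, 8)] <- FALSE
    cand <- cand[keep]
    cand <- cand[cand >= 1 & cand <= length(sk)]
    cand[inset[cand]]
  }
  nnb <- vapply(idx, function(i) length(neighbours(i)), integer(1))
  chains <- list()
  walk <- function(start) {
    path <- integer(0)
    cur <- start
    repeat {
      visited[cur] <<- TRUE
      path <- c(path, cur)
      nxt <- neighbours(cur)
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      cur <- nxt[1]
    }
    path
  }
  for (s in idx[nnb <= 1]) {
    if (visited[s]) next
    path <- walk(s)
    if (length(path) >= 3) chains[[length(chains) + 1]] <- path
  }
  # anything left unvisited sits in closed loops; drop it
  lapply(chains, function(p) {
    cbind(row = ((p - 1) %% nr) + 1, col = ((p - 1) %/% nr) + 1)
  })
}

# total-least-squares line fit of pixel coordinates; returns centre (row, col)
# and a unit direction (dx, dy_up)
tls_line <- function(pix) {
  ctr <- colMeans(pix)
  x <- pix[, 2] - ctr[2]
  yu <- -(pix[, 1] - ctr[1])
  cxx <- mean(x * x); cyy <- mean(yu * yu); cxy <- mean(x * yu)
  # principal axis of the 2x2 covariance
  ang <- 0.5 * atan2(2 * cxy, cxx - cyy)
  list(centre = ctr, dir = c(dx = cos(ang), dyu = sin(ang)),
       angle_deg = wrap_axial(rad2deg(ang)))
}

chain_endpoints <- function(pix) {
  rbind(pix[1, ], pix[nrow(pix), ])
}

# perpendicular distance (px) of a (row, col) point from a tls_line fit
point_line_offset <- function(p, fit) {
  x <- p[2] - fit$centre[2]
  yu <- -(p[1] - fit$centre[1])
  abs(x * fit$dir["dyu"] - yu * fit$dir["dx"])
}

#' Link skeleton chains into fibre segments
#'
#' Two chains are merged when the acute angle between their fitted line
#' directions is at most `link_max_angle_deg` and the minimum
#' endpoint-to-endpoint distance is at most `link_max_dist_px`; merging is
#' transitive.  Each resulting fibre refits a total-least-squares line over
#' all member pixels.
#'
#' Linking reconnects fragments of one fibre broken at branch points, so the
#' two chains must be collinear, not merely parallel and nearby: each chain's
#' centre must lie within a few pixels of the other chain's fitted line.
#' Without this gate, distinct fibres crossing at a shallow angle (or
#' converging tip-to-tip near the cell centre) would be bridged into one
#' spurious segment whose fitted direction belongs to neither fibre.
#'
#' Merged fibres shorter than `cfg$min_segment_px` (projected extent) are
#' discarded: they are below what the tilt measurement can use.
#'
#' @param chains List of pixel chains from [skeletonize_and_split()].
#' @param cfg A [pipeline_config()].
#' @return List of `FibreSegment` objects: `segment_id`, `pixels` (n-by-2),
#'   `centre`, `dir` (unit, y-up), `angle_deg`, `length_px`, `n_chains`.
#' @export
link_segments <- function(chains, cfg = pipeline_config()) {
  n <- length(chains)
  if (n == 0) return(list())
  fits <- lapply(chains, tls_line)
  ends <- lapply(chains, chain_endpoints)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (axial_diff(fits[[i]]$angle_deg, fits[[j]]$angle_deg) >
            cfg$link_max_angle_deg) next
        dd <- sqrt(outer(ends[[i]][, 1], ends[[j]][, 1], "-")^2 +
                     outer(ends[[i]][, 2], ends[[j]][, 2], "-")^2)
        if (min(dd) > cfg$link_max_dist_px) next
        # collinearity gate: centre of each chain close to the other's line
        off_ij <- point_line_offset(fits[[j]]$centre, fits[[i]])
        off_ji <- point_line_offset(fits[[i]]$centre, fits[[j]])
        if (off_ij > 4 || off_ji > 4) next
        parent[find(i)] <- find(j)
      }
    }
  }
  groups <- split(seq_len(n), vapply(seq_len(n), find, integer(1)))
  segs <- vector("list", length(groups))
  min_len <- if (is.null(cfg$min_segment_px)) 0 else cfg$min_segment_px
  for (g in seq_along(groups)) {
    pix <- do.call(rbind, chains[groups[[g]]])
    fit <- tls_line(pix)
    proj <- (pix[, 2] - fit$centre[2]) * fit$dir["dx"] -
      (pix[, 1] - fit$centre[1]) * fit$dir["dyu"]
    len <- diff(range(proj))
    if (len < min_len) next  # stubs too short to carry a measurable angle
    segs[[g]] <- structure(
      list(segment_id = g, pixels = pix, centre = fit$centre, dir = fit$dir,
           angle_deg = fit$angle_deg, length_px = len,
           n_chains = length(groups[[g]])),
      class = "FibreSegment"
    )
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  for (i in seq_along(segs)) segs[[i]]$segment_id <- i
  segs
}
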