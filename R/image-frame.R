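#' Image frame with physical pixel size
#'
#' The universal image container of the pipeline: a 2D non-negative intensity
#' raster together with its isotropic physical pixel size in micrometres and a
#' channel tag identifying what the image shows.
#'
#' @param pixels Numeric matrix of intensities (>= 2 rows and columns, finite,
#'   non-negative). 16-bit camera counts are kept as-is, without rescaling.
#' @param pixel_size_um Physical size of one pixel in micrometres (> 0).
#' @param channel_tag One of `"actin"`, `"phase"`, `"nuclei"`.
#' @return An object of class `ImageFrame`.
#' @export
ImageFrame <- function(pixels, pixel_size_um, channel_tag = c("actin", "phase", "nuclei")) {
  channel_tag <- match.arg(channel_tag)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 2 || ncol(pixels) < 2)
    stop("pixels must have at least 2 rows and 2 columns")
  if (!all(is.finite(pixels)))
    stop("pixel intensities must be finite")
  if (any(pixels < 0))
    stop("pixel intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um, channel_tag = channel_tag),
    class = "ImageFrame"
  )
}

#' @export
print.ImageFrame <- function(x, ...) {
  cat(sprintf("<ImageFrame> %d x %d px, %.6f um/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$channel_tag))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a single-plane grayscale TIFF as an ImageFrame
#'
#' The explicit `pixel_size_um` argument is authoritative; if the file carries
#' resolution metadata that disagrees, a warning is issued and the argument
#' wins. 8/16-bit integer data are preserved without rescaling.
#'
#' @param path Path to a single-plane grayscale TIFF (8- or 16-bit).
#' @param pixel_size_um Physical pixel size in micrometres.
#' @param channel_tag Channel tag for the resulting frame.
#' @return An [ImageFrame].
#' @export
read_image <- function(path, pixel_size_um, channel_tag = c("actin", "phase", "nuclei")) {
  channel_tag <- match.arg(channel_tag)
  if (!file.exists(path)) stop("file not found: ", path)
  planes <- tryCatch(tiff::readTIFF(path, as.is = TRUE, all = TRUE, info = TRUE),
                     error = function(e) stop("unreadable TIFF '", path, "': ",
                                              conditionMessage(e)))
  if (length(planes) != 1)
    stop("multi-plane TIFF '", path, "' needs a channel selector; got ",
         length(planes), " planes")
  img <- planes[[1]]
  if (length(dim(img)) != 2)
    stop("TIFF '", path, "' is not single-channel grayscale (dims: ",
         paste(dim(img), collapse = "x"), ")")
  xres <- attr(img, "x.resolution")
  unit <- attr(img, "resolution.unit")
  if (!is.null(xres) && is.numeric(xres) && xres > 0 && !is.null(unit)) {
    um_per_unit <- switch(as.character(unit), inch = 25400, cm = 10000, NA_real_)
    if (is.finite(um_per_unit)) {
      file_px <- um_per_unit / xres
      if (abs(file_px - pixel_size_um) / pixel_size_um > 1e-4)
        warning(sprintf(
          "TIFF metadata pixel size (%.6f um) differs from argument (%.6f um); using the argument",
          file_px, pixel_size_um))
    }
  }
  storage.mode(img) <- "double"
  ImageFrame(img, pixel_size_um, channel_tag)
}

#' Write an ImageFrame as a 16-bit grayscale TIFF
#'
#' @param frame An [ImageFrame]; intensities are clamped to \[0, 65535\] and
#'   rounded to integers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(frame, path) {
  stopifnot(inherits(frame, "ImageFrame"))
  v <- round(pmin(pmax(frame$pixels, 0), 65535))
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write a homogeneous sequence of records to CSV
#'
#' Angles are stored in degrees and distances in micrometres, one row per
#' record, with a header row.  Values round-trip through [read_records()] at
#' full double precision.
#'
#' @param records A data.frame, or a list of named lists with identical fields.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (length(records) == 0)
      stop("cannot infer columns from an empty list; pass a 0-row data.frame")
    fields <- names(records[[1]])
    ok <- vapply(records, function(r) identical(names(r), fields), logical(1))
    if (!all(ok)) stop("records have heterogeneous fields")
    df <- do.call(rbind, lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    stop("records must be a data.frame or a list of named lists")
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  # format doubles at full precision so that read-back is lossless
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a CSV written by [write_records()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
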