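#' Write a matrix as a single-channel 32-bit float TIFF
#'
#' Stored uncompressed, little-endian, single strip, IEEE-float sample
#' format, so arbitrary (including negative) attenuation and line-integral
#' values round-trip exactly at float precision.  `tiff::readTIFF` reads
#' the format back verbatim; no installed package writes it, hence this
#' minimal writer.
#'
#' @param x numeric matrix (finite values).
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_float_tiff()]
#' @export
write_float_tiff <- function(x, path) {
  check_finite_matrix(x, "matrix")
  con <- file(path, "wb")
  on.exit(close(con))
  w <- ncol(x)
  h <- nrow(x)
  # pixel data in row-major order, immediately after the IFD
  tags <- list(
    c(256L, 3L, 1L, w),          # ImageWidth
    c(257L, 3L, 1L, h),          # ImageLength
    c(258L, 3L, 1L, 32L),        # BitsPerSample
    c(259L, 3L, 1L, 1L),         # Compression: none
    c(262L, 3L, 1L, 1L),         # Photometric: BlackIsZero
    c(273L, 4L, 1L, 0L),         # StripOffsets (patched below)
    c(277L, 3L, 1L, 1L),         # SamplesPerPixel
    c(278L, 3L, 1L, h),          # RowsPerStrip
    c(279L, 4L, 1L, 4L * w * h), # StripByteCounts
    c(339L, 3L, 1L, 3L)          # SampleFormat: IEEE float
  )
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + 12L * length(tags) + 4L
  tags[[6]][4] <- data_offset
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(ifd_offset, con, size = 4L, endian = "little")
  writeBin(length(tags), con, size = 2L, endian = "little")
  for (tg in tags) {
    writeBin(tg[1:2], con, size = 2L, endian = "little")
    writeBin(tg[3], con, size = 4L, endian = "little")
    if (tg[2] == 3L) {  # SHORT value left-justified in the 4-byte slot
      writeBin(c(tg[4], 0L), con, size = 2L, endian = "little")
    } else {
      writeBin(tg[4], con, size = 4L, endian = "little")
    }
  }
  writeBin(0L, con, size = 4L, endian = "little")  # no next IFD
  writeBin(as.numeric(t(x)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a single-channel float TIFF into a matrix
#'
#' Thin wrapper over `tiff::readTIFF` that enforces a single channel and
#' returns a plain numeric matrix.
#'
#' @param path TIFF file path.
#' @return Numeric matrix.
#' @export
read_float_tiff <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  x <- tryCatch(tiff::readTIFF(path), error = function(e)
    stop_io(sprintf("cannot read TIFF %s: %s", path, conditionMessage(e))))
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] != 1L) stop_io(sprintf("%s is not single-channel", path))
    x <- x[, , 1L]
  }
  x
}

#' Write / read scan geometry as YAML
#'
#' Keys mirror the [scan_geometry()] fields (`n_views`, `n_bins`,
#' `bin_spacing`, `n_pixels`, `pixel_spacing`, optionally
#' `angular_range`); lengths in mm, angles in radians with the half
#' rotation implicit when omitted.
#'
#' @param geom a [scan_geometry()].
#' @param path YAML file path.
#' @return `write_geometry` returns `path` invisibly; `read_geometry`
#'   returns a [scan_geometry()].
#' @export
write_geometry <- function(geom, path) {
  check_geometry(geom)
  yaml::write_yaml(unclass(geom), path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  g <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop_io(sprintf("cannot parse geometry %s: %s", path,
                    conditionMessage(e))))
  need <- c("n_views", "n_bins", "bin_spacing", "n_pixels", "pixel_spacing")
  if (!all(need %in% names(g)))
    stop_io(sprintf("geometry %s must define %s", path,
                    paste(need, collapse = ", ")))
  scan_geometry(n_views = g$n_views, n_bins = g$n_bins,
                bin_spacing = g$bin_spacing, n_pixels = g$n_pixels,
                pixel_spacing = g$pixel_spacing,
                angular_range = if (is.null(g$angular_range)) pi else g$angular_range)
}

#' Sinogram and image file I/O with geometry validation
#'
#' Float-TIFF readers/writers that check the array shape against the scan
#' geometry and reject non-finite data, raising classed conditions
#' (`negmar_shape_error`, `negmar_nonfinite_error`, `negmar_io_error`) so
#' callers can distinguish the failure modes.
#'
#' @param path TIFF file path.
#' @param geom a [scan_geometry()], or for the readers a path to a
#'   geometry YAML file.
#' @param s,img matrix to write.
#' @return Readers return the validated matrix; writers return `path`
#'   invisibly.
#' @export
read_sinogram <- function(path, geom) {
  if (is.character(geom)) geom <- read_geometry(geom)
  x <- read_float_tiff(path)
  if (!all(is.finite(x)))
    stop_nonfinite(sprintf("sinogram %s contains non-finite values", path))
  check_sinogram(x, geom, what = sprintf("sinogram %s", path))
  x
}

#' @rdname read_sinogram
#' @export
write_sinogram <- function(s, path, geom) {
  check_sinogram(s, geom)
  write_float_tiff(s, path)
}

#' @rdname read_sinogram
#' @export
read_image <- function(path, geom) {
  if (is.character(geom)) geom <- read_geometry(geom)
  x <- read_float_tiff(path)
  if (!all(is.finite(x)))
    stop_nonfinite(sprintf("image %s contains non-finite values", path))
  check_image(x, geom, what = sprintf("image %s", path))
  x
}

#' @rdname read_sinogram
#' @export
write_image <- function(img, path, geom) {
  check_image(img, geom)
  write_float_tiff(img, path)
}

#' Export a trace mask as an 8-bit TIFF for inspection
#'
#' Flagged entries are written as 255, others as 0.
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_invalid("mask must be a logical matrix")
  tiff::writeTIFF(mask * 1.0, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Quantitative comparison of two reconstructions
#'
#' Reports the figures behind a side-by-side display: maximum absolute
#' and RMS difference between the images, the minimum pixel value and
#' negative-pixel count of each, and - when a ground truth is supplied -
#' RMS error against it inside and outside a region mask (typically the
#' metal support).
#'
#' @param a,b image matrices of matching shape.
#' @param mask optional logical region matrix (e.g. metal support).
#' @param truth optional ground-truth image.
#' @return Named list of scalar metrics.
#' @export
compare_images <- function(a, b, mask = NULL, truth = NULL) {
  check_finite_matrix(a, "a")
  check_finite_matrix(b, "b")
  if (!all(dim(a) == dim(b)))
    stop_shape("a and b must have identical dimensions")
  d <- a - b
  out <- list(
    max_abs_diff = max(abs(d)),
    rms_diff = sqrt(mean(d^2)),
    min_a = min(a), min_b = min(b),
    n_negative_a = sum(a < 0), n_negative_b = sum(b < 0)
  )
  if (!is.null(truth)) {
    check_finite_matrix(truth, "truth")
    if (!all(dim(truth) == dim(a)))
      stop_shape("truth must match the image dimensions")
    rms <- function(x) if (length(x)) sqrt(mean(x^2)) else NA_real_
    out$rms_truth_a <- rms(a - truth)
    out$rms_truth_b <- rms(b - truth)
    if (!is.null(mask)) {
      if (!is.logical(mask) || !all(dim(mask) == dim(a)))
        stop_shape("mask must be a logical matrix matching the images")
      out$rms_truth_a_inside <- rms((a - truth)[mask])
      out$rms_truth_b_inside <- rms((b - truth)[mask])
      out$rms_truth_a_outside <- rms((a - truth)[!mask])
      out$rms_truth_b_outside <- rms((b - truth)[!mask])
    }
  }
  out
}
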