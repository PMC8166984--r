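#' Parallel-beam scan geometry
#'
#' Describes a parallel-beam acquisition over a half rotation together with
#' the square reconstruction grid.  View `i` (0-based) is acquired at angle
#' `i * angular_range / n_views`, i.e. angles sample the half-open interval
#' `[0, pi)`.  Detector bins are centered on the rotation axis: bin `b`
#' (0-based) sits at signed offset `(b - (n_bins - 1) / 2) * bin_spacing`
#' millimetres.  The image origin is at the grid center, with x increasing
#' along columns and y increasing up the rows.
#'
#' @param n_views number of projection angles (>= 1).
#' @param n_bins detector bins per view (>= 1).
#' @param bin_spacing detector sample pitch in mm (> 0).
#' @param n_pixels image side length in pixels.
#' @param pixel_spacing image sample pitch in mm (> 0).
#' @param angular_range angular span in radians; fixed at `pi` for this tool.
#' @return An object of class `scan_geometry`.
#' @examples
#' geom <- scan_geometry(n_views = 90, n_bins = 128, bin_spacing = 1,
#'                       n_pixels = 96, pixel_spacing = 1)
#' geom
#' @export
scan_geometry <- function(n_views, n_bins, bin_spacing, n_pixels,
                          pixel_spacing, angular_range = pi) {
  n_views <- as.integer(n_views)
  n_bins <- as.integer(n_bins)
  n_pixels <- as.integer(n_pixels)
  if (is.na(n_views) || n_views < 1L) stop_invalid("n_views must be >= 1")
  if (is.na(n_bins) || n_bins < 1L) stop_invalid("n_bins must be >= 1")
  if (is.na(n_pixels) || n_pixels < 1L) stop_invalid("n_pixels must be >= 1")
  if (!is.finite(bin_spacing) || bin_spacing <= 0)
    stop_invalid("bin_spacing must be > 0")
  if (!is.finite(pixel_spacing) || pixel_spacing <= 0)
    stop_invalid("pixel_spacing must be > 0")
  if (!is.finite(angular_range) || angular_range <= 0)
    stop_invalid("angular_range must be > 0")
  structure(
    list(n_views = n_views, angular_range = angular_range, n_bins = n_bins,
         bin_spacing = bin_spacing, n_pixels = n_pixels,
         pixel_spacing = pixel_spacing),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("<scan_geometry>\n")
  cat(sprintf("  views : %d over %.1f deg\n", x$n_views,
              x$angular_range * 180 / pi))
  cat(sprintf("  bins  : %d x %.4g mm\n", x$n_bins, x$bin_spacing))
  cat(sprintf("  image : %d x %d px, %.4g mm\n", x$n_pixels, x$n_pixels,
              x$pixel_spacing))
  invisible(x)
}

#' Named scan-geometry presets
#'
#' `"paper"` is the scaled-down airport-bag geometry: 180 views over 180
#' degrees, 597 detector bins of 0.92 mm, reconstructed on a 420 x 420 grid
#' with 0.92 mm pixels (475 mm field of view).  `"test"` is a proportionally
#' reduced geometry (90 views, 128 bins, 96 pixels, 1 mm sampling) sized for
#' fast exercises and continuous testing.
#'
#' @param name `"paper"` or `"test"`.
#' @return A [scan_geometry()].
#' @export
geometry_preset <- function(name = c("paper", "test")) {
  name <- match.arg(name)
  switch(name,
    paper = scan_geometry(n_views = 180L, n_bins = 597L, bin_spacing = 0.92,
                          n_pixels = 420L, pixel_spacing = 0.92),
    test = scan_geometry(n_views = 90L, n_bins = 128L, bin_spacing = 1,
                         n_pixels = 96L, pixel_spacing = 1)
  )
}

is_scan_geometry <- function(x) inherits(x, "scan_geometry")

check_geometry <- function(geom) {
  if (!is_scan_geometry(geom))
    stop_invalid("geom must be a scan_geometry object")
  invisible(geom)
}

check_sinogram <- function(s, geom, what = "sinogram") {
  check_geometry(geom)
  check_finite_matrix(s, what)
  if (nrow(s) != geom$n_views || ncol(s) != geom$n_bins)
    stop_shape(sprintf("%s is %d x %d but geometry expects %d views x %d bins",
                       what, nrow(s), ncol(s), geom$n_views, geom$n_bins))
  invisible(s)
}

check_image <- function(img, geom, what = "image") {
  check_geometry(geom)
  check_finite_matrix(img, what)
  if (nrow(img) != geom$n_pixels || ncol(img) != geom$n_pixels)
    stop_shape(sprintf("%s is %d x %d but geometry expects %d x %d pixels",
                       what, nrow(img), ncol(img), geom$n_pixels,
                       geom$n_pixels))
  invisible(img)
}

# Physical pixel-center coordinates (mm), in column-major vector order
# matching as.vector(img): row index fastest, y decreasing down the rows.
# `inside` flags the reconstruction support: the inscribed field-of-view
# circle, the only region the detector covers at every view angle.
pixel_coords <- function(geom) {
  np <- geom$n_pixels
  cent <- (np - 1) / 2
  idx <- seq_len(np) - 1
  x <- rep((idx - cent) * geom$pixel_spacing, each = np)
  y <- rep((cent - idx) * geom$pixel_spacing, times = np)
  list(x = x, y = y,
       inside = x^2 + y^2 <= (np * geom$pixel_spacing / 2)^2)
}

view_angles <- function(geom) {
  (seq_len(geom$n_views) - 1) * geom$angular_range / geom$n_views
}
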