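#' Exact band-limited ramp (Ram-Lak) convolution kernel
#'
#' Spatial-domain taps of the discrete ramp reconstruction filter at unit
#' sample spacing, indexed by lag `n` in `-(n_bins - 1) .. (n_bins - 1)`:
#' `1/4` at `n = 0`, `-1 / (n pi)^2` at odd `n`, and `0` at even nonzero
#' `n`.  Physical detector-pitch scaling is applied at filtration time by
#' [ramp_filter()], not here.
#'
#' @param n_bins number of detector bins the kernel will be convolved
#'   against (>= 1).
#' @return A `ramp_kernel`: numeric vector of `2 * n_bins - 1` taps with a
#'   `lags` attribute.
#' @examples
#' k <- make_ramp_kernel(4)
#' k[attr(k, "lags") == 0]   # 0.25
#' k[attr(k, "lags") == 1]   # -1/pi^2
#' @export
make_ramp_kernel <- function(n_bins) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop_invalid("n_bins must be >= 1")
  lags <- seq.int(-(n_bins - 1L), n_bins - 1L)
  taps <- numeric(length(lags))
  taps[lags == 0L] <- 1 / 4
  odd <- lags %% 2L != 0L
  taps[odd] <- -1 / (lags[odd] * pi)^2
  structure(taps, lags = lags, class = "ramp_kernel")
}

# Symmetric Toeplitz matrix H[b, j] = h(b - j); same-size convolution with
# zero extension beyond the detector is then s %*% H.
ramp_toeplitz <- function(n_bins) {
  k <- make_ramp_kernel(n_bins)
  lags <- attr(k, "lags")
  stats::toeplitz(as.numeric(k[lags >= 0L]))
}

#' Ramp-filter every view of a sinogram
#'
#' Convolves each detector row with the exact kernel from
#' [make_ramp_kernel()] (full kernel, same-size output, zero extension
#' beyond the detector ends) and scales by `1 / bin_spacing^2` so that the
#' filtered views carry the physical units expected by [backproject()].
#' Linear in its input.
#'
#' @param s sinogram matrix, `n_views` x `n_bins`.
#' @param geom a [scan_geometry()].
#' @return Filtered sinogram of the same shape.
#' @export
ramp_filter <- function(s, geom) {
  check_sinogram(s, geom)
  H <- ramp_toeplitz(geom$n_bins)
  (s %*% H) / geom$bin_spacing^2
}

#' Parallel-beam forward projection (discrete Radon transform)
#'
#' Pixel-driven projector: for each view, every pixel center maps to a
#' continuous detector coordinate and its value (weighted by
#' `pixel_spacing`) is split linearly between the two nearest bins.  Rays
#' beyond the detector extent receive nothing, and pixels outside the
#' reconstruction support - the inscribed field-of-view circle, the only
#' region the detector covers at every angle - contribute nothing (the
#' usual parallel-beam convention, e.g. scikit-image's `circle = TRUE`).
#' The discretization is the exact transpose of [backproject()] up to
#' that function's view-angle quadrature weight, which is what the
#' subgradient of the negativity objective presumes.
#'
#' @param img image matrix, `n_pixels` x `n_pixels`.
#' @param geom a [scan_geometry()].
#' @return Sinogram matrix, `n_views` x `n_bins`, of line-integral values
#'   (attenuation times length, dimensionless).
#' @export
forward_project <- function(img, geom) {
  check_image(img, geom)
  nb <- geom$n_bins
  pc <- pixel_coords(geom)
  vals <- as.vector(img) * geom$pixel_spacing
  nz <- vals != 0 & pc$inside
  sino <- matrix(0, geom$n_views, nb)
  if (!any(nz)) return(sino)
  x <- pc$x[nz]; y <- pc$y[nz]; vals <- vals[nz]
  angles <- view_angles(geom)
  half <- (nb - 1) / 2
  for (vi in seq_len(geom$n_views)) {
    u <- (x * cos(angles[vi]) + y * sin(angles[vi])) / geom$bin_spacing + half
    i0 <- floor(u)
    f <- u - i0
    bins <- c(i0, i0 + 1) + 1  # 1-based target bins
    w <- c(vals * (1 - f), vals * f)
    ok <- bins >= 1 & bins <= nb & w != 0
    if (any(ok)) {
      acc <- rowsum(w[ok], bins[ok])
      sino[vi, as.integer(rownames(acc))] <- acc
    }
  }
  sino
}

#' Unweighted adjoint backprojection
#'
#' The exact transpose of [forward_project()] (gather with linear
#' interpolation between detector bins, weighted by `pixel_spacing`),
#' scaled by `angular_range / n_views` - the view-angle quadrature weight
#' that makes [fbp()] quantitatively correct.  Pixels outside the
#' inscribed field-of-view circle stay exactly zero, mirroring the
#' forward projector's support.
#'
#' @inheritParams ramp_filter
#' @return Image matrix, `n_pixels` x `n_pixels`.
#' @export
backproject <- function(s, geom) {
  check_sinogram(s, geom)
  nb <- geom$n_bins
  pc <- pixel_coords(geom)
  angles <- view_angles(geom)
  half <- (nb - 1) / 2
  x <- pc$x[pc$inside]
  y <- pc$y[pc$inside]
  acc <- numeric(sum(pc$inside))
  for (vi in seq_len(geom$n_views)) {
    u <- (x * cos(angles[vi]) + y * sin(angles[vi])) / geom$bin_spacing + half
    i0 <- floor(u)
    f <- u - i0
    row <- c(s[vi, ], 0)  # sentinel: out-of-range bins contribute zero
    b1 <- i0 + 1
    b2 <- i0 + 2
    b1[b1 < 1 | b1 > nb] <- nb + 1L
    b2[b2 < 1 | b2 > nb] <- nb + 1L
    acc <- acc + (1 - f) * row[b1] + f * row[b2]
  }
  out <- numeric(geom$n_pixels^2)
  out[pc$inside] <- acc * geom$pixel_spacing * geom$angular_range / geom$n_views
  matrix(out, geom$n_pixels, geom$n_pixels)
}

#' Filtered backprojection reconstruction (the operator A)
#'
#' `fbp(s) = backproject(ramp_filter(s))`.  Linear in the sinogram.
#'
#' @inheritParams ramp_filter
#' @return Reconstructed image, `n_pixels` x `n_pixels`, in 1/mm.  Values
#'   may be negative; negative values near metal are exactly the artifact
#'   the optimizer in [run_mar()] targets.
#' @export
fbp <- function(s, geom) {
  backproject(ramp_filter(s, geom), geom)
}

#' Adjoint of the FBP operator
#'
#' Forward projection followed by ramp filtration, carrying the same
#' view-angle quadrature weight as [backproject()] so that
#' `sum(fbp(s) * x) == sum(s * fbp_adjoint(x))` holds to rounding error.
#' This is the operator that turns the image-domain negativity residual
#' into a sinogram-domain gradient.
#'
#' @inheritParams forward_project
#' @return Sinogram matrix, `n_views` x `n_bins`.
#' @export
fbp_adjoint <- function(img, geom) {
  ramp_filter(forward_project(img, geom), geom) *
    (geom$angular_range / geom$n_views)
}
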