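# Shared fixtures and independent oracles, all built in code.

tiny_geom <- function() {
  scan_geometry(n_views = 12, n_bins = 24, bin_spacing = 1,
                n_pixels = 16, pixel_spacing = 1)
}

# Dense operator matrices assembled column by column from basis vectors;
# the brute-force oracle for every adjoint/transpose check.
dense_forward <- function(geom) {
  n <- geom$n_pixels^2
  m <- geom$n_views * geom$n_bins
  A <- matrix(0, m, n)
  for (j in seq_len(n)) {
    e <- matrix(0, geom$n_pixels, geom$n_pixels)
    e[j] <- 1
    A[, j] <- as.vector(forward_project(e, geom))
  }
  A
}

dense_backproject <- function(geom) {
  n <- geom$n_pixels^2
  m <- geom$n_views * geom$n_bins
  B <- matrix(0, n, m)
  for (j in seq_len(m)) {
    s <- matrix(0, geom$n_views, geom$n_bins)
    s[j] <- 1
    B[, j] <- as.vector(backproject(s, geom))
  }
  B
}

# Closed-form Radon transform of a centered disk: 2 mu sqrt(r^2 - t^2).
disk_sinogram <- function(geom, radius, mu) {
  t_off <- (seq_len(geom$n_bins) - 1 - (geom$n_bins - 1) / 2) * geom$bin_spacing
  row <- ifelse(abs(t_off) < radius,
                2 * mu * sqrt(pmax(radius^2 - t_off^2, 0)), 0)
  matrix(rep(row, each = geom$n_views), geom$n_views, geom$n_bins)
}

detector_offsets <- function(geom) {
  (seq_len(geom$n_bins) - 1 - (geom$n_bins - 1) / 2) * geom$bin_spacing
}

grid_radii <- function(geom) {
  pc_x <- rep((seq_len(geom$n_pixels) - 1 - (geom$n_pixels - 1) / 2) *
                geom$pixel_spacing, each = geom$n_pixels)
  pc_y <- rep(((geom$n_pixels - 1) / 2 - (seq_len(geom$n_pixels) - 1)) *
                geom$pixel_spacing, times = geom$n_pixels)
  matrix(sqrt(pc_x^2 + pc_y^2), geom$n_pixels, geom$n_pixels)
}

# A sinogram whose FBP is nonnegative everywhere: a generous uniform disk
# pedestal raises the band-limit ripple of a smooth blob above zero.
# Verified nonnegative at build time so fixed-point tests cannot silently
# run on the wrong premise.
nonneg_fbp_sinogram <- function(geom) {
  r <- grid_radii(geom)
  fov <- geom$n_pixels * geom$pixel_spacing / 2
  blob <- 0.02 * exp(-(r / (0.3 * fov))^2)
  s <- forward_project(blob, geom) + disk_sinogram(geom, 0.995 * fov, 0.05)
  stopifnot(min(fbp(s, geom)) >= 0)
  s
}
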