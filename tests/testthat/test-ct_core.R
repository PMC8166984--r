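test_that("ramp kernel reproduces the exact band-limited taps", {
  k <- make_ramp_kernel(8)
  lags <- attr(k, "lags")
  expect_length(k, 15)
  expect_identical(lags, seq.int(-7L, 7L))
  expect_identical(k[lags == 0], 0.25)
  odd <- lags[lags %% 2L != 0L]
  for (n in odd) expect_identical(k[lags == n], -1 / (n * pi)^2)
  even <- lags[lags %% 2L == 0L & lags != 0L]
  expect_true(all(k[lags %in% even] == 0))
  expect_identical(as.numeric(k), as.numeric(rev(k)))  # symmetry
  expect_error(make_ramp_kernel(0), class = "negmar_invalid_argument")
})

test_that("ramp filtration is the kernel convolution with zero extension", {
  g <- tiny_geom()
  zero <- matrix(0, g$n_views, g$n_bins)
  expect_identical(ramp_filter(zero, g), zero)

  # unit impulse: output row equals the taps centered at that bin
  s <- zero; bin <- 10L; s[3, bin] <- 1
  out <- ramp_filter(s, g)
  k <- make_ramp_kernel(g$n_bins)
  lags <- attr(k, "lags")
  expected <- vapply(seq_len(g$n_bins),
                     function(b) as.numeric(k[lags == (b - bin)]), 0)
  expect_equal(out[3, ], expected / g$bin_spacing^2, tolerance = 1e-12)
  expect_true(all(out[-3, ] == 0))

  # linearity
  set.seed(7)
  s1 <- matrix(rnorm(length(zero)), g$n_views)
  s2 <- matrix(rnorm(length(zero)), g$n_views)
  lhs <- ramp_filter(2.5 * s1 - 1.3 * s2, g)
  rhs <- 2.5 * ramp_filter(s1, g) - 1.3 * ramp_filter(s2, g)
  expect_equal(lhs, rhs, tolerance = 1e-12)

  expect_error(ramp_filter(matrix(0, 3, 3), g), class = "negmar_shape_error")
})

test_that("forward projection matches the closed-form disk Radon transform", {
  g <- scan_geometry(180, 185, 1, 128, 1)
  radius <- 20; mu <- 0.02
  r <- grid_radii(g)
  img <- (r <= radius) * mu
  s <- forward_project(img, g)
  t_off <- detector_offsets(g)
  oracle <- ifelse(abs(t_off) < radius,
                   2 * mu * sqrt(pmax(radius^2 - t_off^2, 0)), 0)
  peak <- max(oracle)
  sel <- abs(t_off) < 0.9 * radius
  # per-bin agreement is limited by pixel-splat aliasing at the sharp rim
  expect_lt(max(abs(t(s[, sel]) - oracle[sel])) / peak, 0.15)
  # averaging over views cancels the aliasing almost completely
  expect_lt(max(abs(colMeans(s)[sel] - oracle[sel])) / peak, 0.02)
  # each view carries exactly the phantom mass (splat conserves weight)
  expect_equal(rowSums(s) * g$bin_spacing,
               rep(sum(img) * g$pixel_spacing^2, g$n_views),
               tolerance = 1e-12)
  expect_identical(forward_project(img * 0, g),
                   matrix(0, g$n_views, g$n_bins))
  expect_error(forward_project(matrix(0, 4, 4), g),
               class = "negmar_shape_error")
})

test_that("backproject is the exact transpose of forward_project", {
  g <- tiny_geom()
  A <- dense_forward(g)
  B <- dense_backproject(g)
  scal <- g$angular_range / g$n_views
  expect_lt(max(abs(B - scal * t(A))), 1e-10)
})

test_that("a single-view smear is constant along the ray direction", {
  g <- scan_geometry(1, 24, 1, 16, 1)
  s <- matrix(1, 1, g$n_bins)
  img <- backproject(s, g)
  # view 0 integrates along y: every column is constant inside the support
  r <- grid_radii(g)
  inside <- r <= g$n_pixels * g$pixel_spacing / 2
  for (col in seq_len(g$n_pixels)) {
    v <- img[, col][inside[, col]]
    if (length(v) > 1) expect_lt(diff(range(v)), 1e-12)
  }
  expect_identical(backproject(s * 0, g), matrix(0, 16, 16))
})

test_that("all four operators are linear", {
  g <- tiny_geom()
  set.seed(11)
  s1 <- matrix(rnorm(g$n_views * g$n_bins), g$n_views)
  s2 <- matrix(rnorm(g$n_views * g$n_bins), g$n_views)
  x1 <- matrix(rnorm(g$n_pixels^2), g$n_pixels)
  x2 <- matrix(rnorm(g$n_pixels^2), g$n_pixels)
  a <- 1.7; b <- -0.6
  for (op in list(ramp_filter, backproject, fbp)) {
    expect_equal(op(a * s1 + b * s2, g), a * op(s1, g) + b * op(s2, g),
                 tolerance = 1e-10)
  }
  for (op in list(forward_project, fbp_adjoint)) {
    expect_equal(op(a * x1 + b * x2, g), a * op(x1, g) + b * op(x2, g),
                 tolerance = 1e-10)
  }
})

test_that("fbp and fbp_adjoint satisfy the adjoint inner-product identity", {
  g <- tiny_geom()
  set.seed(3)
  for (i in 1:20) {
    s <- matrix(rnorm(g$n_views * g$n_bins), g$n_views)
    x <- matrix(rnorm(g$n_pixels^2), g$n_pixels)
    lhs <- sum(fbp(s, g) * x)
    rhs <- sum(s * fbp_adjoint(x, g))
    expect_lt(abs(lhs - rhs) / max(abs(lhs), 1e-12), 1e-6)
  }
})

test_that("FBP recovers the interior of an analytic disk phantom", {
  g <- scan_geometry(180, 185, 1, 128, 1)
  mu <- 0.02; radius <- 20
  rec <- fbp(disk_sinogram(g, radius, mu), g)
  interior <- grid_radii(g) < 0.8 * radius
  expect_lt(abs(mean(rec[interior]) - mu) / mu, 0.05)
})

test_that("FBP of a forward-projected smooth phantom returns the phantom", {
  g <- scan_geometry(180, 185, 1, 128, 1)
  r <- grid_radii(g)
  fov <- g$n_pixels * g$pixel_spacing / 2
  phantom <- 0.02 * exp(-(r / (0.35 * fov))^2)
  rec <- fbp(forward_project(phantom, g), g)
  interior <- r < 0.8 * fov
  rel_rms <- sqrt(mean((rec - phantom)[interior]^2)) /
    sqrt(mean(phantom[interior]^2))
  expect_lt(rel_rms, 0.10)
})
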