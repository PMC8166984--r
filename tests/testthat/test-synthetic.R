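test_that("a single-energy spectrum reduces to the monochromatic line integral", {
  g <- tiny_geom()
  sp <- spectrum_model(energies = 60, weights = 1,
                       mu = rbind(soft = 0.02, metal = 0.5))
  r <- grid_radii(g)
  maps <- list(soft = (r <= 6) * 1.0, metal = (r <= 2) * 1.0)
  maps$soft[maps$metal > 0] <- 0
  poly <- polychromatic_project(maps, sp, g)
  mono <- 0.02 * forward_project(maps$soft, g) +
    0.5 * forward_project(maps$metal, g)
  expect_equal(poly, mono, tolerance = 1e-10)

  empty <- list(soft = matrix(0, 16, 16), metal = matrix(0, 16, 16))
  expect_equal(polychromatic_project(empty, sp, g),
               matrix(0, g$n_views, g$n_bins), tolerance = 1e-15)
})

test_that("beam hardening underestimates line integrals through metal", {
  g <- tiny_geom()
  sp <- spectrum_model(energies = c(40, 100), weights = c(0.5, 0.5),
                       mu = rbind(soft = c(0.03, 0.02),
                                  metal = c(1.2, 0.3)))
  r <- grid_radii(g)
  maps <- list(soft = (r <= 6) * 1.0, metal = (r <= 2) * 1.0)
  maps$soft[maps$metal > 0] <- 0
  poly <- polychromatic_project(maps, sp, g)
  # reference: monochromatic at the weighted-average attenuation
  mu_bar_soft <- 0.5 * 0.03 + 0.5 * 0.02
  mu_bar_met <- 0.5 * 1.2 + 0.5 * 0.3
  mono <- mu_bar_soft * forward_project(maps$soft, g) +
    mu_bar_met * forward_project(maps$metal, g)
  through_metal <- forward_project(maps$metal, g) > 0.5
  expect_true(all(poly[through_metal] < mono[through_metal]))
  # direct two-energy arithmetic for one ray (Jensen's inequality)
  l <- 4
  expect_lt(-log(0.5 * exp(-1.2 * l) + 0.5 * exp(-0.3 * l)), mu_bar_met * l)
})

test_that("phantom rasterization matches an area-count oracle", {
  g <- geometry_preset("test")
  radius <- 10
  spec <- phantom_spec(
    ellipses = data.frame(x = 0, y = 0, a = 20, b = 20, phi = 0, value = 1),
    metal = data.frame(x = 0, y = 0, r = radius)
  )
  maps <- make_phantom(spec, g)
  n_metal <- sum(maps$metal > 0)
  area <- pi * radius^2 / g$pixel_spacing^2
  perimeter <- 2 * pi * radius / g$pixel_spacing
  expect_lt(abs(n_metal - area), perimeter)
  # metal-over-background precedence
  expect_true(all(maps$soft[maps$metal > 0] == 0))
  # empty spec
  empty <- make_phantom(phantom_spec(
    ellipses = data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                          b = numeric(0), phi = numeric(0),
                          value = numeric(0)),
    metal = data.frame(x = numeric(0), y = numeric(0), r = numeric(0))), g)
  expect_identical(empty$soft, matrix(0, 96, 96))
  expect_identical(empty$metal, matrix(0, 96, 96))
  # shapes outside the field of view are rejected
  expect_error(make_phantom(phantom_spec(
    ellipses = data.frame(x = 40, y = 0, a = 20, b = 5, phi = 0, value = 1),
    metal = data.frame(x = numeric(0), y = numeric(0), r = numeric(0))), g),
    class = "negmar_invalid_argument")
})

test_that("spectrum_model enforces its invariants", {
  expect_error(spectrum_model(c(60, 40), c(0.5, 0.5),
                              rbind(soft = c(0.02, 0.03))),
               class = "negmar_invalid_argument")  # unsorted energies
  expect_error(spectrum_model(c(40, 60), c(0.5, 0.5),
                              rbind(soft = c(0.02, 0.03))),
               class = "negmar_invalid_argument")  # mu increasing
  expect_error(spectrum_model(c(40, 60), c(-1, 2),
                              rbind(soft = c(0.03, 0.02))),
               class = "negmar_invalid_argument")  # negative weight
  sp <- spectrum_model(c(40, 60), c(2, 2), rbind(soft = c(0.03, 0.02)))
  expect_equal(sum(sp$weights), 1)  # normalization
})

test_that("the demo case is deterministic and exhibits the target pathology", {
  d1 <- make_demo_case(seed = 4)
  d2 <- make_demo_case(seed = 4)
  expect_identical(d1$sinogram, d2$sinogram)
  expect_identical(d1$ground_truth, d2$ground_truth)
  expect_identical(d1$metal_mask, d2$metal_mask)

  raw <- fbp(d1$sinogram, d1$geometry)
  expect_lt(min(raw), 0)  # negative undershoot present
  seg <- segment_metal(raw, 1 / 3)
  recovery <- sum(seg[d1$metal_mask] > 0) / sum(d1$metal_mask)
  expect_gte(recovery, 0.9)
  # metal attenuation dominates the background by >= 10x
  expect_gte(min(d1$ground_truth[d1$metal_mask]) /
               max(d1$ground_truth[!d1$metal_mask]), 10)
})
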