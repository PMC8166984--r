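#' Discrete x-ray spectrum with per-material attenuation curves
#'
#' A small set of energy levels with fluence weights and, for each
#' material, the linear attenuation at every level.  This is the minimal
#' polychromatic model that produces beam hardening: low energies are
#' absorbed preferentially, so measured log-attenuation grows sub-linearly
#' with path length - severely so through metal.
#'
#' @param energies energy levels in keV, strictly increasing.
#' @param weights nonnegative fluence weights; normalized to sum to 1.
#' @param mu materials x energies matrix of linear attenuation (1/mm),
#'   positive and non-increasing with energy in every row; row names are
#'   the material names.
#' @param reference index of the reference energy; ground-truth images are
#'   expressed in attenuation at this level.
#' @return A `spectrum_model`.
#' @export
spectrum_model <- function(energies, weights, mu, reference = 1L) {
  if (length(energies) < 1L || any(!is.finite(energies)) ||
      is.unsorted(energies, strictly = TRUE))
    stop_invalid("energies must be finite and strictly increasing")
  if (length(weights) != length(energies) || any(!is.finite(weights)) ||
      any(weights < 0) || sum(weights) <= 0)
    stop_invalid("weights must be nonnegative with a positive sum")
  if (!is.matrix(mu) || ncol(mu) != length(energies) || is.null(rownames(mu)))
    stop_invalid("mu must be a named materials x energies matrix")
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop_invalid("mu must be positive and finite")
  if (any(apply(mu, 1, function(r) any(diff(r) > 0))))
    stop_invalid("mu must be non-increasing with energy for every material")
  reference <- as.integer(reference)
  if (is.na(reference) || reference < 1L || reference > length(energies))
    stop_invalid("reference must index an energy level")
  structure(list(energies = as.numeric(energies),
                 weights = as.numeric(weights) / sum(weights),
                 mu = mu, reference = reference),
            class = "spectrum_model")
}

#' Default two-material demonstration spectrum
#'
#' Five levels from 40 to 120 keV with a water-like soft material and an
#' iron-like metal.  The attenuation values are documented constants
#' chosen so the metal dominates the soft material by more than a factor
#' of ten at every energy and hardens strongly, not physical table
#' lookups.  The reference energy is 60 keV.
#'
#' @return A [spectrum_model()].
#' @export
default_spectrum <- function() {
  mu <- rbind(
    soft = c(0.030, 0.024, 0.021, 0.019, 0.018),
    metal = c(1.60, 0.90, 0.55, 0.38, 0.30)
  )
  spectrum_model(energies = c(40, 60, 80, 100, 120),
                 weights = c(0.30, 0.30, 0.20, 0.13, 0.07),
                 mu = mu, reference = 2L)
}

#' Phantom specification
#'
#' Soft background built from ellipses plus metallic disk inserts.
#' Ellipse `value` is a density relative to the spectrum's soft-material
#' attenuation (1 = reference soft tissue); overlapping ellipses add.
#' Metal disks are solid: where a disk covers a pixel the soft density is
#' discarded (metal-over-background resolves to metal).
#'
#' @param ellipses data frame with columns `x`, `y` (center, mm), `a`,
#'   `b` (semi-axes, mm), `phi` (rotation, radians), `value` (relative
#'   density), and optionally `taper` (fraction of the ellipse radius over
#'   which the density falls smoothly to zero at the rim; default 0 =
#'   sharp edge).  Tapered soft edges keep band-limit overshoot of the
#'   discrete FBP from generating negative pixels of its own, so that
#'   negative values isolate the beam-hardening mechanism.
#' @param metal data frame with columns `x`, `y` (center, mm) and `r`
#'   (radius, mm).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(ellipses, metal) {
  need_e <- c("x", "y", "a", "b", "phi", "value")
  need_m <- c("x", "y", "r")
  if (!is.data.frame(ellipses) || !all(need_e %in% names(ellipses)))
    stop_invalid("ellipses needs columns x, y, a, b, phi, value")
  if (is.null(ellipses$taper)) ellipses$taper <- rep(0, nrow(ellipses))
  if (any(!is.finite(ellipses$taper) | ellipses$taper < 0 |
          ellipses$taper >= 1))
    stop_invalid("ellipse taper must be in [0, 1)")
  if (!is.data.frame(metal) || !all(need_m %in% names(metal)))
    stop_invalid("metal needs columns x, y, r")
  structure(list(ellipses = ellipses, metal = metal), class = "phantom_spec")
}

#' Rasterize a phantom into per-material density maps
#'
#' Pixel-center inclusion: a pixel belongs to a shape when its center
#' falls inside.  Returns one map per material; the reference-energy
#' ground truth is each map times its material's reference attenuation,
#' summed.
#'
#' @param spec a [phantom_spec()].
#' @param geom a [scan_geometry()].
#' @return Named list with matrices `soft` (relative density) and `metal`
#'   (0/1 indicator).
#' @export
make_phantom <- function(spec, geom) {
  if (!inherits(spec, "phantom_spec")) stop_invalid("spec must be a phantom_spec")
  check_geometry(geom)
  fov_half <- geom$n_pixels * geom$pixel_spacing / 2
  ok_e <- with(spec$ellipses,
               sqrt(x^2 + y^2) + pmax(a, b) <= fov_half)
  ok_m <- with(spec$metal, sqrt(x^2 + y^2) + r <= fov_half)
  if (!all(ok_e, ok_m))
    stop_invalid("all phantom shapes must lie within the field of view")
  pc <- pixel_coords(geom)
  np <- geom$n_pixels
  soft <- numeric(np^2)
  for (i in seq_len(nrow(spec$ellipses))) {
    e <- spec$ellipses[i, ]
    dx <- pc$x - e$x
    dy <- pc$y - e$y
    u <- dx * cos(e$phi) + dy * sin(e$phi)
    v <- -dx * sin(e$phi) + dy * cos(e$phi)
    rho <- sqrt((u / e$a)^2 + (v / e$b)^2)
    tp <- if (is.null(e$taper)) 0 else e$taper
    if (tp > 0) {
      # raised-cosine rim from normalized radius 1 - taper down to 0 at 1
      r0 <- 1 - tp
      w <- ifelse(rho <= r0, 1,
                  ifelse(rho >= 1, 0, 0.5 * (1 + cos(pi * (rho - r0) / tp))))
      soft <- soft + e$value * w
    } else {
      soft <- soft + e$value * as.numeric(rho <= 1)
    }
  }
  metal <- numeric(np^2)
  for (i in seq_len(nrow(spec$metal))) {
    d <- spec$metal[i, ]
    metal <- pmax(metal,
                  as.numeric((pc$x - d$x)^2 + (pc$y - d$y)^2 <= d$r^2))
  }
  soft[metal > 0] <- 0
  list(soft = matrix(soft, np, np), metal = matrix(metal, np, np))
}

#' Ground-truth attenuation image at the reference energy
#'
#' @param maps material maps from [make_phantom()].
#' @param spectrum a [spectrum_model()].
#' @return Attenuation image (1/mm).
#' @export
ground_truth_image <- function(maps, spectrum) {
  ref <- spectrum$reference
  out <- 0
  for (m in rownames(spectrum$mu)) {
    if (is.null(maps[[m]])) stop_invalid(sprintf("missing material map '%s'", m))
    out <- out + maps[[m]] * spectrum$mu[m, ref]
  }
  out
}

#' Polychromatic (beam-hardened) projection
#'
#' For every ray the material path lengths come from [forward_project()];
#' the transmitted fraction is the spectrum-weighted Beer-Lambert sum
#' `I = sum_E w(E) exp(-sum_m mu_m(E) l_m)` and the sinogram records
#' `-log(I)`.  With a single energy level this reduces exactly to the
#' monochromatic line integral.  Through metal the polychromatic value
#' falls below the reference-energy monochromatic one - the bias that
#' makes raw FBP undershoot negative next to metal.
#'
#' @param maps named list of material density maps (see [make_phantom()]).
#' @param spectrum a [spectrum_model()].
#' @param geom a [scan_geometry()].
#' @param noise_photons optional incident photon count per ray; when
#'   given, transmitted counts are Poisson-sampled (seed the RNG for
#'   reproducibility).  `NULL` (default) is noiseless - the artifact this
#'   package addresses is bias, not noise.
#' @return Sinogram matrix, `n_views` x `n_bins`.
#' @export
polychromatic_project <- function(maps, spectrum, geom, noise_photons = NULL) {
  if (!inherits(spectrum, "spectrum_model"))
    stop_invalid("spectrum must be a spectrum_model")
  mats <- rownames(spectrum$mu)
  lengths <- lapply(mats, function(m) {
    if (is.null(maps[[m]])) stop_invalid(sprintf("missing material map '%s'", m))
    forward_project(maps[[m]], geom)
  })
  I <- matrix(0, geom$n_views, geom$n_bins)
  for (e in seq_along(spectrum$energies)) {
    expo <- 0
    for (j in seq_along(mats))
      expo <- expo + spectrum$mu[mats[j], e] * lengths[[j]]
    I <- I + spectrum$weights[e] * exp(-expo)
  }
  if (!is.null(noise_photons)) {
    if (!is.finite(noise_photons) || noise_photons <= 0)
      stop_invalid("noise_photons must be > 0")
    counts <- matrix(stats::rpois(length(I), noise_photons * I), nrow(I))
    I <- counts / noise_photons
  }
  floor_ <- 1e-12
  if (any(I < floor_)) {
    warning(sprintf("transmitted intensity clamped at %g for %d rays",
                    floor_, sum(I < floor_)), call. = FALSE)
    I <- pmax(I, floor_)
  }
  -log(I)
}

#' Seeded beam-hardened demonstration case
#'
#' Builds a deterministic phantom - a soft elliptical body with interior
#' structure and three randomly placed metal disks - and simulates its
#' polychromatic sinogram on the given geometry.  Generation asserts the
#' properties the reconstruction method relies on: the raw FBP must
#' contain negative pixels (the beam-hardening undershoot) and the
#' 1/3-of-max segmentation must recover at least 90 percent of the true
#' metal support.  A case failing either assertion raises an error rather
#' than returning silently.
#'
#' @param seed integer seed; the same seed reproduces the case bit for
#'   bit.
#' @param geom a [scan_geometry()]; default the `"test"` preset.
#' @param spectrum a [spectrum_model()]; default [default_spectrum()].
#' @return List with `sinogram`, `ground_truth` (reference-energy image),
#'   `metal_mask` (logical true-support matrix), `maps`, `geometry`,
#'   `spectrum`, `seed`.
#' @export
make_demo_case <- function(seed, geom = geometry_preset("test"),
                           spectrum = default_spectrum()) {
  check_geometry(geom)
  seed <- as.integer(seed)
  if (is.na(seed)) stop_invalid("seed must be an integer")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  # The body is a disk filling the reconstruction support, so every
  # in-support pixel carries positive attenuation and negative values can
  # only come from the beam-hardening undershoot the method targets.
  fov_half <- geom$n_pixels * geom$pixel_spacing / 2
  body_r <- 0.99 * fov_half
  ellipses <- data.frame(
    x = c(0, -0.25, 0.30) * fov_half,
    y = c(0, 0.10, -0.12) * fov_half,
    a = c(body_r, 0.28 * fov_half, 0.20 * fov_half),
    b = c(body_r, 0.20 * fov_half, 0.16 * fov_half),
    phi = c(0, -0.4, 0.9),
    value = c(1, 0.35, -0.25),
    taper = c(0, 0.35, 0.35)
  )
  n_disks <- 3L
  ang <- stats::runif(n_disks, 0, 2 * pi)
  rad <- stats::runif(n_disks, 0.15, 0.45) * fov_half
  metal <- data.frame(
    x = rad * cos(ang),
    y = rad * sin(ang),
    r = stats::runif(n_disks, 0.055, 0.085) * fov_half
  )
  spec <- phantom_spec(ellipses, metal)
  maps <- make_phantom(spec, geom)
  truth <- ground_truth_image(maps, spectrum)
  sino <- polychromatic_project(maps, spectrum, geom)

  raw <- fbp(sino, geom)
  if (min(raw) >= 0)
    stop_generation("demo case failed its negativity assertion: raw FBP has no negative pixels")
  seg <- segment_metal(raw, 1 / 3)
  support <- maps$metal > 0
  recovered <- sum(seg[support] > 0) / sum(support)
  if (sum(support) == 0 || recovered < 0.9)
    stop_generation(sprintf(
      "demo case failed its segmentation assertion: %.1f%% of metal support recovered",
      100 * recovered))

  list(sinogram = sino, ground_truth = truth, metal_mask = support,
       maps = maps, geometry = geom, spectrum = spectrum, seed = seed)
}
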