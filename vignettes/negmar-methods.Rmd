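---
title: "Restricting negative pixels: the model behind negmar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restricting negative pixels: the model behind negmar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negmar)
```

## The problem

An x-ray tube emits a broad energy spectrum, and low-energy photons are
absorbed preferentially.  Through a few centimetres of soft material this
*beam hardening* is a mild, correctable bias; through metal it is severe:
the measured log-attenuation falls far below the true line integral.  A
filtered-backprojection (FBP) reconstruction from such data shows dark
streaks between and around metal objects, and — since the corrupted
projections are *under*-estimates — pixels next to the metal routinely
undershoot below zero.  A linear attenuation coefficient cannot be
negative, so every negative pixel is certainly artifact.

`negmar` turns that observation into the whole objective.  No data-fidelity
term, no prior on the image: the objective is just the energy of the
negative pixels of the FBP image,

$$F(P) \;=\; \bigl\lVert \min(0,\, A P) \bigr\rVert_2^2 ,$$

where $P$ is the sinogram (all views stacked into a vector), $A$ is the FBP
operator, and the $\min$ acts elementwise.  The free variables are **only
the metal-affected projections** $P_M$; everything else, $P_{\text{not}M}$,
is measured cleanly and is never touched.  After the projections are
repaired, one ordinary FBP produces the final image.  This is *not*
projection inpainting: the metal and its projections are never removed, and
no metal-free image is ever reconstructed.

## The pipeline

1. **Raw reconstruction.** $X_{\text{raw}} = A P$ by `fbp()`.
2. **Metal segmentation.** `segment_metal()` keeps every pixel at or above
   a threshold of $1/3 \times \max(X_{\text{raw}})$ and zeroes the rest.
   Metal attenuation dwarfs everything else, so a bare threshold suffices;
   the fraction is exposed as `seg_fraction` because it is a tunable, and
   ties at the threshold are kept (the rule zeroes values *smaller than*
   the threshold).
3. **Trace identification.** `compute_trace()` forward-projects the
   metal-only image; every sinogram entry receiving any positive
   contribution is flagged as $P_M$.  Linear-interpolation footprints
   create values at rounding level, so the flagging threshold `trace_eps`
   defaults to $10^{-9} \times$ the projection maximum — effectively "any
   positive contribution" but robust to rounding.  No dilation is applied;
   the trace is exactly the set of rays that intersect segmented metal.
4. **Restricted descent.** `run_mar()` iterates
   $$P_M^{(k+1)} = P_M^{(k)} - \beta\, D\, A^T \min\{0,\, A P^{(k)}\},$$
   where $D$ masks the update to the trace and $A^T$ — forward projection
   followed by ramp filtration — is the adjoint of the FBP operator.
   $\min(0,\cdot)$ is not differentiable at zero; the subgradient element
   there is taken as 0, which is what the formula computes implicitly.
   The mask is computed once, before the loop, because segmentation and
   trace identification precede the iteration in the protocol.

The comparator `clamp_negatives()` — the naive "set negative pixels to
zero" — is included deliberately.  The method's one firm claim is that it
is *different* from this clamp: repairing projections moves entire
streaks, including pixels that were positive, which no pointwise clamp can
do.  The acceptance checks quantify exactly that.

## Discretization of the operators

No standard discretization is mandated by the algorithm, so the package
picks the one that makes the adjoint identity *exact*, because the
gradient formula presumes it:

* **Projector pair.** A pixel-driven splat: at each view, each pixel
  center maps to a continuous detector coordinate and its value (weighted
  by the pixel pitch) is split linearly between the two neighbouring
  bins.  `backproject()` is the literal transpose (a gather with the same
  weights).  On a $16\times16$ grid with 12 views the dense matrices agree
  with each other's transpose to $10^{-16}$.  The quantitative
  line-integral scale of this splat assumes `bin_spacing == pixel_spacing`,
  which both presets satisfy.
* **Reconstruction support.** Pixels outside the inscribed field-of-view
  circle are not covered by the detector at every angle and are excluded
  from both operators (the common parallel-beam convention, cf.
  scikit-image's `circle = TRUE`).  Grid corners therefore stay exactly
  zero instead of accumulating angle-dependent ripple.
* **Ramp filter.** The exact band-limited kernel: $h(0)=1/4$,
  $h(n)=-1/(n\pi)^2$ for odd $n$, $0$ otherwise, applied by direct
  convolution (a symmetric Toeplitz matrix product) with zero extension
  beyond the detector and no apodization window.  Physical scaling is
  $1/\Delta t^2$ at filtration and $\Delta\theta = \pi/n_{\text{views}}$
  at backprojection, which makes `fbp()` quantitatively correct: the
  analytic disk phantom reconstructs to within 0.5 % in the interior.
* **Adjoint scaling.** `fbp_adjoint()` carries the same $\Delta\theta$
  quadrature weight, so $\langle A s, x\rangle = \langle s, A^T x\rangle$
  holds to rounding error and the central-difference check of the
  gradient passes at $10^{-4}$ relative.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `beta` | 1 | — | gradient step size |
| `n_iterations` | 500 | — | fixed iteration count; no early exit |
| `seg_fraction` | 1/3 | — | metal threshold as fraction of image max |
| `trace_eps` | auto | line-integral | flagging threshold on the metal projection |

A unit step is only meaningful relative to an operator scaling, which the
protocol leaves implicit.  Under this package's scaling $\beta = 1$
descends monotonically on the bundled phantoms, but as a safeguard the
step is halved (at most 20 times per run, recorded in `step_sizes`)
whenever an iteration would increase $F$.  The objective history is always
recorded — length `n_iterations + 1`, including the initial value — so
convergence can be audited after the fact.

## The synthetic data generator

The algorithm was demonstrated on real scanner data that is not
redistributable, so the package ships a simulator that reproduces the
*mechanism* rather than any particular dataset.  `make_demo_case()`
builds, for a given seed, a soft-material body with interior structure
and three randomly placed metal disks, and projects it through a discrete
five-level spectrum (40–120 keV) with documented — not physically tabulated —
attenuation constants: a water-like soft material and an iron-like metal
at $\geq 10\times$ the soft attenuation everywhere, hardening steeply.
For each ray, per-material path lengths $\ell_m$ come from the same
forward projector used everywhere else, and the recorded value is
$-\ln \sum_E w(E)\, e^{-\sum_m \mu_m(E)\ell_m}$.  With a single energy
level this reduces exactly to the monochromatic line integral (tested to
$10^{-10}$); with several, Jensen's inequality makes every metal-crossing
value an underestimate — the beam-hardening bias.

Two deliberate phantom-design choices isolate the phenomenon under study:

* the body disk fills the reconstruction support, so every in-support
  pixel has a positive attenuation baseline, and
* soft interior edges get raised-cosine tapers, so band-limit overshoot
  of the discrete FBP does not generate negative pixels of its own.

With a sharp body edge or open air in the field of view, discretization
ripple around exactly-zero pixels flips signs at random and drowns the
metal-related negativity in sign noise.  As configured, negative pixels
appear only near the metal — which is precisely the regime the method
addresses.  Generation asserts this (raw FBP minimum $< 0$) and asserts
that 1/3-of-max segmentation recovers $\geq 90\%$ of the true metal
support; a draw failing either assertion raises an error rather than
returning silently.

What the simulator deliberately omits: detector noise (the method targets
bias, not noise — optional Poisson sampling is available behind
`noise_photons`), scatter, finite focal spot and detector response,
physical spectra, and any fan- or cone-beam geometry.  Passing tests on
these phantoms therefore demonstrate the mechanism and the optimizer's
behaviour, not clinical or security-screening performance.

## Numerical and degenerate-case choices

* Empty metal (no pixel above threshold, or an all-false mask): the run
  returns the raw FBP unchanged with an `empty_mask` warning — the
  algorithm is a no-op without metal.
* If $F$ still increases after the step-halving budget is exhausted, the
  run completes and sets a `divergence` flag rather than aborting.
* Transmitted intensity in the simulator is floored at $10^{-12}$ (with a
  warning) before the logarithm.
* Float TIFF I/O validates shape against the geometry and rejects
  non-finite values with distinct condition classes.

## Problem sizes

The bundled checks use a $16\times16$ grid with 12 views for everything
requiring dense operator matrices or finite differences, a $128\times128$
grid with 180 views for reconstruction-fidelity oracles, and the
90-view / 128-bin / 96-pixel `"test"` preset with the full 500-iteration
protocol for the end-to-end demonstration.  The `"paper"` preset
(180 views, 597 bins of 0.92 mm, $420\times420$ image) is the geometry the
method was originally demonstrated at and runs in a few minutes.

## Known limitations

* The objective measures the *energy* of negative pixels, not their
  *number*.  Descent reliably removes deep undershoots (the image minimum
  typically rises by a factor of 3–5), but a shallow negative haze can
  spread while $F$ falls, so the negative-pixel count is not monotone and
  on some random phantoms ends slightly above the raw count even after
  500 iterations.  The count comparison in the acceptance suite holds for
  the documented demo seed; treat the count as a descriptive statistic,
  not a guarantee.
* The restricted update can only change the image through rays in the
  metal trace; artifacts not attributable to those rays (e.g. aliasing
  from sparse views far from metal) are reduced only incidentally.
* $F$ has no unique minimizer — many trace completions yield nonnegative
  images — and no convergence criterion beyond the fixed iteration count
  is applied.
* The pixel-driven splat shows bin-level aliasing on sharp edges (up to
  ~12 % of the profile peak at single bins); view-averaged profiles are
  accurate to well under 1 %.  This is shared by pixel-driven projectors
  generally and is why the pair is used as a matched adjoint rather than
  as a high-fidelity simulator of single rays.
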