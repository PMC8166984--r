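#' Negative part of an image
#'
#' Elementwise `min(0, x)`: keeps the negative pixels and zeroes the rest.
#' The result is the residual the objective penalizes - nonzero only where
#' the reconstruction violates the physical nonnegativity of attenuation.
#'
#' @param img image matrix.
#' @return Matrix of the same shape, nonpositive everywhere.
#' @export
negative_part <- function(img) {
  check_finite_matrix(img, "image")
  pmin(img, 0)
}

#' Clamp negative pixels to zero
#'
#' Elementwise `max(0, x)` - the naive comparator that simply deletes
#' negative pixels from the raw FBP image.  The iterative method is *not*
#' equivalent to this: it also changes pixels that were nonnegative,
#' because repairing the metal-affected projections moves whole streaks.
#'
#' @param img image matrix.
#' @return Matrix of the same shape, nonnegative everywhere.
#' @export
clamp_negatives <- function(img) {
  check_finite_matrix(img, "image")
  pmax(img, 0)
}

#' Negativity objective
#'
#' The squared L2 norm of the negative pixel values,
#' `F = sum(min(0, x)^2)`.  Zero exactly when the image is nonnegative
#' everywhere.
#'
#' @param img image matrix.
#' @return Nonnegative scalar.
#' @export
objective <- function(img) {
  check_finite_matrix(img, "image")
  sum(pmin(img, 0)^2)
}

#' Subgradient of the negativity objective in the projection domain
#'
#' `2 * fbp_adjoint(negative_part(fbp(p)))`.  The min makes the objective
#' nondifferentiable at pixels that are exactly zero; there the
#' subgradient element is taken as zero, which is what the min form does
#' implicitly.
#'
#' @param p sinogram matrix.
#' @param geom a [scan_geometry()].
#' @return Sinogram-shaped gradient matrix.
#' @export
subgradient <- function(p, geom) {
  2 * fbp_adjoint(negative_part(fbp(p, geom)), geom)
}

#' Metal artifact reduction by restricted gradient descent
#'
#' Runs the full pipeline: FBP of the measured sinogram, metal
#' segmentation at `seg_fraction` of the image maximum, trace
#' identification by forward projection, then `n_iterations` updates
#' \deqn{P_M^{(k+1)} = P_M^{(k)} - \beta \, D \, A^T \min(0, A P^{(k)}),}
#' where only the metal-affected entries \eqn{P_M} move and the rest of
#' the sinogram is preserved bit for bit.  The measured values initialize
#' \eqn{P_M^{(0)}}; metal and its projections are never removed.  If an
#' iteration would increase the objective the step size is halved before
#' the step is accepted (at most 20 halvings per run, logged in
#' `step_sizes`).  The final image is the FBP of the repaired sinogram.
#'
#' @param p0 measured sinogram, `n_views` x `n_bins`.
#' @param geom a [scan_geometry()].
#' @param config a [mar_config()].
#' @param mask optional precomputed trace mask; `NULL` (default) computes
#'   it from the raw FBP via [segment_metal()] and [compute_trace()].
#' @return A `mar_result` with elements `final_sinogram`, `final_image`,
#'   `raw_image`, `objective_history` (length `n_iterations + 1`,
#'   including the initial value), `step_sizes`, `mask`, and `warnings`
#'   (any of `"empty_mask"`, `"divergence"`).  With an empty mask the
#'   input is returned unchanged together with the raw FBP image and an
#'   `"empty_mask"` warning.
#' @examples
#' \donttest{
#' demo <- make_demo_case(seed = 1)
#' res <- run_mar(demo$sinogram, demo$geometry,
#'                config = mar_config(n_iterations = 50))
#' res
#' }
#' @export
run_mar <- function(p0, geom, config = mar_config(), mask = NULL) {
  check_sinogram(p0, geom)
  if (!inherits(config, "mar_config"))
    stop_invalid("config must be a mar_config object")
  raw <- fbp(p0, geom)
  if (is.null(mask)) {
    metal <- segment_metal(raw, config$seg_fraction)
    mask <- compute_trace(metal, geom, config$trace_eps)
  } else if (!is.logical(mask) || !all(dim(mask) == dim(p0))) {
    stop_shape("mask must be a logical matrix matching the sinogram shape")
  }
  K <- config$n_iterations
  F0 <- objective(raw)
  if (!any(mask)) {
    warning("no metal trace found; returning the raw FBP unchanged",
            call. = FALSE)
    return(new_mar_result(p0, raw, raw, rep(F0, K + 1L), numeric(0), mask,
                          warnings = "empty_mask"))
  }
  P <- p0
  X <- raw
  Fcur <- F0
  history <- numeric(K + 1L)
  history[1L] <- F0
  steps <- numeric(K)
  beta <- config$beta
  halvings <- 0L
  for (k in seq_len(K)) {
    g <- 2 * fbp_adjoint(pmin(X, 0), geom)
    repeat {
      Pn <- P
      Pn[mask] <- P[mask] - beta * g[mask]
      Xn <- fbp(Pn, geom)
      Fn <- objective(Xn)
      if (Fn <= Fcur || halvings >= 20L) break
      beta <- beta / 2
      halvings <- halvings + 1L
    }
    steps[k] <- beta
    P <- Pn
    X <- Xn
    Fcur <- Fn
    history[k + 1L] <- Fn
  }
  warn <- character(0)
  if (history[K + 1L] > history[1L]) {
    warning("objective increased over the run (divergence)", call. = FALSE)
    warn <- "divergence"
  }
  new_mar_result(P, X, raw, history, steps, mask, warnings = warn)
}

new_mar_result <- function(final_sinogram, final_image, raw_image,
                           objective_history, step_sizes, mask, warnings) {
  structure(
    list(final_sinogram = final_sinogram, final_image = final_image,
         raw_image = raw_image, objective_history = objective_history,
         step_sizes = step_sizes, mask = mask, warnings = warnings),
    class = "mar_result"
  )
}

#' @export
print.mar_result <- function(x, ...) {
  h <- x$objective_history
  cat("<mar_result>\n")
  cat(sprintf("  iterations : %d\n", length(h) - 1L))
  cat(sprintf("  objective  : %.6g -> %.6g\n", h[1], h[length(h)]))
  cat(sprintf("  trace size : %d of %d sinogram entries\n",
              sum(x$mask), length(x$mask)))
  if (length(x$step_sizes))
    cat(sprintf("  step size  : %.4g (final)\n",
                x$step_sizes[length(x$step_sizes)]))
  if (length(x$warnings))
    cat(sprintf("  warnings   : %s\n", paste(x$warnings, collapse = ", ")))
  invisible(x)
}
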