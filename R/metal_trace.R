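#' Optimizer configuration
#'
#' Bundles the tunables of the restricted gradient descent.  The defaults
#' follow the reconstruction protocol the method was demonstrated with:
#' unit step size, 500 iterations, metal segmented at one third of the
#' maximum image value.
#'
#' @param beta step size of the gradient descent (> 0, dimensionless).  If
#'   an iteration would increase the objective the step is halved (at most
#'   20 times over the whole run) before being accepted, so the default is
#'   usable on any geometry.
#' @param n_iterations fixed iteration count (>= 1); there is no
#'   tolerance-based early exit, but the objective history is recorded so
#'   convergence can be audited.
#' @param seg_fraction fraction of the maximum raw-image value used as the
#'   metal segmentation threshold, in (0, 1).
#' @param trace_eps threshold on the forward-projected metal-only image
#'   above which a sinogram entry is flagged as metal-affected.  `NULL`
#'   (default) resolves to `1e-9 * max(projection)`, i.e. effectively "any
#'   positive contribution" while robust to interpolation rounding.
#' @return A `mar_config` list.
#' @export
mar_config <- function(beta = 1, n_iterations = 500L, seg_fraction = 1 / 3,
                       trace_eps = NULL) {
  if (!is.finite(beta) || beta <= 0) stop_invalid("beta must be > 0")
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L)
    stop_invalid("n_iterations must be >= 1")
  if (!is.finite(seg_fraction) || seg_fraction <= 0 || seg_fraction >= 1)
    stop_invalid("seg_fraction must be in (0, 1)")
  if (!is.null(trace_eps) && (!is.finite(trace_eps) || trace_eps < 0))
    stop_invalid("trace_eps must be >= 0 (or NULL for automatic)")
  structure(list(beta = beta, n_iterations = n_iterations,
                 seg_fraction = seg_fraction, trace_eps = trace_eps),
            class = "mar_config")
}

#' Segment metal from a raw FBP image
#'
#' Thresholds at `seg_fraction` times the maximum image value: every pixel
#' below the threshold is set to zero, pixels at or above it are kept
#' unchanged.  With the default fraction of 1/3 this isolates metal, whose
#' attenuation dwarfs the rest of the object.  An image with no positive
#' values yields an all-zero (empty-metal) result.
#'
#' @param raw raw FBP reconstruction (matrix).
#' @param seg_fraction threshold fraction in (0, 1); default 1/3.
#' @return Metal-only image of the same shape.
#' @export
segment_metal <- function(raw, seg_fraction = 1 / 3) {
  check_finite_matrix(raw, "raw image")
  if (!is.finite(seg_fraction) || seg_fraction <= 0 || seg_fraction >= 1)
    stop_invalid("seg_fraction must be in (0, 1)")
  m <- max(raw)
  out <- raw
  if (m <= 0) {
    out[] <- 0
    return(out)
  }
  out[raw < seg_fraction * m] <- 0
  out
}

#' Identify the metal trace in the sinogram
#'
#' Forward-projects the metal-only image and flags every sinogram entry
#' whose projected value exceeds `trace_eps`: these are the rays that pass
#' through metal, the index set of the optimization variables.  All other
#' entries are never touched by the optimizer.
#'
#' @param metal_only metal-only image, typically from [segment_metal()].
#' @param geom a [scan_geometry()].
#' @param trace_eps nonnegative flagging threshold; `NULL` resolves to
#'   `1e-9 * max(projection)`.
#' @return Logical `n_views` x `n_bins` matrix (`TRUE` = metal-affected).
#' @export
compute_trace <- function(metal_only, geom, trace_eps = NULL) {
  proj <- forward_project(metal_only, geom)
  top <- max(proj)
  if (is.null(trace_eps)) trace_eps <- 1e-9 * max(top, 0)
  if (!is.finite(trace_eps) || trace_eps < 0)
    stop_invalid("trace_eps must be >= 0")
  if (top <= 0) return(matrix(FALSE, geom$n_views, geom$n_bins))
  proj > trace_eps
}

#' Restrict a sinogram to the metal trace
#'
#' The dimension-reduction operator of the update rule, realized as
#' masking so that sinogram shape is preserved: flagged entries pass
#' through, all others become exactly zero.  Idempotent and linear.
#'
#' @param g sinogram-shaped matrix (e.g. a gradient).
#' @param mask logical matrix from [compute_trace()].
#' @return Matrix equal to `g` on the mask and zero elsewhere.
#' @export
apply_restriction <- function(g, mask) {
  if (!is.matrix(g) || !is.matrix(mask) || !is.logical(mask))
    stop_invalid("g must be a matrix and mask a logical matrix")
  if (!all(dim(g) == dim(mask)))
    stop_shape(sprintf("g is %d x %d but mask is %d x %d",
                       nrow(g), ncol(g), nrow(mask), ncol(mask)))
  g[!mask] <- 0
  g
}
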