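# Classed conditions so callers (and the CLI) can distinguish failure modes.

stop_negmar <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "negmar_error"), call = call))
}

stop_invalid <- function(msg) stop_negmar(msg, "negmar_invalid_argument")

stop_shape <- function(msg) {
  stop_negmar(msg, c("negmar_shape_error", "negmar_invalid_argument"))
}

stop_nonfinite <- function(msg) {
  stop_negmar(msg, c("negmar_nonfinite_error", "negmar_invalid_argument"))
}

stop_io <- function(msg) stop_negmar(msg, "negmar_io_error")

stop_generation <- function(msg) stop_negmar(msg, "negmar_generation_error")

check_finite_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_invalid(sprintf("%s must be a numeric matrix", what))
  if (!all(is.finite(x)))
    stop_nonfinite(sprintf("%s contains non-finite values", what))
  invisible(x)
}
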