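# Parameter vectors are stored and optimised on the log10 scale throughout;
# conversion to the linear scale happens only where the right-hand side or a
# readout function is evaluated.

#' Coerce and validate a log10 parameter vector for a model
#'
#' Parameters are handled as named numeric vectors of log10 values (the scale
#' on which estimation, profiling and confidence intervals operate). This
#' helper checks completeness and finiteness and returns the vector reordered
#' to match `model$param_labels`.
#'
#' @param x Named numeric vector of log10 parameter values.
#' @param model A [dynamic_model()].
#' @return Named numeric vector ordered like `model$param_labels`.
#' @export
as_log10_params <- function(x, model) {
  if (is.null(names(x)) || !is.numeric(x)) {
    abort("parameters must be a named numeric vector of log10 values",
          class = "plsens_config_error")
  }
  missing <- setdiff(model$param_labels, names(x))
  if (length(missing)) {
    abort(paste0("missing parameter(s): ", paste(missing, collapse = ", ")),
          class = "plsens_config_error")
  }
  x <- x[model$param_labels]
  if (any(!is.finite(x))) {
    abort("parameter values must be finite on the log10 scale",
          class = "plsens_config_error")
  }
  x
}

# Linear-scale parameter vector including model constants (e.g. A0 = 290).
linear_params <- function(params, model) {
  p <- 10^params
  if (length(model$constants)) {
    p <- c(p, unlist(model$constants))
  }
  p
}
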