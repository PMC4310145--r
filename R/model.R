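#' Define a dynamic (ODE) model
#'
#' A `pls_model` bundles everything needed to simulate a biochemical network:
#' state labels, parameter labels, the right-hand side f of the ODE system
#' dx/dt = f(x, u(t), theta), a (possibly parameter-dependent) initial state,
#' and one or more readout functions y = g(x, theta) mapping the state
#' trajectory to what an instrument would record. Parameters live on the log10
#' scale everywhere in the package; `rhs`, `initial_state` and the readout
#' functions receive them on the linear scale (with constants appended).
#'
#' @param name Model name.
#' @param states Character vector of state labels (non-empty, unique).
#' @param params Character vector of parameter labels (non-empty, unique).
#' @param rhs Function `(t, x, p, u)` returning the state derivative vector;
#'   `x` and `p` are named numeric vectors on the linear scale, `u` the scalar
#'   stimulus value.
#' @param initial_state Function `(p)` returning the named state vector at
#'   t = 0. Initial conditions may depend on estimated parameters (e.g. a pool
#'   size that is itself estimated), so the initial state is re-derived from
#'   the current parameter vector at every simulation.
#' @param readouts Named list of functions `(x, p)` where `x` is the state
#'   matrix (rows = times, columns = states) and `p` the linear-scale
#'   parameters; each returns the readout trajectory.
#' @param constants Named list of fixed quantities available to `rhs`,
#'   `initial_state` and readouts (not estimated).
#' @param compiled Optional list describing a compiled right-hand side for
#'   [deSolve::ode()]: `func`, `initfunc`, `dllname` and `parms`, the latter a
#'   function `(p, u)` building the double vector the compiled code expects.
#' @param spec Optional declarative specification (see [model_from_spec()])
#'   kept for round-tripping with [write_model_spec()].
#' @return An object of class `pls_model`.
#' @seealso [model_from_spec()], [insilico_model()], [dsalina_model()]
#' @export
dynamic_model <- function(name, states, params, rhs, initial_state, readouts,
                          constants = list(), compiled = NULL, spec = NULL) {
  if (!length(states) || anyDuplicated(states)) {
    abort("state labels must be non-empty and unique", class = "plsens_config_error")
  }
  if (!length(params) || anyDuplicated(params)) {
    abort("parameter labels must be non-empty and unique", class = "plsens_config_error")
  }
  if (length(intersect(states, params))) {
    abort("state and parameter labels must not overlap", class = "plsens_config_error")
  }
  stopifnot(is.function(rhs), is.function(initial_state), is.list(readouts))
  if (is.null(names(readouts)) || any(names(readouts) == "")) {
    abort("readouts must be a named list of functions", class = "plsens_config_error")
  }
  structure(
    list(name = name, state_labels = states, param_labels = params,
         rhs = rhs, initial_state = initial_state, readouts = readouts,
         constants = constants, compiled = compiled, spec = spec),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$name, "\n", sep = "")
  cat("  states:     ", paste(x$state_labels, collapse = ", "), "\n", sep = "")
  cat("  parameters: ", paste(x$param_labels, collapse = ", "), "\n", sep = "")
  cat("  readouts:   ", paste(names(x$readouts), collapse = ", "), "\n", sep = "")
  if (length(x$constants)) {
    cat("  constants:  ",
        paste(names(x$constants), unlist(x$constants), sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Check a model at a concrete parameter vector
#'
#' Evaluates the right-hand side at the initial state and verifies the result
#' is finite — a cheap structural sanity check before expensive analyses.
#'
#' @param model A [dynamic_model()].
#' @param params Named log10 parameter vector.
#' @param u Stimulus value used for the check.
#' @return `TRUE` invisibly; aborts otherwise.
#' @export
validate_model <- function(model, params, u = 0) {
  params <- as_log10_params(params, model)
  p <- linear_params(params, model)
  x0 <- model$initial_state(p)
  if (length(x0) != length(model$state_labels)) {
    abort("initial_state must return one value per state", class = "plsens_config_error")
  }
  dx <- model$rhs(0, setNames(as.numeric(x0), model$state_labels), p, u)
  if (length(dx) != length(x0) || any(!is.finite(dx))) {
    abort("rhs at the initial state is not a finite vector", class = "plsens_config_error")
  }
  invisible(TRUE)
}

#' Stimulus (input) profile u(t)
#'
#' Either a constant input or a single rectangular pulse, e.g. the 1 s
#' actinic light pulse of 166 uE m-2 s-1 used for fluorescence induction.
#'
#' @param kind `"constant"` or `"pulse"`.
#' @param amplitude Input amplitude (>= 0), in the input's natural units
#'   (e.g. uE m-2 s-1 for light).
#' @param start Pulse onset time in seconds (pulse only).
#' @param duration Pulse duration in seconds (> 0 for a pulse).
#' @return A `pls_stimulus` object.
#' @export
stimulus_profile <- function(kind = c("constant", "pulse"), amplitude,
                             start = 0, duration = Inf) {
  kind <- match.arg(kind)
  if (amplitude < 0) abort("stimulus amplitude must be >= 0", class = "plsens_config_error")
  if (kind == "pulse" && !(duration > 0)) {
    abort("pulse duration must be > 0", class = "plsens_config_error")
  }
  structure(list(kind = kind, amplitude = amplitude, start = start,
                 duration = duration),
            class = "pls_stimulus")
}

# Times at which u(t) is discontinuous (integration is split there).
stimulus_breaks <- function(stim) {
  if (stim$kind == "constant") return(numeric(0))
  b <- c(stim$start, stim$start + stim$duration)
  b[is.finite(b)]
}

# u(t) evaluated in the open interior of a segment.
stimulus_value <- function(stim, t) {
  if (stim$kind == "constant") return(stim$amplitude)
  if (t >= stim$start && t < stim$start + stim$duration) stim$amplitude else 0
}

#' An intervention (inhibition) on one parameter
#'
#' Emulates the action of an inhibitor by scaling the targeted rate constant:
#' the linear-scale parameter value is multiplied by `factor` before
#' integration (default 1e-4, a near-complete knock-down).
#'
#' @param target_param Parameter label to scale.
#' @param factor Positive multiplier on the linear-scale value.
#' @return A `pls_intervention` object.
#' @export
intervention <- function(target_param, factor = 1e-4) {
  if (!is.character(target_param) || length(target_param) != 1) {
    abort("target_param must be a single parameter label", class = "plsens_config_error")
  }
  if (!is.numeric(factor) || length(factor) != 1 || !(factor > 0)) {
    abort("intervention factor must be > 0", class = "plsens_validation_error")
  }
  structure(list(target_param = target_param, factor = factor),
            class = "pls_intervention")
}

#' Apply an intervention to a log10 parameter vector
#'
#' Returns a copy with the target's log10 value shifted by `log10(factor)`
#' (i.e. the linear value multiplied by `factor`); the input is untouched.
#'
#' @param params Named log10 parameter vector.
#' @param iv A [intervention()] or list of them.
#' @return Modified copy of `params`.
#' @export
apply_intervention <- function(params, iv) {
  if (inherits(iv, "pls_intervention")) iv <- list(iv)
  for (one in iv) {
    if (!(one$target_param %in% names(params))) {
      abort(paste0("unknown intervention target: ", one$target_param),
            class = "plsens_config_error")
    }
    if (!(one$factor > 0)) {
      abort("intervention factor must be > 0", class = "plsens_validation_error")
    }
    params[[one$target_param]] <- params[[one$target_param]] + log10(one$factor)
  }
  params
}

#' Describe an experiment
#'
#' The design variables of an experiment: which readouts are recorded, which
#' interventions (inhibitions) are in place, the stimulus profile, and the
#' measurement time points.
#'
#' @param observed Character vector of readout labels (non-empty, unique).
#' @param times Strictly increasing measurement time points, seconds.
#' @param stimulus A [stimulus_profile()].
#' @param interventions List of [intervention()] objects (may be empty).
#' @return A `pls_design` object.
#' @export
experiment_design <- function(observed, times, stimulus, interventions = list()) {
  if (!length(observed) || anyDuplicated(observed)) {
    abort("observed readouts must be non-empty and unique", class = "plsens_config_error")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("measurement times must be strictly increasing", class = "plsens_validation_error")
  }
  if (!inherits(stimulus, "pls_stimulus")) {
    abort("stimulus must be a stimulus_profile()", class = "plsens_config_error")
  }
  if (inherits(interventions, "pls_intervention")) interventions <- list(interventions)
  structure(list(observed = observed, times = as.numeric(times),
                 stimulus = stimulus, interventions = interventions),
            class = "pls_design")
}

#' @export
print.pls_design <- function(x, ...) {
  cat("<pls_design>\n")
  cat("  observed: ", paste(x$observed, collapse = ", "), "\n", sep = "")
  cat("  times:    ", length(x$times), " points on [",
      format(min(x$times)), ", ", format(max(x$times)), "] s\n", sep = "")
  cat("  stimulus: ", x$stimulus$kind, ", amplitude ", x$stimulus$amplitude,
      "\n", sep = "")
  if (length(x$interventions)) {
    cat("  interventions: ",
        paste(vapply(x$interventions, function(iv)
          paste0(iv$target_param, " x ", format(iv$factor)), ""), collapse = "; "),
        "\n", sep = "")
  }
  invisible(x)
}
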