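#' Solver settings
#'
#' Defaults target stiff systems whose rate constants span many orders of
#' magnitude (the fluorescence induction model mixes rates from ~1e-2 to
#' ~3e5 s-1): `lsoda` with absolute tolerance 1e-9 and relative tolerance
#' 1e-7.
#'
#' @param atol Absolute tolerance.
#' @param rtol Relative tolerance.
#' @param method Integration method passed to [deSolve::ode()].
#' @param maxsteps Maximum internal steps per output interval.
#' @return A list of solver settings.
#' @export
solver_control <- function(atol = 1e-9, rtol = 1e-7, method = "lsoda",
                           maxsteps = 50000) {
  list(atol = atol, rtol = rtol, method = method, maxsteps = maxsteps)
}

simulation_failure <- function(model, params, message = "ODE integration failed") {
  abort(message, class = "plsens_simulation_error", model = model$name,
        params = params)
}

#' Simulate a model under an experiment design
#'
#' Integrates the ODE system at the given log10 parameters. Interventions in
#' the design are applied first (linear-scale multiplication of the targeted
#' parameters), the initial state is then derived from the post-intervention
#' parameters, and the stimulus is piecewise constant: integration is split at
#' the pulse edges so the solver never steps across a discontinuity.
#'
#' @param model A [dynamic_model()].
#' @param params Named log10 parameter vector.
#' @param design A [experiment_design()]; its stimulus and interventions are
#'   used, and its `times` are the default evaluation grid.
#' @param eval_times Strictly increasing evaluation times (>= 0); defaults to
#'   `design$times`.
#' @param control [solver_control()] settings.
#' @param use_compiled Use the model's compiled right-hand side when present
#'   (the bundled models ship one); set `FALSE` to force the R-level RHS.
#' @return A `pls_trajectory`: list with `times`, the state matrix `states`
#'   (rows = times, columns = states), the log10 `params` actually simulated
#'   (post-intervention) and their linear-scale version `params_linear`.
#' @export
simulate_model <- function(model, params, design, eval_times = design$times,
                           control = solver_control(), use_compiled = TRUE) {
  params <- as_log10_params(params, model)
  if (length(design$interventions)) {
    params <- apply_intervention(params, design$interventions)
  }
  if (is.unsorted(eval_times, strictly = TRUE)) {
    abort("eval_times must be strictly increasing", class = "plsens_validation_error")
  }
  if (min(eval_times) < 0) {
    abort("eval_times must be >= 0", class = "plsens_validation_error")
  }
  p <- linear_params(params, model)
  x0 <- model$initial_state(p)
  x0 <- setNames(as.numeric(x0), model$state_labels)
  if (any(!is.finite(x0))) simulation_failure(model, params, "non-finite initial state")

  tmax <- max(eval_times)
  breaks <- stimulus_breaks(design$stimulus)
  bounds <- sort(unique(c(0, breaks[breaks > 0 & breaks < tmax], tmax)))
  if (tmax == 0) bounds <- c(0, 0) # degenerate: only t = 0 requested

  compiled <- if (isTRUE(use_compiled)) model$compiled else NULL
  out_times <- numeric(0)
  out_states <- NULL
  y <- x0
  for (seg in seq_len(length(bounds) - 1)) {
    a <- bounds[seg]; b <- bounds[seg + 1]
    if (b <= a) next
    u_seg <- stimulus_value(design$stimulus, a)
    seg_times <- sort(unique(c(a, eval_times[eval_times > a & eval_times <= b], b)))
    sol <- tryCatch(
      {
        if (!is.null(compiled)) {
          deSolve::ode(y = y, times = seg_times, func = compiled$func,
                       parms = compiled$parms(p, u_seg),
                       dllname = compiled$dllname, initfunc = compiled$initfunc,
                       method = control$method, atol = control$atol,
                       rtol = control$rtol, maxsteps = control$maxsteps)
        } else {
          deSolve::ode(y = y, times = seg_times,
                       func = function(t, yy, parms) {
                         list(model$rhs(t, setNames(yy, model$state_labels), p, u_seg))
                       },
                       parms = NULL, method = control$method,
                       atol = control$atol, rtol = control$rtol,
                       maxsteps = control$maxsteps)
        }
      },
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(sol) || nrow(sol) < length(seg_times) || any(!is.finite(sol))) {
      simulation_failure(model, params)
    }
    states <- sol[, -1, drop = FALSE]
    colnames(states) <- model$state_labels
    out_times <- c(out_times, seg_times)
    out_states <- rbind(out_states, states)
    y <- setNames(as.numeric(states[nrow(states), ]), model$state_labels)
  }
  # collect requested rows (t = 0 row is the initial state itself)
  if (is.null(out_states)) {
    out_times <- 0
    out_states <- matrix(x0, nrow = 1, dimnames = list(NULL, model$state_labels))
  }
  idx <- match(eval_times, out_times)
  if (anyNA(idx)) simulation_failure(model, params, "solver did not return all requested times")
  structure(
    list(times = eval_times, states = out_states[idx, , drop = FALSE],
         params = params, params_linear = p, model = model$name),
    class = "pls_trajectory"
  )
}

#' Evaluate a readout on a simulated trajectory
#'
#' Applies the model's readout function g pointwise, e.g. the fluorescence
#' readout F = G * k2 * x1 for the induction model.
#'
#' @param model A [dynamic_model()].
#' @param traj A `pls_trajectory` from [simulate_model()].
#' @param label Readout label defined on the model (a state label is also
#'   accepted and returns that state's trajectory).
#' @return Numeric readout trajectory at `traj$times`.
#' @export
evaluate_readout <- function(model, traj, label) {
  if (label %in% names(model$readouts)) {
    as.numeric(model$readouts[[label]](traj$states, traj$params_linear))
  } else if (label %in% model$state_labels) {
    as.numeric(traj$states[, label])
  } else {
    abort(paste0("undefined readout label: ", label), class = "plsens_config_error")
  }
}

#' @export
tidy.pls_trajectory <- function(x, ...) {
  states <- as_tibble(as.data.frame(x$states))
  out <- dplyr::mutate(states, time = x$times, .before = 1)
  tidyr::pivot_longer(out, -"time", names_to = "state", values_to = "value")
}
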