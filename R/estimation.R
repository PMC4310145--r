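#' Weighted residual sum of squares
#'
#' The objective chi2(theta) = sum over records of
#' `((mean - predicted) / sd)^2`. Under the additive Gaussian noise model
#' this is -2 log L up to a constant, so its minimiser is the maximum
#' likelihood estimate.
#'
#' @param data A dataset (see [as_pls_dataset()]).
#' @param predicted Data frame with columns `time`, `readout`, `value` and
#'   (if `data` has several conditions) `condition`, giving the model
#'   prediction for every record of `data`.
#' @return Non-negative scalar.
#' @export
chi_squared <- function(data, predicted) {
  data <- as_pls_dataset(data, check_order = FALSE)
  predicted <- as_tibble(predicted)
  if (!("condition" %in% names(predicted))) predicted$condition <- "base"
  if (!("value" %in% names(predicted))) {
    abort("predicted must carry a value column", class = "plsens_alignment_error")
  }
  joined <- dplyr::left_join(
    data, predicted[c("condition", "readout", "time", "value")],
    by = c("condition", "readout", "time")
  )
  if (anyNA(joined$value)) {
    abort("missing prediction for some data records", class = "plsens_alignment_error")
  }
  sum(((joined$mean - joined$value) / joined$sd)^2)
}

#' Model predictions aligned to a dataset
#'
#' Simulates each experimental condition once at the requested parameters and
#' returns the predicted readout value for every record of `data`.
#'
#' @param model A [dynamic_model()].
#' @param params Named log10 parameter vector.
#' @param data A dataset.
#' @param designs A single [experiment_design()] (applied to every condition)
#'   or a named list of designs keyed by condition.
#' @param control [solver_control()].
#' @param use_compiled Passed to [simulate_model()].
#' @return `data` with an added `value` column.
#' @export
predict_observations <- function(model, params, data, designs,
                                 control = solver_control(),
                                 use_compiled = TRUE) {
  data <- as_pls_dataset(data)
  designs <- normalize_designs(designs, data)
  out <- vector("list", length(designs))
  names(out) <- names(designs)
  for (cond in unique(data$condition)) {
    d_cond <- data[data$condition == cond, ]
    design <- designs[[cond]]
    times <- sort(unique(d_cond$time))
    positive <- times[times > 0]
    traj <- simulate_model(model, params, design, eval_times = positive,
                           control = control, use_compiled = use_compiled)
    # t = 0 records come straight from the (parameter-dependent) initial state
    if (length(positive) < length(times)) {
      p <- traj$params_linear
      x0 <- setNames(as.numeric(model$initial_state(p)), model$state_labels)
      traj$states <- rbind(matrix(x0, nrow = 1, dimnames = list(NULL, model$state_labels)),
                           traj$states)
      traj$times <- c(0, traj$times)
    }
    vals <- numeric(nrow(d_cond))
    for (lab in unique(d_cond$readout)) {
      y <- evaluate_readout(model, traj, lab)
      sel <- d_cond$readout == lab
      vals[sel] <- y[match(d_cond$time[sel], traj$times)]
    }
    d_cond$value <- vals
    out[[cond]] <- d_cond
  }
  dplyr::bind_rows(out)
}

normalize_designs <- function(designs, data) {
  conds <- unique(data$condition)
  if (inherits(designs, "pls_design")) {
    designs <- setNames(rep(list(designs), length(conds)), conds)
  }
  missing <- setdiff(conds, names(designs))
  if (length(missing)) {
    abort(paste0("no design for condition(s): ", paste(missing, collapse = ", ")),
          class = "plsens_config_error")
  }
  designs[conds]
}

#' Optimiser settings for [fit_mle()]
#'
#' Bounded trust-region (Levenberg-Marquardt) least squares on the log10
#' parameters; tolerances 1e-8 on objective and step, at most 500 iterations
#' per start.
#'
#' @param ftol,ptol Convergence tolerances on the objective and the step.
#' @param maxiter Maximum iterations per start.
#' @param penalty Residual value substituted when a simulation fails during
#'   optimisation (the step is effectively rejected rather than fatal).
#' @return A list of settings.
#' @export
fit_control <- function(ftol = 1e-8, ptol = 1e-8, maxiter = 500, penalty = 1e4) {
  list(ftol = ftol, ptol = ptol, maxiter = maxiter, penalty = penalty)
}

# Residual closure shared by fitting and profiling. The data/trajectory
# alignment is resolved once up front, and conditions whose dynamics are
# indistinguishable (same stimulus and interventions — observing different
# readouts does not change the trajectory) share a single simulation per
# evaluation. This closure sits in the innermost optimiser loop.
make_residual_fn <- function(model, data, designs, control, fit_ctrl,
                             use_compiled = TRUE) {
  data <- as_pls_dataset(data)
  designs <- normalize_designs(designs, data)
  conds <- unique(data$condition)
  sig <- vapply(conds, function(cond) {
    d <- designs[[cond]]
    paste(d$stimulus$kind, d$stimulus$amplitude, d$stimulus$start,
          d$stimulus$duration,
          paste(vapply(d$interventions, function(iv)
            paste0(iv$target_param, "*", iv$factor), ""), collapse = ";"),
          sep = "|")
  }, "")
  state_labels <- model$state_labels
  constants_vec <- if (length(model$constants)) unlist(model$constants)
  compiled <- if (isTRUE(use_compiled)) model$compiled else NULL
  p_names <- c(model$param_labels, names(constants_vec))
  parm_idx <- if (!is.null(compiled) && !is.null(compiled$parm_names)) {
    match(compiled$parm_names, p_names)
  }
  plan <- lapply(split(conds, sig), function(gconds) {
    times <- sort(unique(data$time[data$condition %in% gconds]))
    positive <- times[times > 0]
    design <- designs[[gconds[1]]]
    # pre-resolved integration segments: u is constant within each, the
    # output grid is fixed, and `keep` marks the rows that are data times
    tmax <- max(times)
    breaks <- stimulus_breaks(design$stimulus)
    bounds <- sort(unique(c(0, breaks[breaks > 0 & breaks < tmax], tmax)))
    segs <- list()
    for (i in seq_len(length(bounds) - 1)) {
      a <- bounds[i]; b <- bounds[i + 1]
      if (b <= a) next
      st <- sort(unique(c(a, positive[positive > a & positive <= b], b)))
      segs[[length(segs) + 1]] <-
        list(times = st, u = stimulus_value(design$stimulus, a),
             keep = which(st %in% positive))
    }
    iv_shift <- setNames(numeric(length(model$param_labels)),
                         model$param_labels)
    for (iv in design$interventions) {
      iv_shift[[iv$target_param]] <- iv_shift[[iv$target_param]] +
        log10(iv$factor)
    }
    sub <- lapply(gconds, function(cond) {
      d <- data[data$condition == cond, ]
      idx <- lapply(unique(d$readout), function(lab) {
        sel <- which(d$readout == lab)
        list(rows = sel, tidx = match(d$time[sel], times))
      })
      names(idx) <- unique(d$readout)
      list(cond = cond, idx = idx, mean = d$mean, sd = d$sd, n = nrow(d))
    })
    list(design = design, segs = segs, iv_shift = iv_shift,
         n_positive = length(positive),
         has0 = length(positive) < length(times), sub = sub)
  })
  total_n <- nrow(data)

  sim_states <- function(theta, pl) {
    # lean equivalent of simulate_model() for repeated evaluation: same
    # solver, tolerances and segmentation, without per-call re-validation
    p <- 10^(theta + pl$iv_shift)
    if (!is.null(constants_vec)) p <- c(p, constants_vec)
    x0 <- as.numeric(model$initial_state(p))
    if (any(!is.finite(x0))) return(NULL)
    y <- x0
    states <- matrix(NA_real_, nrow = pl$n_positive + pl$has0,
                     ncol = length(state_labels),
                     dimnames = list(NULL, state_labels))
    row0 <- 0L
    if (pl$has0) {
      states[1L, ] <- x0
      row0 <- 1L
    }
    for (sg in pl$segs) {
      sol <- tryCatch({
        if (!is.null(compiled)) {
          pv <- if (!is.null(parm_idx)) c(p[parm_idx], sg$u) else
            compiled$parms(p, sg$u)
          deSolve::lsoda(y, sg$times, func = compiled$func,
                         parms = pv,
                         dllname = compiled$dllname,
                         initfunc = compiled$initfunc,
                         atol = control$atol, rtol = control$rtol,
                         maxsteps = control$maxsteps)
        } else {
          u_seg <- sg$u
          deSolve::lsoda(y, sg$times, func = function(t, yy, parms) {
            list(model$rhs(t, setNames(yy, state_labels), p, u_seg))
          }, parms = NULL, atol = control$atol, rtol = control$rtol,
          maxsteps = control$maxsteps)
        }
      }, error = function(e) NULL, warning = function(w) NULL)
      if (is.null(sol) || nrow(sol) < length(sg$times) || any(!is.finite(sol))) {
        return(NULL)
      }
      nk <- length(sg$keep)
      if (nk) {
        states[row0 + seq_len(nk), ] <- sol[sg$keep, -1, drop = FALSE]
        row0 <- row0 + nk
      }
      y <- sol[nrow(sol), -1]
    }
    states
  }

  function(theta) {
    out <- vector("list", length(conds))
    names(out) <- conds
    for (pl in plan) {
      states <- sim_states(theta, pl)
      if (is.null(states)) return(rep(fit_ctrl$penalty, total_n))
      p <- 10^(theta + pl$iv_shift)
      if (!is.null(constants_vec)) p <- c(p, constants_vec)
      for (s in pl$sub) {
        v <- numeric(s$n)
        for (lab in names(s$idx)) {
          y <- if (lab %in% colnames(states)) {
            states[, lab]
          } else {
            model$readouts[[lab]](states, p)
          }
          v[s$idx[[lab]]$rows] <- y[s$idx[[lab]]$tidx]
        }
        out[[s$cond]] <- (s$mean - v) / s$sd
      }
    }
    out <- unlist(out, use.names = FALSE)
    out[!is.finite(out)] <- fit_ctrl$penalty
    out
  }
}

#' Maximum-likelihood estimation by multi-start local least squares
#'
#' Runs `n_starts` bounded Levenberg-Marquardt optimisations of the weighted
#' residual sum of squares. The first start is the user-supplied guess
#' (unperturbed); the remaining starts are drawn by Latin-hypercube sampling
#' inside the bounds. Parameter bounds default to a box of half-width
#' `bound_width` log10 units around the start (matching the default profiling
#' range). Reproducible under a fixed seed.
#'
#' @param model A [dynamic_model()].
#' @param data A dataset.
#' @param designs A design or named list of designs by condition.
#' @param start Named log10 parameter vector used as first start and bounds
#'   centre.
#' @param n_starts Number of local optimisations (>= 1).
#' @param seed Integer seed for the start sampling.
#' @param bounds Optional list with named vectors `lower`, `upper` (log10).
#' @param bound_width Half-width of the default bounds box, log10 units.
#' @param control [fit_control()] optimiser settings.
#' @param solver [solver_control()] integration settings.
#' @param shake After the local optimisations, explore the sloppy valley by
#'   short conditional re-optimisations at coordinate offsets around the
#'   winner and restart from any deeper point found (repeated while it
#'   helps). Trust-region steps alone routinely stall in shallow side basins
#'   of multimodal sum-of-squares surfaces; this cheap sweep makes chi2_min
#'   a trustworthy reference for profile thresholds.
#' @return A `pls_fit` object: the estimate `par`, `chi2_min`, a per-start
#'   table, and everything needed to profile the fit later.
#' @export
fit_mle <- function(model, data, designs, start, n_starts = 20, seed = 1,
                    bounds = NULL, bound_width = 3,
                    control = fit_control(), solver = solver_control(),
                    shake = TRUE) {
  if (n_starts < 1) abort("n_starts must be >= 1", class = "plsens_validation_error")
  data <- as_pls_dataset(data)
  designs <- normalize_designs(designs, data)
  start <- as_log10_params(start, model)
  if (is.null(bounds)) {
    bounds <- list(lower = start - bound_width, upper = start + bound_width)
  }
  lower <- as_log10_params(bounds$lower, model)
  upper <- as_log10_params(bounds$upper, model)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    abort("bounds must be finite with lower < upper", class = "plsens_validation_error")
  }
  np <- length(start)
  starts <- matrix(start, nrow = 1)
  if (n_starts > 1) {
    unit <- withr::with_seed(seed, lhs::randomLHS(n_starts - 1, np))
    starts <- rbind(starts,
                    sweep(sweep(unit, 2, upper - lower, "*"), 2, lower, "+"))
  }
  colnames(starts) <- names(start)

  resid_fn <- make_residual_fn(model, data, designs, solver, control)
  runs <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    th0 <- pmin(pmax(starts[i, ], lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = control$ftol, ptol = control$ptol,
                           maxiter = control$maxiter)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      runs[[i]] <- list(par = th0, chi2 = Inf, converged = FALSE,
                        message = "optimizer error")
    } else {
      runs[[i]] <- list(par = setNames(as.numeric(res$par), names(start)),
                        chi2 = res$deviance,
                        converged = res$info %in% 1:4,
                        message = res$message)
    }
  }
  chis <- vapply(runs, function(r) r$chi2, numeric(1))
  if (all(!is.finite(chis))) {
    abort("all optimisation starts failed", class = "plsens_estimation_error",
          diagnostics = vapply(runs, function(r) r$message, ""))
  }
  best <- which.min(chis)
  # polish the winner: restarting the trust-region iteration from the
  # current point escapes stalls on sloppy ridges; repeat while it helps
  for (round in seq_len(5)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = runs[[best]]$par, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = control$ftol, ptol = control$ptol,
                           maxiter = control$maxiter)),
      error = function(e) NULL
    )
    if (is.null(res)) break
    gain <- runs[[best]]$chi2 - res$deviance
    runs[[best]] <- list(par = setNames(as.numeric(res$par), names(start)),
                         chi2 = res$deviance, converged = res$info %in% 1:4,
                         message = res$message)
    if (!is.finite(gain) || gain < 1e-6 * max(1, res$deviance)) break
  }
  chis[best] <- runs[[best]]$chi2

  if (isTRUE(shake)) {
    # coordinate-wise valley exploration: fix one parameter at an offset,
    # briefly re-optimise the rest, and restart the full fit from any
    # deeper point. Escapes shallow side basins along sloppy ridges.
    offsets <- c(-2, -1, -0.5, -0.2, 0.2, 0.5, 1, 2)
    for (sweep in seq_len(3)) {
      cur <- runs[[best]]
      found <- NULL
      for (pn in names(start)) {
        free <- setdiff(names(start), pn)
        if (!length(free)) next
        for (dv in offsets) {
          v <- cur$par[[pn]] + dv
          if (v < lower[[pn]] || v > upper[[pn]]) next
          fn <- function(tf) {
            full <- c(setNames(v, pn), setNames(tf, free))[names(start)]
            resid_fn(full)
          }
          r <- tryCatch(
            minpack.lm::nls.lm(par = cur$par[free], lower = lower[free],
                               upper = upper[free], fn = fn,
                               control = minpack.lm::nls.lm.control(
                                 ftol = control$ftol, ptol = control$ptol,
                                 maxiter = 40)),
            error = function(e) NULL
          )
          if (!is.null(r) && r$deviance < cur$chi2 - 1e-2 &&
              (is.null(found) || r$deviance < found$chi2)) {
            found <- list(par = c(setNames(v, pn),
                                  setNames(as.numeric(r$par), free))[names(start)],
                          chi2 = r$deviance)
          }
        }
      }
      if (is.null(found)) break
      r <- tryCatch(
        minpack.lm::nls.lm(par = found$par, lower = lower, upper = upper,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             ftol = control$ftol, ptol = control$ptol,
                             maxiter = control$maxiter)),
        error = function(e) NULL
      )
      if (is.null(r) || r$deviance >= runs[[best]]$chi2) break
      runs[[best]] <- list(par = setNames(as.numeric(r$par), names(start)),
                           chi2 = r$deviance, converged = r$info %in% 1:4,
                           message = r$message)
      chis[best] <- r$deviance
    }
  }
  starts_table <- tibble(
    start = seq_len(n_starts),
    chi2 = chis,
    converged = vapply(runs, function(r) r$converged, logical(1)),
    message = vapply(runs, function(r) r$message, character(1))
  )
  structure(
    list(par = runs[[best]]$par, chi2_min = chis[best], starts = starts_table,
         seed = seed, start = start, bounds = list(lower = lower, upper = upper),
         model = model, data = data, designs = designs,
         control = control, solver = solver, n_obs = nrow(data)),
    class = "pls_fit"
  )
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("<pls_fit> ", x$model$name, ": chi2_min = ", format(x$chi2_min),
      " (", x$n_obs, " records, ", length(x$par), " parameters, ",
      nrow(x$starts), " starts)\n", sep = "")
  print(round(x$par, 4))
  invisible(x)
}

#' @export
tidy.pls_fit <- function(x, ...) {
  tibble(term = names(x$par), estimate = as.numeric(x$par))
}

#' @export
glance.pls_fit <- function(x, ...) {
  tibble(chi2_min = x$chi2_min, n_obs = x$n_obs, n_par = length(x$par),
         df_residual = x$n_obs - length(x$par),
         n_starts = nrow(x$starts), n_converged = sum(x$starts$converged),
         seed = x$seed)
}
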