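#' Prediction ensemble from profile-likelihood samples
#'
#' Simulates the model once per parameter sample (and once at the estimate)
#' and extracts a single prediction — a state or readout trajectory — on a
#' common time grid. The pointwise extremes of the ensemble approximate the
#' confidence band of the prediction induced by the sampled parameter's
#' uncertainty.
#'
#' @param model A [dynamic_model()].
#' @param samples A `pls_samples` from [profile_samples()].
#' @param design A [experiment_design()] providing stimulus/interventions.
#' @param prediction State or readout label to extract.
#' @param times Prediction time grid (strictly increasing, > 0).
#' @param theta_hat Estimate used for the reference trajectory (default: the
#'   one stored with the samples).
#' @param control [solver_control()].
#' @return A `pls_ensemble`: `times`, matrix `trajectories` (rows = samples),
#'   `mle` trajectory, `prediction` and `param` labels.
#' @export
prediction_ensemble <- function(model, samples, design, prediction, times,
                                theta_hat = attr(samples, "theta_hat"),
                                control = solver_control()) {
  if (!nrow(samples)) abort("empty sample set", class = "plsens_sampling_error")
  par_names <- model$param_labels
  sims <- vector("list", nrow(samples))
  dropped <- 0L
  for (i in seq_len(nrow(samples))) {
    th <- unlist(samples[i, par_names])
    sims[[i]] <- tryCatch({
      traj <- simulate_model(model, th, design, eval_times = times,
                             control = control)
      evaluate_readout(model, traj, prediction)
    }, plsens_simulation_error = function(e) NULL)
    if (is.null(sims[[i]])) dropped <- dropped + 1L
  }
  if (dropped > 0) {
    warn(paste0(dropped, " sample(s) dropped after simulation failure"))
  }
  keep <- !vapply(sims, is.null, logical(1))
  if (!any(keep)) abort("all ensemble simulations failed", class = "plsens_ensemble_error")
  traj_hat <- simulate_model(model, theta_hat, design, eval_times = times,
                             control = control)
  structure(
    list(prediction = prediction, param = attr(samples, "param"),
         times = times,
         trajectories = do.call(rbind, sims[keep]),
         mle = evaluate_readout(model, traj_hat, prediction)),
    class = "pls_ensemble"
  )
}

# trapezoidal time average (grids may be non-uniform, e.g. log-spaced)
trapz_mean <- function(times, y) {
  if (length(times) == 1) return(y[1])
  dt <- diff(times)
  sum(dt * (head(y, -1) + tail(y, -1)) / 2) / (max(times) - min(times))
}

#' Profile-likelihood sensitivity index
#'
#' The PLS index of parameter theta_i for prediction p at time t_k is the
#' squared spread of the prediction ensemble, normalised by the time-averaged
#' reference trajectory:
#' \deqn{s_i(t_k) = \left(\frac{\max(\{p_i(t_k)\}) - \min(\{p_i(t_k)\})}{\langle \hat p(t)\rangle_t}\right)^2}
#' where the extremes run over predictions sampled along theta_i's profile
#' likelihood and the denominator is the trapezoidal time average of the
#' prediction at the estimate.
#'
#' @param ens A `pls_ensemble` (or a list with fields `times`,
#'   `trajectories`, `mle`).
#' @return Numeric vector s_i(t_k), one value per time.
#' @export
pls_index <- function(ens) {
  denom <- trapz_mean(ens$times, ens$mle)
  if (abs(denom) < 1e-12) {
    abort("time-averaged reference prediction is (numerically) zero",
          class = "plsens_degenerate_denominator_error")
  }
  spread <- apply(ens$trajectories, 2, max) - apply(ens$trajectories, 2, min)
  (spread / denom)^2
}

#' Total PLS index
#'
#' Sum of the PLS indices over all parameters and all prediction times:
#' the overall uncertainty of one prediction.
#'
#' @param s Matrix of PLS indices, rows = parameters, columns = times (or a
#'   list of equal-length index vectors, one per parameter).
#' @return Non-negative scalar.
#' @export
pls_total <- function(s) {
  if (is.list(s)) {
    lens <- lengths(s)
    if (length(unique(lens)) != 1) {
      abort("PLS index vectors must share their length", class = "plsens_validation_error")
    }
    s <- do.call(rbind, s)
  }
  sum(s)
}

#' PLS entropy
#'
#' Shannon entropy of the per-time, column-normalised PLS indices: at each
#' time the indices are normalised to sum to one across parameters,
#' \deqn{J_k = \sum_i -\tilde s_i(t_k) \log \tilde s_i(t_k)},
#' with 0 log 0 := 0 and natural logarithm; J_tot is the sum over times.
#' High entropy means the prediction uncertainty at that time is spread
#' homogeneously over many parameters; J_k is at most log(n_parameters).
#' Columns whose indices are all zero contribute J_k = 0.
#'
#' @param s Matrix of PLS indices, rows = parameters, columns = times.
#' @param normalize Divide entropies by `log(nrow(s))` so different
#'   parameter counts are comparable (default `FALSE`).
#' @return List with `s_tilde` (column-normalised matrix), `J_k` (per-time
#'   entropy) and `J_tot`.
#' @export
pls_entropy <- function(s, normalize = FALSE) {
  if (!is.matrix(s)) s <- matrix(s, nrow = 1)
  if (any(s < 0)) abort("PLS indices must be >= 0", class = "plsens_validation_error")
  col_sums <- colSums(s)
  zero_cols <- col_sums == 0
  if (any(zero_cols)) {
    inform(paste0(sum(zero_cols), " time point(s) with all-zero PLS indices (J_k set to 0)"))
  }
  s_tilde <- sweep(s, 2, ifelse(zero_cols, 1, col_sums), "/")
  terms <- ifelse(s_tilde > 0, -s_tilde * log(s_tilde), 0)
  J_k <- colSums(terms)
  J_k[zero_cols] <- 0
  if (isTRUE(normalize) && nrow(s) > 1) J_k <- J_k / log(nrow(s))
  list(s_tilde = s_tilde, J_k = J_k, J_tot = sum(J_k))
}

#' Full PLS analysis over a set of predictions
#'
#' Assembles, for each requested prediction, the matrix of PLS indices
#' (rows = parameters, columns = prediction times) from per-parameter
#' profile-likelihood samples, together with the totals s_tot and J_tot —
#' the coordinates of a candidate prediction in the design criterion space.
#' Each sample is simulated once and every prediction extracted from the same
#' trajectory.
#'
#' @param model A [dynamic_model()].
#' @param samples Named list of `pls_samples`, one per parameter (see
#'   [profile_samples()]).
#' @param design A [experiment_design()].
#' @param predictions Character vector of state/readout labels.
#' @param times Prediction time grid.
#' @param theta_hat Estimate for the reference trajectory (default: stored in
#'   the first sample set).
#' @param control [solver_control()].
#' @param normalize_entropy Passed to [pls_entropy()].
#' @return Named list of `pls_result` objects (one per prediction), class
#'   `pls_summary`. Each has fields `prediction`, `s`, `s_tilde`, `s_tot`,
#'   `J_k`, `J_tot`, `times`, `params`.
#' @export
pls_summary <- function(model, samples, design, predictions, times,
                        theta_hat = attr(samples[[1]], "theta_hat"),
                        control = solver_control(), normalize_entropy = FALSE) {
  stopifnot(length(samples) >= 1, !is.null(names(samples)))
  par_names <- model$param_labels
  traj_hat <- simulate_model(model, theta_hat, design, eval_times = times,
                             control = control)
  mle <- lapply(predictions, function(p) evaluate_readout(model, traj_hat, p))
  names(mle) <- predictions

  # spread (max - min over samples) per parameter and prediction
  spreads <- lapply(predictions, function(p)
    matrix(NA_real_, nrow = length(samples), ncol = length(times),
           dimnames = list(names(samples), NULL)))
  names(spreads) <- predictions
  for (i in seq_along(samples)) {
    smp <- samples[[i]]
    lo <- hi <- NULL
    kept <- 0L
    for (r in seq_len(nrow(smp))) {
      th <- unlist(smp[r, par_names])
      ys <- tryCatch({
        traj <- simulate_model(model, th, design, eval_times = times,
                               control = control)
        lapply(predictions, function(p) evaluate_readout(model, traj, p))
      }, plsens_simulation_error = function(e) NULL)
      if (is.null(ys)) next
      kept <- kept + 1L
      ym <- do.call(rbind, ys)
      if (is.null(lo)) {
        lo <- ym; hi <- ym
      } else {
        lo <- pmin(lo, ym); hi <- pmax(hi, ym)
      }
    }
    if (kept == 0L) {
      abort(paste0("all ensemble simulations failed for parameter ",
                   names(samples)[i]),
            class = "plsens_ensemble_error")
    }
    if (kept < nrow(smp)) {
      warn(paste0(nrow(smp) - kept, " sample(s) dropped for parameter ",
                  names(samples)[i]))
    }
    for (j in seq_along(predictions)) {
      spreads[[j]][i, ] <- hi[j, ] - lo[j, ]
    }
  }

  out <- lapply(predictions, function(p) {
    denom <- trapz_mean(times, mle[[p]])
    if (abs(denom) < 1e-12) {
      abort(paste0("time-averaged reference prediction of ", p,
                   " is (numerically) zero"),
            class = "plsens_degenerate_denominator_error")
    }
    s <- (spreads[[p]] / denom)^2
    ent <- pls_entropy(s, normalize = normalize_entropy)
    structure(
      list(prediction = p, s = s, s_tilde = ent$s_tilde, s_tot = sum(s),
           J_k = ent$J_k, J_tot = ent$J_tot, times = times,
           params = names(samples)),
      class = "pls_result"
    )
  })
  names(out) <- predictions
  structure(out, class = "pls_summary")
}

#' Criterion-space coordinates of a PLS analysis
#'
#' @param results A `pls_summary` (or list of `pls_result`).
#' @return Tibble with columns `prediction`, `s_tot`, `J_tot`.
#' @export
criterion_space <- function(results) {
  dplyr::bind_rows(lapply(unclass(results), function(r)
    tibble(prediction = r$prediction, s_tot = r$s_tot, J_tot = r$J_tot)))
}

#' @export
print.pls_result <- function(x, ...) {
  cat("<pls_result> prediction ", x$prediction, ": s_tot = ",
      format(x$s_tot, digits = 5), ", J_tot = ", format(x$J_tot, digits = 5),
      " (", length(x$params), " parameters x ", length(x$times),
      " times)\n", sep = "")
  invisible(x)
}

#' @export
tidy.pls_result <- function(x, ...) {
  tibble(
    prediction = x$prediction,
    param = rep(x$params, times = ncol(x$s)),
    time = rep(x$times, each = nrow(x$s)),
    s = as.numeric(x$s),
    s_tilde = as.numeric(x$s_tilde)
  )
}

#' @export
glance.pls_result <- function(x, ...) {
  tibble(prediction = x$prediction, s_tot = x$s_tot, J_tot = x$J_tot,
         n_params = length(x$params), n_times = length(x$times))
}

#' @export
tidy.pls_summary <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), tidy))
}

#' @export
glance.pls_summary <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), glance))
}
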