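#' Profiling policy
#'
#' Controls the adaptive walk along a profile likelihood. Starting at the
#' estimate, the profiled parameter is stepped outward in both directions and
#' all other parameters are re-optimised at each step (warm-started from the
#' neighbouring point, with one fallback restart from the estimate). The step
#' size adapts by bisection so each accepted step increases the profile by
#' roughly `target_frac * delta_alpha`; it is confined to
#' `[step_min, step_max]` log10 units. A direction stops once the profile
#' exceeds `stop_factor * delta_alpha` above the minimum or the `range` limit
#' is reached. The 0.1 step cap keeps at least 10 profile points per decade
#' on flat (unbounded) branches, which the sampling stage relies on.
#'
#' @param alpha Significance level used for the stop threshold and as the
#'   default for [confidence_interval()].
#' @param df Degrees of freedom of the chi-square threshold (1 = pointwise,
#'   number of parameters = simultaneous).
#' @param step_init,step_min,step_max Initial / smallest / largest step in
#'   log10 units.
#' @param range Maximum distance from the estimate, log10 units.
#' @param stop_factor Stop once the profile rises above
#'   `stop_factor * qchisq(1 - alpha, df)`.
#' @param target_frac Targeted per-step profile increase, as a fraction of
#'   the threshold.
#' @param max_points Cap on grid points per direction.
#' @param maxiter Maximum optimiser iterations per re-optimisation.
#' @param ftol Convergence tolerance of the nuisance re-optimisations;
#'   looser than the fit's because a re-optimum resolved far below the
#'   per-step chi2 target buys nothing.
#' @param refine Refine confidence-interval crossings by root finding on the
#'   re-optimised profile (recommended); otherwise linear interpolation.
#' @return A list of settings.
#' @export
profile_control <- function(alpha = 0.05, df = 1, step_init = 0.02,
                            step_min = 1e-3, step_max = 0.1, range = 3,
                            stop_factor = 1.2, target_frac = 0.1,
                            max_points = 400, maxiter = 50, ftol = 1e-7,
                            refine = TRUE) {
  list(alpha = alpha, df = df, step_init = step_init, step_min = step_min,
       step_max = step_max, range = range, stop_factor = stop_factor,
       target_frac = target_frac, max_points = max_points, maxiter = maxiter,
       ftol = ftol, refine = refine)
}

# Adaptive profile walk shared by the ODE and generic-objective front ends.
# refit(value, warm) must return list(par = full named vector, chi2, converged).
profile_core <- function(theta_hat, chi2_min, param, refit, control) {
  hat_i <- theta_hat[[param]]
  delta <- qchisq(1 - control$alpha, control$df)
  stop_level <- delta * control$stop_factor
  target <- delta * control$target_frac

  # try several warm starts, keep the best re-optimum
  refit_best <- function(value, warms) {
    best <- NULL
    for (w in warms) {
      res <- refit(value, w)
      if (is.null(best) || res$chi2 < best$chi2 ||
          (res$converged && !best$converged && res$chi2 <= best$chi2 + 1e-9)) {
        best <- res
      }
    }
    best
  }

  walk <- function(dir) {
    rows <- list()
    last_par <- theta_hat
    prev_par <- theta_hat
    last_value <- hat_i
    last_chi2 <- chi2_min
    step <- control$step_init
    while (length(rows) < control$max_points) {
      remaining <- control$range - abs(last_value - hat_i)
      if (remaining <= 1e-12) break
      step <- min(step, remaining)
      shrinks <- 0L
      repeat {
        value <- last_value + dir * step
        res <- refit(value, last_par) # warm start from the neighbour
        if (!res$converged || res$chi2 - last_chi2 > 2 * target) {
          # suspicious climb or failure: retry from a linear extrapolation
          # of the optimiser path (ridges are usually locally straight)
          alt <- refit(value, 2 * last_par - prev_par)
          if (alt$chi2 < res$chi2 || (alt$converged && !res$converged)) res <- alt
        }
        if (!res$converged) {
          alt <- refit(value, theta_hat) # fallback restart from the estimate
          if (alt$chi2 <= res$chi2 || alt$converged) res <- alt
        }
        inc <- res$chi2 - last_chi2
        # shrink on steep climbs, but at most twice per point: re-optimiser
        # jitter on flat ridges would otherwise pin the walk at the minimum
        # step and crawl
        if (is.finite(inc) && inc > 2 * target && shrinks < 2L &&
            step / 2 >= control$step_min) {
          step <- step / 2
          shrinks <- shrinks + 1L
        } else {
          break
        }
      }
      if (res$chi2 - chi2_min > stop_level) {
        # a stop ends the branch and decides identifiability: before
        # accepting one, rescue the re-optimisation from fresh starts
        res <- refit_best(value, list(res$par, theta_hat,
                                      (last_par + theta_hat) / 2))
      }
      rows[[length(rows) + 1]] <-
        list(value = value, chi2 = res$chi2, par = res$par,
             converged = res$converged)
      if (res$chi2 - chi2_min > stop_level) break
      if (is.finite(inc) && abs(inc) < target) {
        step <- min(2 * step, control$step_max)
      }
      # anti-crawl: if the last few points moved the profile by less than
      # one step target in total, the branch is flat (or jittery) — stride
      n <- length(rows)
      if (n >= 5 && abs(rows[[n]]$chi2 - rows[[n - 4]]$chi2) < target) {
        step <- min(2 * step, control$step_max)
      }
      prev_par <- last_par
      last_par <- res$par
      last_value <- value
      last_chi2 <- res$chi2
    }
    # backward sweep: chi2_PL is non-decreasing outward, so a point above
    # its outward neighbour marks a failed re-optimisation — retry it,
    # warm-started from that neighbour. Only points near or above the
    # stop threshold matter (they decide bounds); jitter deep inside the
    # confidence region is left alone.
    if (length(rows) > 1) {
      floor_chi2 <- chi2_min + 0.5 * qchisq(1 - control$alpha, control$df)
      for (i in seq(length(rows) - 1, 1)) {
        if (rows[[i]]$chi2 > floor_chi2 &&
            rows[[i]]$chi2 > rows[[i + 1]]$chi2 + 1e-9) {
          res <- refit(rows[[i]]$value, rows[[i + 1]]$par)
          if (res$chi2 < rows[[i]]$chi2) {
            rows[[i]] <- list(value = rows[[i]]$value, chi2 = res$chi2,
                              par = res$par, converged = res$converged)
          }
        }
      }
    }
    rows
  }

  left <- rev(walk(-1))
  right <- walk(1)
  center <- list(list(value = hat_i, chi2 = chi2_min, par = theta_hat,
                      converged = TRUE))
  rows <- c(left, center, right)
  grid <- tibble(
    value = vapply(rows, `[[`, numeric(1), "value"),
    chi2_pl = vapply(rows, `[[`, numeric(1), "chi2"),
    converged = vapply(rows, `[[`, logical(1), "converged")
  )
  paths <- do.call(rbind, lapply(rows, function(r) r$par[names(theta_hat)]))
  colnames(paths) <- names(theta_hat)
  if (!any(grid$converged)) {
    abort(paste0("profiling failed at every point for ", param),
          class = "plsens_profile_error")
  }
  structure(
    list(param = param, theta_hat = theta_hat, chi2_min = chi2_min,
         grid = grid, paths = paths, refit = refit, control = control),
    class = "pls_profile"
  )
}

#' Profile likelihood of one parameter of a fitted model
#'
#' Computes chi2_PL(theta_i) = min over the other parameters of chi2(theta)
#' along an adaptive grid in theta_i, re-optimising the nuisance parameters
#' at every grid point with the same bounded least-squares optimiser used by
#' [fit_mle()].
#'
#' @param fit A `pls_fit` from [fit_mle()].
#' @param param Parameter label to profile.
#' @param control A [profile_control()] policy.
#' @return A `pls_profile` object: the grid of profiled values, chi2_PL, the
#'   re-optimised full parameter vector at every point, and a refit closure
#'   used for threshold-crossing refinement.
#' @export
profile_parameter <- function(fit, param, control = profile_control()) {
  if (!(param %in% names(fit$par))) {
    abort(paste0("unknown parameter: ", param), class = "plsens_config_error")
  }
  all_par <- names(fit$par)
  free <- setdiff(all_par, param)
  resid_fn <- make_residual_fn(fit$model, fit$data, fit$designs, fit$solver,
                               fit$control)
  lower <- fit$bounds$lower[free]
  upper <- fit$bounds$upper[free]
  assemble <- function(value, th_free) {
    full <- c(setNames(value, param), setNames(th_free, free))
    full[all_par]
  }
  refit <- if (length(free) == 0) {
    function(value, warm) {
      full <- setNames(value, param)
      list(par = full, chi2 = sum(resid_fn(full)^2), converged = TRUE)
    }
  } else {
    function(value, warm) {
      th0 <- pmin(pmax(warm[free], lower), upper)
      fn <- function(tf) resid_fn(assemble(value, tf))
      lm_once <- function(par0) tryCatch(
        minpack.lm::nls.lm(par = par0, lower = lower, upper = upper, fn = fn,
                           control = minpack.lm::nls.lm.control(
                             ftol = control$ftol %||% fit$control$ftol,
                             ptol = fit$control$ptol,
                             maxiter = control$maxiter)),
        error = function(e) NULL
      )
      res <- lm_once(th0)
      if (!is.null(res) && res$niter >= control$maxiter) {
        # continuation restart: a fresh trust region often finishes the job
        res2 <- lm_once(res$par)
        if (!is.null(res2) && res2$deviance <= res$deviance) res <- res2
      }
      if (is.null(res)) {
        return(list(par = assemble(value, th0), chi2 = Inf, converged = FALSE))
      }
      list(par = assemble(value, setNames(as.numeric(res$par), free)),
           chi2 = res$deviance, converged = res$info %in% 1:4)
    }
  }
  profile_core(fit$par, fit$chi2_min, param, refit, control)
}

#' Profile likelihood of a generic scalar objective
#'
#' Same adaptive profiling as [profile_parameter()] but for an arbitrary
#' objective function chi2(theta) — useful for surrogate objectives, linear
#' models and cross-checks against closed forms.
#'
#' @param objfun Function of a named parameter vector returning the scalar
#'   objective (-2 log-likelihood scale).
#' @param theta_hat Named vector at (or near) the objective's minimiser.
#' @param param Parameter label to profile.
#' @param chi2_min Objective at `theta_hat`.
#' @param lower,upper Optional named bounds for the nuisance re-optimisation.
#' @param control A [profile_control()] policy.
#' @return A `pls_profile` object.
#' @export
profile_objective <- function(objfun, theta_hat, param,
                              chi2_min = objfun(theta_hat),
                              lower = NULL, upper = NULL,
                              control = profile_control()) {
  all_par <- names(theta_hat)
  free <- setdiff(all_par, param)
  lo <- if (is.null(lower)) rep(-Inf, length(free)) else lower[free]
  hi <- if (is.null(upper)) rep(Inf, length(free)) else upper[free]
  assemble <- function(value, th_free) {
    full <- c(setNames(value, param), setNames(th_free, free))
    full[all_par]
  }
  refit <- if (length(free) == 0) {
    function(value, warm) {
      list(par = setNames(value, param), chi2 = objfun(setNames(value, param)),
           converged = TRUE)
    }
  } else {
    function(value, warm) {
      res <- tryCatch(
        nlminb(start = warm[free],
               objective = function(tf) objfun(assemble(value, tf)),
               lower = lo, upper = hi,
               control = list(iter.max = 500, abs.tol = 0)),
        error = function(e) NULL
      )
      if (is.null(res)) {
        return(list(par = assemble(value, warm[free]), chi2 = Inf,
                    converged = FALSE))
      }
      list(par = assemble(value, res$par), chi2 = res$objective,
           converged = res$convergence == 0)
    }
  }
  profile_core(theta_hat, chi2_min, param, refit, control)
}

#' Profile every parameter of a fit
#'
#' If the profile walks uncover a point materially below the fitted
#' minimum — which happens on sloppy multimodal surfaces, where ridge-path
#' re-optimisation explores further than any local fit — the fit is
#' restarted from that point and all parameters are re-profiled, so the
#' returned profiles are always anchored at the best optimum found
#' (at most `max_rounds` rounds).
#'
#' @param fit A `pls_fit`.
#' @param params Parameter labels to profile (default: all).
#' @param control A [profile_control()] policy.
#' @param max_rounds Maximum profile/refit rounds (1 disables the refit
#'   loop).
#' @return A named list of `pls_profile` objects, class `pls_profiles`,
#'   with the (possibly updated) fit in the `fit` attribute.
#' @export
profile_parameters <- function(fit, params = names(fit$par),
                               control = profile_control(), max_rounds = 2) {
  out <- NULL
  for (round in seq_len(max(1, max_rounds))) {
    out <- lapply(params, function(p) profile_parameter(fit, p, control))
    names(out) <- params
    best <- NULL
    for (pr in out) {
      conv <- pr$grid$converged
      i <- which.min(replace(pr$grid$chi2_pl, !conv, Inf))
      if (length(i) && (is.null(best) || pr$grid$chi2_pl[i] < best$chi2)) {
        best <- list(chi2 = pr$grid$chi2_pl[i], par = pr$paths[i, ])
      }
    }
    # small dips are absorbed by the chi2_ref threshold logic; only a
    # materially deeper optimum (which also moves the anchor estimate)
    # justifies a refit round
    if (is.null(best) || best$chi2 >= fit$chi2_min - 1 ||
        round == max_rounds) {
      break
    }
    inform(paste0("profiling found a deeper optimum (chi2 ",
                  format(best$chi2, digits = 6), " < ",
                  format(fit$chi2_min, digits = 6),
                  "); refitting and re-profiling"))
    fit <- fit_mle(fit$model, fit$data, fit$designs,
                   start = setNames(as.numeric(best$par), names(fit$par)),
                   n_starts = 1, seed = fit$seed, bounds = fit$bounds,
                   control = fit$control, solver = fit$solver, shake = FALSE)
  }
  structure(out, class = "pls_profiles", fit = fit)
}

branch_rows <- function(profile, side = c("lower", "upper")) {
  side <- match.arg(side)
  hat <- profile$theta_hat[[profile$param]]
  g <- profile$grid
  keep <- g$converged & (if (side == "lower") g$value < hat else g$value > hat)
  rows <- which(keep)
  # ordered walking outward from the estimate
  rows[order(abs(g$value[rows] - hat))]
}

#' Profile-likelihood confidence interval of a parameter
#'
#' The interval is the set of values whose profile stays within
#' `qchisq(1 - alpha, df)` of the minimum. Each bound is located by
#' bracketing the first threshold crossing on the profile grid and refining
#' it by root finding on the re-optimised profile (linear interpolation if
#' refinement is disabled). A branch that never crosses the threshold within
#' the profiled range yields an infinite bound, and the parameter is
#' classified practically non-identifiable.
#'
#' @param profile A `pls_profile`.
#' @param alpha Significance level (default: the profiling policy's).
#' @param df Degrees of freedom (default: the profiling policy's).
#' @param chi2_ref Reference (best-known) chi2 the threshold is measured
#'   from. Defaults to the smaller of the fit's chi2_min and the lowest
#'   converged profile value — if the profile walk uncovered a deeper
#'   optimum, the threshold honours it instead of an inflated minimum.
#' @return One-row tibble: `param`, `estimate`, `lower`, `upper`, `alpha`,
#'   `df`, `identifiability`.
#' @export
confidence_interval <- function(profile, alpha = NULL, df = NULL,
                                chi2_ref = NULL) {
  alpha <- alpha %||% profile$control$alpha
  df <- df %||% profile$control$df
  if (sum(profile$grid$converged) < 3) {
    abort("profile has fewer than 3 converged points",
          class = "plsens_insufficient_profile_error")
  }
  ref <- chi2_ref %||%
    min(profile$chi2_min, profile$grid$chi2_pl[profile$grid$converged])
  threshold <- ref + qchisq(1 - alpha, df)
  hat <- profile$theta_hat[[profile$param]]

  find_bound <- function(side) {
    rows <- branch_rows(profile, side)
    if (!length(rows)) return(if (side == "lower") -Inf else Inf)
    g <- profile$grid
    vals <- g$value[rows]; chis <- g$chi2_pl[rows]
    cross <- which(chis > threshold)
    if (!length(cross)) return(if (side == "lower") -Inf else Inf)
    j <- cross[1]
    v_in <- if (j == 1) hat else vals[j - 1]
    c_in <- if (j == 1) profile$chi2_min else chis[j - 1]
    v_out <- vals[j]; c_out <- chis[j]
    if (isTRUE(profile$control$refine) && !is.null(profile$refit) &&
        is.finite(c_out) && c_in <= threshold && c_out > threshold) {
      warm <- if (j == 1) profile$theta_hat else
        profile$paths[match(vals[j - 1], profile$grid$value), ]
      f <- function(v) profile$refit(v, warm)$chi2 - threshold
      root <- tryCatch(
        uniroot(f, lower = min(v_in, v_out), upper = max(v_in, v_out),
                f.lower = if (side == "lower") c_out - threshold else c_in - threshold,
                f.upper = if (side == "lower") c_in - threshold else c_out - threshold,
                tol = max(1e-5, 1e-3 * abs(v_out - v_in)),
                maxiter = 12)$root,
        error = function(e) NULL
      )
      if (!is.null(root)) return(root)
    }
    # linear interpolation of the crossing; a degenerate bracket (failed
    # point, or non-monotone chi2 from re-optimiser jitter) falls back to
    # the outer grid point rather than extrapolating
    if (!is.finite(c_out) || c_out <= c_in || c_in > threshold) return(v_out)
    v_in + (threshold - c_in) / (c_out - c_in) * (v_out - v_in)
  }

  lower <- find_bound("lower")
  upper <- find_bound("upper")
  tibble(
    param = profile$param, estimate = hat, lower = lower, upper = upper,
    alpha = alpha, df = df,
    identifiability = if (is.finite(lower) && is.finite(upper))
      "identifiable" else "practically-non-identifiable"
  )
}

#' @param profiles A `pls_profiles` list from [profile_parameters()].
#' @rdname confidence_interval
#' @export
confidence_intervals <- function(profiles, alpha = NULL, df = NULL,
                                 chi2_ref = NULL) {
  ref <- chi2_ref %||% min(vapply(profiles, function(p)
    min(p$chi2_min, p$grid$chi2_pl[p$grid$converged]), numeric(1)))
  dplyr::bind_rows(lapply(profiles, confidence_interval, alpha = alpha,
                          df = df, chi2_ref = ref))
}

#' Parameter samples along a profile likelihood
#'
#' Returns the re-optimised full parameter vectors at every converged grid
#' point inside the confidence region. On a branch that never crosses the
#' threshold (unbounded confidence interval) the samples extend over
#' `extension` log10 units from the estimate and are flagged
#' `extended-range`: for unidentifiable parameters the prediction spread is
#' explored over a wide, explicitly chosen range rather than an undefined
#' one.
#'
#' @param profile A `pls_profile`.
#' @param alpha,df Threshold settings (default: the profiling policy's).
#' @param extension Range, in log10 units from the estimate, covered on
#'   unbounded branches (default 3).
#' @param chi2_ref Reference chi2 (see [confidence_interval()]).
#' @return A `pls_samples` tibble: one column per parameter plus `.value`
#'   (the profiled value), `.chi2` and `.extended`.
#' @export
profile_samples <- function(profile, alpha = NULL, df = NULL, extension = 3,
                            chi2_ref = NULL) {
  alpha <- alpha %||% profile$control$alpha
  df <- df %||% profile$control$df
  delta <- qchisq(1 - alpha, df)
  g <- profile$grid
  hat <- profile$theta_hat[[profile$param]]
  ref <- chi2_ref %||% min(profile$chi2_min, g$chi2_pl[g$converged])
  dchi2 <- g$chi2_pl - ref

  unbounded <- c(
    lower = !any(g$chi2_pl[g$converged & g$value < hat] > ref + delta),
    upper = !any(g$chi2_pl[g$converged & g$value > hat] > ref + delta)
  )
  keep <- g$converged & dchi2 < delta & abs(g$value - hat) <= extension + 1e-9
  if (!any(keep)) {
    abort("no profile points inside the confidence region",
          class = "plsens_sampling_error")
  }
  on_unbounded <- (g$value < hat & unbounded[["lower"]]) |
    (g$value > hat & unbounded[["upper"]])
  out <- as_tibble(as.data.frame(profile$paths[keep, , drop = FALSE]))
  out$.value <- g$value[keep]
  out$.chi2 <- g$chi2_pl[keep]
  out$.extended <- on_unbounded[keep]
  attr(out, "param") <- profile$param
  attr(out, "theta_hat") <- profile$theta_hat
  class(out) <- c("pls_samples", class(out))
  out
}

#' Flag optimiser failures via wing monotonicity
#'
#' Outside the confidence region a well-resolved profile is non-decreasing
#' away from the estimate on each branch; a decrease larger than `slack`
#' indicates a failed nuisance re-optimisation.
#'
#' @param profile A `pls_profile`.
#' @param slack Permitted decrease.
#' @return `TRUE` if both wings are monotone within `slack`.
#' @export
profile_wings_monotone <- function(profile, slack = 1e-2) {
  delta <- qchisq(1 - profile$control$alpha, profile$control$df)
  ok <- TRUE
  for (side in c("lower", "upper")) {
    rows <- branch_rows(profile, side)
    chis <- profile$grid$chi2_pl[rows] # ordered walking outward
    outside <- which(chis > profile$chi2_min + delta)
    if (length(outside)) {
      chis <- chis[seq(outside[1], length(chis))]
      if (length(chis) > 1) ok <- ok && all(diff(chis) > -slack)
    }
  }
  ok
}

#' @export
print.pls_profile <- function(x, ...) {
  ci <- confidence_interval(x)
  cat("<pls_profile> ", x$param, ": ", nrow(x$grid), " points, CI(",
      format(1 - ci$alpha), ", df=", ci$df, ") = [",
      format(ci$lower, digits = 4), ", ", format(ci$upper, digits = 4),
      "] — ", ci$identifiability, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.pls_profile <- function(x, ...) {
  dplyr::mutate(x$grid, param = x$param, .before = 1)
}

#' @export
tidy.pls_profiles <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), tidy))
}

#' @export
glance.pls_profile <- function(x, ...) {
  confidence_interval(x)
}

#' @export
glance.pls_profiles <- function(x, ...) {
  confidence_intervals(x)
}
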