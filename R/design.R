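#' Enumerate candidate experiments
#'
#' Generates all single additions to a base design — each unmeasured state as
#' a new readout, each single-parameter inhibition — and optionally their
#' pairwise readout-plus-inhibition combinations. Ordering is deterministic
#' (by candidate id).
#'
#' @param model A [dynamic_model()].
#' @param design The base [experiment_design()].
#' @param readouts Include unmeasured states as readout candidates.
#' @param inhibitions Include single-parameter inhibitions.
#' @param combinations Include readout x inhibition pairs.
#' @param inhibition_factor Linear-scale factor applied by candidate
#'   inhibitions (default 1e-4, an essentially complete knock-down; the value
#'   is illustrative and configurable).
#' @param inhibition_params Parameters eligible for inhibition (default: all
#'   model parameters).
#' @return Tibble with columns `id`, `type`, `added_readouts` (list),
#'   `interventions` (list). Empty (with a warning) when nothing can be
#'   added.
#' @export
enumerate_candidates <- function(model, design, readouts = TRUE,
                                 inhibitions = FALSE, combinations = FALSE,
                                 inhibition_factor = 1e-4,
                                 inhibition_params = model$param_labels) {
  unmeasured <- setdiff(model$state_labels, design$observed)
  rows <- list()
  if (isTRUE(readouts)) {
    for (s in unmeasured) {
      rows[[length(rows) + 1]] <- tibble(
        id = paste0("readout:", s), type = "readout",
        added_readouts = list(s), interventions = list(list())
      )
    }
  }
  if (isTRUE(inhibitions)) {
    for (p in inhibition_params) {
      rows[[length(rows) + 1]] <- tibble(
        id = paste0("inhibit:", p), type = "inhibition",
        added_readouts = list(character(0)),
        interventions = list(list(intervention(p, inhibition_factor)))
      )
    }
  }
  if (isTRUE(combinations)) {
    for (s in unmeasured) {
      for (p in inhibition_params) {
        rows[[length(rows) + 1]] <- tibble(
          id = paste0("readout:", s, "+inhibit:", p), type = "combination",
          added_readouts = list(s),
          interventions = list(list(intervention(p, inhibition_factor)))
        )
      }
    }
  }
  if (!length(rows)) {
    warn("no candidates: all states measured and inhibitions disallowed")
    return(tibble(id = character(0), type = character(0),
                  added_readouts = list(), interventions = list()))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$id)
}

#' Pareto front (both criteria maximised)
#'
#' @param points Data frame with the two criterion columns.
#' @param x,y Column names of the criteria.
#' @return Logical vector: `TRUE` for nondominated rows.
#' @export
pareto_front <- function(points, x = "s_tot", y = "J_tot") {
  xv <- points[[x]]; yv <- points[[y]]
  n <- length(xv)
  vapply(seq_len(n), function(i) {
    !any(xv >= xv[i] & yv >= yv[i] & (xv > xv[i] | yv > yv[i]))
  }, logical(1))
}

#' Score design candidates in the criterion space
#'
#' A readout candidate's coordinates are the (s_tot, J_tot) of predicting
#' that state under the base design — already available from the base PLS
#' analysis. Candidates carrying an inhibition are scored by re-simulating
#' the prediction ensembles under the inhibited parameter set: the
#' intervention is added to the design, so both the samples and the reference
#' trajectory feel the knock-down. For inhibition-only candidates the
#' coordinates are summed over the base design's observed readouts; for
#' combination candidates over the added readouts. Pareto flags are computed
#' with both coordinates maximised — the scoring reports the full front
#' rather than a single winner, since a high total index and a homogeneous
#' parameter contribution generally trade off.
#'
#' @param base_pls A `pls_summary` of the base design covering every
#'   candidate readout (see [pls_summary()]).
#' @param candidates Tibble from [enumerate_candidates()].
#' @param model,samples,design,times,theta_hat Needed to re-simulate
#'   inhibition candidates; may be omitted when all candidates are pure
#'   readouts.
#' @param control [solver_control()].
#' @return Tibble `id`, `s_tot`, `J_tot`, `pareto`.
#' @export
score_candidates <- function(base_pls, candidates, model = NULL,
                             samples = NULL, design = NULL, times = NULL,
                             theta_hat = NULL, control = solver_control()) {
  score_one <- function(i) {
    cand <- candidates[i, ]
    ivs <- cand$interventions[[1]]
    added <- cand$added_readouts[[1]]
    if (!length(ivs)) {
      if (!all(added %in% names(base_pls))) {
        abort(paste0("no base PLS result for candidate ", cand$id),
              class = "plsens_scoring_error")
      }
      cs <- criterion_space(base_pls[added])
      return(tibble(id = cand$id, s_tot = sum(cs$s_tot), J_tot = sum(cs$J_tot)))
    }
    if (is.null(model) || is.null(samples) || is.null(design)) {
      abort("model, samples and design are required to score inhibition candidates",
            class = "plsens_scoring_error")
    }
    design_iv <- design
    design_iv$interventions <- c(design$interventions, ivs)
    preds <- if (length(added)) added else design$observed
    res <- pls_summary(model, samples, design_iv, predictions = preds,
                       times = times %||% design$times,
                       theta_hat = theta_hat %||% attr(samples[[1]], "theta_hat"),
                       control = control)
    cs <- criterion_space(res)
    tibble(id = cand$id, s_tot = sum(cs$s_tot), J_tot = sum(cs$J_tot))
  }
  out <- dplyr::bind_rows(lapply(seq_len(nrow(candidates)), score_one))
  out$pareto <- pareto_front(out)
  out
}

#' Anticipatory in-silico experiment for a candidate design
#'
#' Simulates the candidate design at the current estimate, adds Gaussian
#' noise, and returns a synthetic dataset (condition = candidate id) ready to
#' be merged with the existing data — the data one would expect if the
#' candidate experiment were performed and the model were right.
#'
#' @param model A [dynamic_model()].
#' @param fit A `pls_fit`; its estimate generates the data.
#' @param candidate One row of the tibble from [enumerate_candidates()] (or
#'   an equivalent list with `id`, `added_readouts`, `interventions`).
#' @param design Base [experiment_design()]; the candidate modifies a copy.
#' @param noise A [noise_spec()]; default 5% relative with absolute floor
#'   1e-3.
#' @param seed Integer seed for the noise draw.
#' @param times Measurement times of the new experiment (default: the base
#'   design's).
#' @return A synthetic dataset tibble (provenance `synthetic:<seed>`).
#' @export
anticipatory_experiment <- function(model, fit, candidate, design,
                                    noise = noise_spec(sd_rel = 0.05, sd_abs = 1e-3),
                                    seed = 1, times = design$times) {
  added <- if (is.data.frame(candidate)) candidate$added_readouts[[1]] else candidate$added_readouts
  ivs <- if (is.data.frame(candidate)) candidate$interventions[[1]] else candidate$interventions
  id <- if (is.data.frame(candidate)) candidate$id[[1]] else candidate$id
  observed <- if (length(added)) added else design$observed
  cand_design <- experiment_design(
    observed = observed, times = times, stimulus = design$stimulus,
    interventions = c(design$interventions, ivs)
  )
  generate_dataset(model, fit$par, cand_design, noise = noise, seed = seed,
                   condition = id)
}

#' Re-profile a candidate design on merged data
#'
#' Refits the model to the merged dataset (base plus anticipatory records),
#' re-profiles every parameter and reports the resulting confidence
#' intervals and identifiable count — the expensive, anticipatory assessment
#' of a candidate, as opposed to the cheap criterion-space score.
#'
#' @param model A [dynamic_model()].
#' @param data Merged dataset (conditions distinguish the experiments).
#' @param designs Named list of designs, one per condition in `data`.
#' @param start Log10 start for the refit (typically the base estimate).
#' @param candidate_id Id recorded in the result.
#' @param n_starts,seed,control,solver Passed to [fit_mle()].
#' @param profile [profile_control()] policy for the re-profiling.
#' @return A `pls_design_eval`: list with `id`, `fit`, `profiles`, `ci`
#'   (tibble of per-parameter intervals) and `n_identifiable`.
#' @export
evaluate_design <- function(model, data, designs, start,
                            candidate_id = "candidate", n_starts = 1, seed = 1,
                            control = fit_control(), solver = solver_control(),
                            profile = profile_control()) {
  fit <- fit_mle(model, data, designs, start = start, n_starts = n_starts,
                 seed = seed, control = control, solver = solver)
  profiles <- profile_parameters(fit, control = profile)
  ci <- confidence_intervals(profiles)
  structure(
    list(id = candidate_id, fit = fit, profiles = profiles, ci = ci,
         n_identifiable = sum(ci$identifiability == "identifiable")),
    class = "pls_design_eval"
  )
}

#' @export
print.pls_design_eval <- function(x, ...) {
  cat("<pls_design_eval> ", x$id, ": ", x$n_identifiable, "/", nrow(x$ci),
      " parameters identifiable (chi2_min = ", format(x$fit$chi2_min), ")\n",
      sep = "")
  invisible(x)
}

#' @export
glance.pls_design_eval <- function(x, ...) {
  tibble(id = x$id, chi2_min = x$fit$chi2_min,
         n_identifiable = x$n_identifiable, n_par = nrow(x$ci))
}
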