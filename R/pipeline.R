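#' Read an analysis configuration (YAML or JSON)
#'
#' The configuration mirrors [run_pipeline()]'s arguments: `model` (bundled
#' name or path to a declarative model spec) or `fixture` (bundled scenario
#' name), `dataset` (CSV path), a `design` block (`observed`, `times`,
#' `stimulus`, `interventions`), an `estimation` block (`start`, `n_starts`,
#' `seed`, `bound_width`), a `profiling` block (`alpha`, `df`, `extension`),
#' a `pls` block (`predictions`, `times`) and a `design_selection` block
#' (`enabled`, `inhibitions`, `combinations`, `inhibition_factor`).
#' Defaults are materialised so run logs are auditable.
#'
#' @param path Configuration file.
#' @return Config list.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "plsens_parse_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg
}

config_design <- function(block) {
  stim <- block$stimulus %||% list(kind = "constant", amplitude = 0)
  ivs <- lapply(block$interventions %||% list(), function(iv)
    intervention(iv$target_param, iv$factor %||% 1e-4))
  experiment_design(
    observed = as.character(block$observed),
    times = as.numeric(block$times),
    stimulus = stimulus_profile(stim$kind, stim$amplitude,
                                start = stim$start %||% 0,
                                duration = stim$duration %||% Inf),
    interventions = ivs
  )
}

write_json_sorted <- function(x, path) {
  # sorted keys for diffable output
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v))) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else v
  }
  jsonlite::write_json(sort_rec(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Serialise a fit to JSON
#'
#' @param fit A `pls_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  write_json_sorted(list(
    model = fit$model$name,
    parameters_log10 = as.list(fit$par),
    chi2_min = fit$chi2_min,
    n_obs = fit$n_obs,
    seed = fit$seed,
    starts = lapply(seq_len(nrow(fit$starts)), function(i)
      list(start = fit$starts$start[i], chi2 = fit$starts$chi2[i],
           converged = fit$starts$converged[i]))
  ), path)
}

#' Serialise a profile to CSV
#'
#' Columns: `param, grid_log10, chi2_pl, converged` plus one column per
#' nuisance parameter (the re-optimised full vector at each grid point).
#'
#' @param profile A `pls_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  out <- tibble(
    param = profile$param,
    grid_log10 = profile$grid$value,
    chi2_pl = profile$grid$chi2_pl,
    converged = profile$grid$converged
  )
  out <- dplyr::bind_cols(out, as_tibble(as.data.frame(profile$paths)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Chains estimation, profiling, PLS uncertainty propagation and (optionally)
#' design-candidate scoring, writing every stage's result to `out_dir`:
#' `fit.json`, `ci.csv`, `profiles/<param>.csv`, `pls/<prediction>.csv`,
#' `criterion_space.csv` (one row per analysed prediction),
#' `candidates.csv` (one row per scored design candidate) and
#' `run_log.json` (resolved settings, seeds, package version). All
#' randomness flows from the single `seed` recorded in the log.
#'
#' @param config A config list ([read_analysis_config()]) or path to one.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; overrides the config's.
#' @return Invisibly, a list with `fit`, `profiles`, `ci`, `pls`,
#'   `criterion`, and the resolved `config`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_analysis_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  est <- config$estimation %||% list()
  prof_cfg <- config$profiling %||% list()
  pls_cfg <- config$pls %||% list()
  sel <- config$design_selection %||% list()
  seed <- as.integer(seed %||% est$seed %||% 1L)

  if (!is.null(config$fixture)) {
    fx <- make_fixture(config$fixture, seed = seed)
    model <- fx$model; designs <- fx$designs; data <- fx$data
    start <- unlist(est$start %||% fx$truth)
  } else {
    model <- if (config$model %in% c("insilico4", "dsalina")) {
      model_library(config$model)
    } else {
      model_from_spec(config$model)
    }
    data <- read_dataset(config$dataset)
    designs <- list(base = config_design(config$design))
    start <- unlist(est$start)
    if (is.null(start)) abort("estimation$start is required", class = "plsens_config_error")
  }
  start <- as_log10_params(start, model)

  fit <- fit_mle(model, data, designs, start = start,
                 n_starts = est$n_starts %||% 20, seed = seed,
                 bound_width = est$bound_width %||% 3)
  write_fit_json(fit, file.path(out_dir, "fit.json"))

  pctrl <- profile_control(alpha = prof_cfg$alpha %||% 0.05,
                           df = prof_cfg$df %||% 1,
                           range = prof_cfg$range %||% 3)
  profiles <- profile_parameters(fit, control = pctrl)
  dir.create(file.path(out_dir, "profiles"), showWarnings = FALSE)
  for (p in names(profiles)) {
    write_profile_csv(profiles[[p]], file.path(out_dir, "profiles",
                                               paste0(p, ".csv")))
  }
  ci <- confidence_intervals(profiles)
  readr::write_csv(ci, file.path(out_dir, "ci.csv"), progress = FALSE)

  samples <- lapply(profiles, profile_samples,
                    extension = prof_cfg$extension %||% 3)
  base_design <- designs[[1]]
  predictions <- as.character(pls_cfg$predictions %||% model$state_labels)
  pls_times <- as.numeric(pls_cfg$times %||%
    seq(min(base_design$times), max(base_design$times), length.out = 101))
  if (pls_times[1] <= 0) {
    pls_times <- pls_times[pls_times > 0] # predictions live on t > 0
  }
  pls <- pls_summary(model, samples, base_design, predictions, pls_times,
                     theta_hat = fit$par)
  dir.create(file.path(out_dir, "pls"), showWarnings = FALSE)
  for (p in names(pls)) {
    s <- pls[[p]]$s
    readr::write_csv(
      dplyr::bind_cols(tibble(param = rownames(s)),
                       as_tibble(as.data.frame(s))),
      file.path(out_dir, "pls", paste0(p, ".csv")), progress = FALSE)
  }

  # criterion space of the analysed predictions (one row per prediction)
  pred_space <- criterion_space(pls)
  pred_space$pareto <- pareto_front(pred_space)
  readr::write_csv(pred_space, file.path(out_dir, "criterion_space.csv"),
                   progress = FALSE)

  criterion <- NULL
  if (isTRUE(sel$enabled %||% TRUE)) {
    cands <- enumerate_candidates(
      model, base_design,
      readouts = sel$readouts %||% TRUE,
      inhibitions = sel$inhibitions %||% FALSE,
      combinations = sel$combinations %||% FALSE,
      inhibition_factor = sel$inhibition_factor %||% 1e-4
    )
    if (nrow(cands)) {
      # ensure every readout candidate has a base PLS result
      missing <- setdiff(unlist(cands$added_readouts), names(pls))
      if (length(missing)) {
        extra <- pls_summary(model, samples, base_design, missing, pls_times,
                             theta_hat = fit$par)
        pls <- structure(c(unclass(pls), unclass(extra)), class = "pls_summary")
      }
      criterion <- score_candidates(pls, cands, model = model,
                                    samples = samples, design = base_design,
                                    times = pls_times, theta_hat = fit$par)
      readr::write_csv(criterion, file.path(out_dir, "candidates.csv"),
                       progress = FALSE)
    }
  }

  write_json_sorted(list(
    package_version = as.character(utils::packageVersion("plsens")),
    r_version = R.version.string,
    seed = seed,
    model = model$name,
    n_obs = nrow(data),
    resolved = list(
      estimation = list(n_starts = est$n_starts %||% 20,
                        bound_width = est$bound_width %||% 3),
      profiling = list(alpha = pctrl$alpha, df = pctrl$df,
                       extension = prof_cfg$extension %||% 3),
      pls = list(predictions = predictions, n_times = length(pls_times))
    )
  ), file.path(out_dir, "run_log.json"))

  invisible(list(fit = fit, profiles = profiles, ci = ci, pls = pls,
                 criterion = criterion, config = config, seed = seed))
}
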