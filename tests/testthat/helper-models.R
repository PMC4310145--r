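# Shared fixtures and small models for the test suite. Heavy analyses are
# memoised so several test files can share one computation.

# one-state exponential decay x' = -k x, x(0) = A, built through the
# declarative-model path so that path is exercised everywhere
decay_model <- function() {
  model_from_spec(list(
    name = "decay", states = "x", parameters = c("A", "k"),
    odes = list(x = "-k * x"), initial = list(x = "A")
  ))
}

decay_design <- function(n = 10, tmax = 5) {
  experiment_design("x", seq(tmax / n, tmax, length.out = n),
                    stimulus_profile("constant", 0))
}

decay_truth <- c(A = 0, k = -0.3)

insilico_design_base <- function(observed = "D") {
  experiment_design(observed, seq(0, 10, length.out = 16),
                    stimulus_profile("constant", 1))
}

# quadratic surrogate objectives for profiling oracles
quad_separable <- function(theta) (theta[["a"]] - 2)^2 + (theta[["b"]] - 1)^2
quad_correlated <- function(theta) (theta[["a"]] - theta[["b"]])^2 + 0.01 * theta[["b"]]^2

# memoisation for expensive shared analyses
.cache <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# full baseline analysis of the in-silico scenario: fit, profiles, samples,
# PLS over all four states
insilico_analysis <- function() {
  memo("insilico_analysis", {
    fx <- make_fixture("insilico_baseline")
    fit <- fit_mle(fx$model, fx$data, fx$designs$base, start = fx$truth,
                   n_starts = 20, seed = fx$seed)
    profiles <- suppressWarnings(profile_parameters(fit))
    ci <- confidence_intervals(profiles)
    samples <- lapply(profiles, profile_samples)
    times <- seq(0.1, 10, length.out = 100)
    pls <- pls_summary(fx$model, samples, fx$designs$base,
                       c("A", "B", "C", "D"), times, theta_hat = fit$par)
    list(fx = fx, fit = fit, profiles = profiles, ci = ci, samples = samples,
         times = times, pls = pls)
  })
}

# fluorescence-induction identifiability analyses (the slowest fixtures;
# fits warm-start at the scenario's generating truth). These analyses ask
# only for interval bounds — no PLS sampling — so the walk may stride at
# 0.25 log10 units on flat stretches and bounds come from grid
# interpolation; the 13-parameter profile sets dominate the suite's
# runtime.
dsalina_policy <- function() profile_control(step_max = 0.25, refine = FALSE)

dsalina_base_analysis <- function() {
  memo("dsalina_base_analysis", {
    fx <- make_fixture("dsalina_baseline")
    fit <- fit_mle(fx$model, fx$data, fx$designs, start = fx$truth,
                   n_starts = 1, seed = fx$seed)
    profiles <- suppressMessages(suppressWarnings(
      profile_parameters(fit, control = dsalina_policy())))
    list(fx = fx, fit = attr(profiles, "fit"), profiles = profiles,
         ci = confidence_intervals(profiles))
  })
}

dsalina_aug_analysis <- function() {
  memo("dsalina_aug_analysis", {
    fx <- make_fixture("dsalina_augmented")
    fit <- fit_mle(fx$model, fx$data, fx$designs, start = fx$truth,
                   n_starts = 1, seed = fx$seed)
    profiles <- suppressMessages(suppressWarnings(
      profile_parameters(fit, control = dsalina_policy())))
    list(fx = fx, fit = attr(profiles, "fit"), profiles = profiles,
         ci = confidence_intervals(profiles))
  })
}

# fitted decay scenario shared by profiling / design tests
decay_analysis <- function() {
  memo("decay_analysis", {
    model <- decay_model()
    design <- decay_design()
    data <- generate_dataset(model, decay_truth, design,
                             noise = noise_spec(sd_abs = 0.05), seed = 11)
    fit <- fit_mle(model, data, design, start = decay_truth, n_starts = 3,
                   seed = 5)
    profiles <- profile_parameters(fit)
    list(model = model, design = design, data = data, fit = fit,
         profiles = profiles, ci = confidence_intervals(profiles))
  })
}
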