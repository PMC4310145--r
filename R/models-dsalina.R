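#' Chlorophyll fluorescence induction model for Dunaliella salina
#'
#' Five-state model of the millisecond-scale fluorescence induction kinetics
#' of photosystem II after light onset. The states are probabilities / pool
#' levels per reaction center: x1 = excited antennae A*, x2 = reduced first
#' quinone acceptor QA-, x3 = reduced second quinone acceptor QB-,
#' x4 = doubly reduced QB2-, x5 = oxidised plastoquinone pool PQ. The light
#' intensity u drives antenna excitation; fluorescence is dissipated from the
#' excited antennae with rate k2 and recorded as F = G * k2 * x1, where G is
#' an overall instrument gain.
#'
#' ODE system:
#' \deqn{\dot x_1 = k_1 u (A_0 - x_1) - k_2 x_1 - k_3 x_1 (1 - x_2) + k_4 x_2 (A_0 - x_1)}
#' \deqn{\dot x_2 = k_3 x_1 (1-x_2) - k_4 x_2 (A_0-x_1) - k_5 x_2 (r_2-x_3-x_4) + k_6 x_3 (1-x_2) - k_7 x_2 x_3 + k_8 x_4 (1-x_2)}
#' \deqn{\dot x_3 = k_5 x_2 (r_2-x_3-x_4) - k_6 x_3 (1-x_2) - k_7 x_2 x_3 + k_8 x_4 (1-x_2)}
#' \deqn{\dot x_4 = k_7 x_2 x_3 - k_8 x_4 (1-x_2) - k_9 x_4 x_5}
#' \deqn{\dot x_5 = -k_9 x_4 x_5 + k_{10} (PQ_0 - x_5)}
#'
#' The electron transfer QA- + QB- -> QA + QB2- contributes the matched
#' -k7*x2*x3 terms in the x2 and x3 equations and +k7*x2*x3 in x4.
#'
#' The antenna pool size A0 = 290 is fixed; the remaining 13 parameters
#' (k1..k10, the plastoquinone pool size PQ0, the QB pool size r2 and the
#' gain G) are estimated. The initial state is x0 = (0, 0, 0, 0, PQ0), so the
#' initial condition depends on an estimated parameter and is re-derived at
#' every simulation. Besides F, identity readouts x1..x5 are exposed so the
#' internal quinone states can serve as candidate readouts in design studies.
#'
#' @return A [dynamic_model()] with 5 states and 13 free parameters.
#' @export
dsalina_model <- function() {
  spec <- list(
    name = "dsalina",
    states = paste0("x", 1:5),
    parameters = c(paste0("k", 1:10), "PQ0", "r2", "G"),
    constants = list(A0 = 290),
    odes = list(
      x1 = "k1 * u * (A0 - x1) - k2 * x1 - k3 * x1 * (1 - x2) + k4 * x2 * (A0 - x1)",
      x2 = "k3 * x1 * (1 - x2) - k4 * x2 * (A0 - x1) - k5 * x2 * (r2 - x3 - x4) + k6 * x3 * (1 - x2) - k7 * x2 * x3 + k8 * x4 * (1 - x2)",
      x3 = "k5 * x2 * (r2 - x3 - x4) - k6 * x3 * (1 - x2) - k7 * x2 * x3 + k8 * x4 * (1 - x2)",
      x4 = "k7 * x2 * x3 - k8 * x4 * (1 - x2) - k9 * x4 * x5",
      x5 = "-k9 * x4 * x5 + k10 * (PQ0 - x5)"
    ),
    initial = list(x5 = "PQ0"),
    readouts = list(F = "G * k2 * x1")
  )
  model <- model_from_spec(spec)
  model$compiled <- list(
    func = "deriv_dsalina", initfunc = "init_dsalina", dllname = "plsens",
    parm_names = c(paste0("k", 1:10), "A0", "PQ0", "r2"),
    parms = function(p, u)
      c(p[c(paste0("k", 1:10), "A0", "PQ0", "r2")], u)
  )
  model
}

#' Reference maximum-likelihood estimate for the fluorescence model
#'
#' The bundled reference estimate (log10 scale) obtained from PAM
#' fluorescence induction data of D. salina under a 1 s, 166 uE m-2 s-1
#' light pulse. It serves as ground truth for the bundled synthetic
#' scenarios and as the natural warm start for anticipatory design analyses.
#'
#' @return Named log10 parameter vector of the 13 free parameters.
#' @export
dsalina_mle <- function() {
  c(k1 = -1.9507, k2 = 1.2603, k3 = 3.3192, k4 = 2.0231, k5 = 4.5278,
    k6 = 5.5047, k7 = 4.6765, k8 = 2.8452, k9 = 1.5753, k10 = 0.1611,
    PQ0 = 1.4930, r2 = -0.3069, G = -2.8061)
}

#' Default stimulus and measurement grid for the fluorescence model
#'
#' A single 166 uE m-2 s-1 pulse of 1 s with 200 log-spaced measurement
#' times on [1e-4, 1] s (the induction phases are spread over decades, so a
#' logarithmic grid resolves them all).
#'
#' @param n_times Number of log-spaced measurement times.
#' @return A [experiment_design()] observing the fluorescence readout `F`.
#' @export
dsalina_design <- function(n_times = 200) {
  experiment_design(
    observed = "F",
    times = 10^seq(log10(1e-4), 0, length.out = n_times),
    stimulus = stimulus_profile("pulse", amplitude = 166, start = 0, duration = 1)
  )
}
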