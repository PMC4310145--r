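#' Four-species in silico benchmark network
#'
#' A mass-action network of species A, B, C, D in which an input u feeds A and
#' two parallel pathways activate the readout state D: a direct route
#' A -> B -> D (rates k11, k12) and a reversible route A <-> C -> D (rates
#' k21, k22 back, k23 forward), with a first-order sink d on D. All initial
#' conditions are zero. The two parallel D-activating routes plus the sink
#' give the model enough flexibility that time-course data of D alone leave
#' every rate constant practically non-identifiable — the situation the
#' PLS-based design machinery is meant to resolve.
#'
#' ODE system (u is the constant input):
#' \deqn{\dot A = u - (k_{11}+k_{21})A + k_{22}C}
#' \deqn{\dot B = k_{11}A - k_{12}B}
#' \deqn{\dot C = k_{21}A - k_{22}C - k_{23}C}
#' \deqn{\dot D = k_{12}B + k_{23}C - d\,D}
#'
#' Identity readouts are defined for each state. A compiled right-hand side
#' is attached for speed; set `use_compiled = FALSE` in [simulate_model()] to
#' use the R-level expressions instead.
#'
#' @return A [dynamic_model()] with states A, B, C, D and parameters
#'   k11, k12, k21, k22, k23, d.
#' @export
insilico_model <- function() {
  spec <- list(
    name = "insilico4",
    states = c("A", "B", "C", "D"),
    parameters = c("k11", "k12", "k21", "k22", "k23", "d"),
    odes = list(
      A = "u - (k11 + k21) * A + k22 * C",
      B = "k11 * A - k12 * B",
      C = "k21 * A - k22 * C - k23 * C",
      D = "k12 * B + k23 * C - d * D"
    ),
    initial = list(),
    readouts = list()
  )
  model <- model_from_spec(spec)
  model$compiled <- list(
    func = "deriv_insilico4", initfunc = "init_insilico4", dllname = "plsens",
    parm_names = c("k11", "k12", "k21", "k22", "k23", "d"),
    parms = function(p, u) c(p[c("k11", "k12", "k21", "k22", "k23", "d")], u)
  )
  model
}

#' Reference parameters of the in silico network
#'
#' The log10 rate constants used as ground truth by the bundled synthetic
#' scenarios.
#'
#' @return Named log10 parameter vector.
#' @export
insilico_truth <- function() {
  c(k11 = 0.043, k12 = 0.301, k21 = 0.398, k22 = 0.004, k23 = -0.301,
    d = 0.004)
}
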