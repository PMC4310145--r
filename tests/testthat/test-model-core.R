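test_that("zero input and zero initial state give identically zero trajectories", {
  m <- insilico_model()
  d <- experiment_design("D", seq(0.5, 5, length.out = 5),
                         stimulus_profile("constant", 0))
  tr <- simulate_model(m, insilico_truth(), d)
  expect_true(all(tr$states == 0))

  md <- dsalina_model()
  dd <- experiment_design("F", c(0.01, 0.1, 1),
                          stimulus_profile("constant", 0))
  trd <- simulate_model(md, dsalina_mle(), dd)
  # no excitation: x1 stays 0, hence F stays 0; the PQ pool stays full
  expect_equal(unname(trd$states[, "x1"]), rep(0, 3))
  expect_equal(evaluate_readout(md, trd, "F"), rep(0, 3))
  expect_equal(unname(trd$states[, "x5"]), rep(10^dsalina_mle()[["PQ0"]], 3),
               tolerance = 1e-8)
})

test_that("compiled and R-level right-hand sides agree for both bundled models", {
  m <- dsalina_model()
  d <- dsalina_design(40)
  a <- simulate_model(m, dsalina_mle(), d, use_compiled = TRUE)
  b <- simulate_model(m, dsalina_mle(), d, use_compiled = FALSE)
  expect_lt(max(abs(a$states - b$states)), 1e-6)

  mi <- insilico_model()
  di <- insilico_design_base()
  ai <- simulate_model(mi, insilico_truth(), di,
                       eval_times = seq(0.5, 10, length.out = 12))
  bi <- simulate_model(mi, insilico_truth(), di,
                       eval_times = seq(0.5, 10, length.out = 12),
                       use_compiled = FALSE)
  expect_lt(max(abs(ai$states - bi$states)), 1e-8)
})

test_that("fluorescence rises to a maximum during the pulse and decays after it", {
  m <- dsalina_model()
  # horizon past the 1 s pulse so the decay phase is visible
  d <- experiment_design("F", 10^seq(-4, log10(2), length.out = 120),
                         stimulus_profile("pulse", 166, 0, 1))
  tr <- simulate_model(m, dsalina_mle(), d)
  F <- evaluate_readout(m, tr, "F")
  dF <- diff(F)
  expect_gt(F[1], 0)
  expect_true(any(dF > 0) && any(dF < 0))       # rise then fall
  expect_gt(which.max(F), 2)                    # maximum away from the start
  expect_lt(which.max(F), length(F))            # and before the horizon end
})

test_that("induction states respect their pool bounds at the reference estimate", {
  m <- dsalina_model()
  th <- dsalina_mle()
  tr <- simulate_model(m, th, dsalina_design(150))
  p <- 10^th
  tol <- 1e-6
  expect_true(all(tr$states[, "x1"] >= -tol & tr$states[, "x1"] <= 290 + tol))
  expect_true(all(tr$states[, "x2"] >= -tol & tr$states[, "x2"] <= 1 + tol))
  expect_true(all(tr$states[, "x3"] >= -tol))
  expect_true(all(tr$states[, "x4"] >= -tol))
  expect_true(all(tr$states[, "x3"] + tr$states[, "x4"] <= p[["r2"]] + tol))
  expect_true(all(tr$states[, "x5"] >= -tol & tr$states[, "x5"] <= p[["PQ0"]] + tol))
  # plastoquinone pool is consumed during the induction
  expect_lt(tr$states[nrow(tr$states), "x5"], p[["PQ0"]])
})

test_that("simulation is deterministic and converges under tolerance refinement", {
  m <- dsalina_model()
  d <- dsalina_design(30)
  a <- simulate_model(m, dsalina_mle(), d)
  b <- simulate_model(m, dsalina_mle(), d)
  expect_identical(a$states, b$states)

  coarse <- solver_control(atol = 1e-8, rtol = 1e-6)
  fine <- solver_control(atol = 1e-9, rtol = 1e-7)
  Fa <- evaluate_readout(m, simulate_model(m, dsalina_mle(), d, control = coarse), "F")
  Fb <- evaluate_readout(m, simulate_model(m, dsalina_mle(), d, control = fine), "F")
  expect_lt(max(abs(Fa - Fb)), 10 * 1e-6 * max(abs(Fa)) + 10 * 1e-8)
})

test_that("readout evaluation applies g pointwise", {
  m <- dsalina_model()
  # hand-built trajectory: F = G * k2 * x1 is plain arithmetic
  states <- matrix(0, nrow = 3, ncol = 5,
                   dimnames = list(NULL, paste0("x", 1:5)))
  states[2, "x1"] <- 3
  traj <- structure(list(times = 1:3, states = states,
                         params_linear = c(G = 1e-2, k2 = 10)),
                    class = "pls_trajectory")
  expect_equal(evaluate_readout(m, traj, "F"), c(0, 0.3, 0))
  # identity readout returns the state unchanged
  expect_equal(evaluate_readout(m, traj, "x1"), states[, "x1"],
               ignore_attr = TRUE)
  expect_error(evaluate_readout(m, traj, "nope"), class = "plsens_config_error")
})

test_that("interventions scale parameters multiplicatively in log space", {
  th <- c(k21 = 0.398, d = 0)
  out <- apply_intervention(th, intervention("k21", 1e-4))
  expect_equal(out[["k21"]], -3.602)
  expect_equal(th[["k21"]], 0.398) # original untouched
  expect_equal(apply_intervention(th, intervention("k21", 1)), th)
  twice <- apply_intervention(apply_intervention(th, intervention("d", 0.1)),
                              intervention("d", 0.1))
  once <- apply_intervention(th, intervention("d", 0.01))
  expect_equal(twice, once)
  expect_error(intervention("k21", 0), class = "plsens_validation_error")
  expect_error(apply_intervention(th, intervention("zz", 0.5)),
               class = "plsens_config_error")
})

test_that("simulating with an intervention equals simulating scaled parameters", {
  m <- insilico_model()
  iv <- intervention("k21", 1e-4)
  d_iv <- experiment_design("D", seq(1, 10, length.out = 6),
                            stimulus_profile("constant", 1),
                            interventions = list(iv))
  d_plain <- experiment_design("D", seq(1, 10, length.out = 6),
                               stimulus_profile("constant", 1))
  a <- simulate_model(m, insilico_truth(), d_iv)
  b <- simulate_model(m, apply_intervention(insilico_truth(), iv), d_plain)
  expect_equal(a$states, b$states, tolerance = 1e-10)
})

test_that("constructors validate their invariants", {
  expect_error(experiment_design("D", c(1, 1, 2), stimulus_profile("constant", 1)),
               class = "plsens_validation_error")
  expect_error(experiment_design(character(0), 1:3, stimulus_profile("constant", 1)),
               class = "plsens_config_error")
  expect_error(stimulus_profile("pulse", 10, duration = 0),
               class = "plsens_config_error")
  expect_error(stimulus_profile("constant", -1), class = "plsens_config_error")
  m <- insilico_model()
  expect_error(as_log10_params(c(k11 = 1), m), class = "plsens_config_error")
  expect_silent(validate_model(m, insilico_truth()))
})

test_that("declarative specs round-trip through YAML", {
  m <- dsalina_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(m, path)
  m2 <- model_from_spec(path)
  expect_equal(m2$state_labels, m$state_labels)
  expect_equal(m2$param_labels, m$param_labels)
  d <- dsalina_design(20)
  a <- simulate_model(m, dsalina_mle(), d, use_compiled = FALSE)
  b <- simulate_model(m2, dsalina_mle(), d)
  expect_equal(a$states, b$states, tolerance = 1e-10)
  # undefined symbols in a spec are rejected
  expect_error(model_from_spec(list(name = "bad", states = "x",
                                    parameters = "k",
                                    odes = list(x = "-k * y"))),
               class = "plsens_config_error")
})
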