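test_that("candidate enumeration covers readouts, inhibitions and the empty case", {
  m <- insilico_model()
  base <- insilico_design_base("D")
  ro <- enumerate_candidates(m, base)
  expect_equal(ro$id, c("readout:A", "readout:B", "readout:C"))

  full <- insilico_design_base(c("A", "B", "C", "D"))
  inh <- enumerate_candidates(m, full, readouts = TRUE, inhibitions = TRUE)
  expect_equal(nrow(inh), 6) # nothing to add as readout, one per parameter
  expect_true(all(inh$type == "inhibition"))

  expect_warning(none <- enumerate_candidates(m, full, readouts = TRUE,
                                              inhibitions = FALSE),
                 "no candidates")
  expect_equal(nrow(none), 0)
})

test_that("Pareto flags agree with a brute-force domination check", {
  set.seed(12)
  pts <- tibble::tibble(s_tot = runif(40), J_tot = runif(40))
  fast <- pareto_front(pts)
  brute <- vapply(seq_len(40), function(i) {
    dominated <- FALSE
    for (j in seq_len(40)) {
      if (j != i && pts$s_tot[j] >= pts$s_tot[i] && pts$J_tot[j] >= pts$J_tot[i] &&
          (pts$s_tot[j] > pts$s_tot[i] || pts$J_tot[j] > pts$J_tot[i])) {
        dominated <- TRUE
      }
    }
    !dominated
  }, logical(1))
  expect_equal(fast, brute)

  # a single candidate is trivially nondominated; a strictly smaller point is dominated
  expect_true(pareto_front(tibble::tibble(s_tot = 1, J_tot = 1)))
  two <- tibble::tibble(s_tot = c(2, 1), J_tot = c(2, 1))
  expect_equal(pareto_front(two), c(TRUE, FALSE))
})

test_that("anticipatory experiments honour their noise spec and seed", {
  an <- decay_analysis()
  cand <- tibble::tibble(id = "readout:x", type = "readout",
                         added_readouts = list("x"),
                         interventions = list(list()))
  exact <- anticipatory_experiment(an$model, an$fit, cand, an$design,
                                   noise = noise_spec(allow_exact = TRUE),
                                   seed = 3)
  pred <- predict_observations(an$model, an$fit$par, exact,
                               setNames(list(an$design), "readout:x"))
  expect_equal(exact$mean, pred$value, tolerance = 1e-10)
  expect_equal(unique(exact$condition), "readout:x")

  noisy1 <- anticipatory_experiment(an$model, an$fit, cand, an$design, seed = 3)
  noisy2 <- anticipatory_experiment(an$model, an$fit, cand, an$design, seed = 3)
  noisy3 <- anticipatory_experiment(an$model, an$fit, cand, an$design, seed = 4)
  expect_identical(noisy1$mean, noisy2$mean)
  expect_false(identical(noisy1$mean, noisy3$mean))
})

test_that("re-evaluating the unchanged design reproduces the base analysis", {
  an <- decay_analysis()
  ev <- evaluate_design(an$model, an$data, an$design, start = an$fit$par,
                        candidate_id = "base", seed = 5)
  expect_equal(ev$fit$chi2_min, an$fit$chi2_min, tolerance = 1e-6)
  expect_equal(ev$n_identifiable, sum(an$ci$identifiability == "identifiable"))
})

test_that("informative extra observations cannot reduce the identifiable count", {
  an <- decay_analysis()
  base_n <- sum(an$ci$identifiability == "identifiable")
  cand <- tibble::tibble(id = "more", type = "readout",
                         added_readouts = list("x"),
                         interventions = list(list()))
  extra <- anticipatory_experiment(an$model, an$fit, cand, an$design,
                                   noise = noise_spec(sd_abs = 1e-3), seed = 6,
                                   times = seq(0.25, 5, length.out = 25))
  merged <- dplyr::bind_rows(an$data, extra)
  ev <- evaluate_design(an$model, merged,
                        list(base = an$design,
                             more = experiment_design("x", seq(0.25, 5, length.out = 25),
                                                      an$design$stimulus)),
                        start = an$fit$par, candidate_id = "more", seed = 6)
  expect_gte(ev$n_identifiable, base_n)
  # added data may only tighten profile intervals (up to optimiser slack)
  widths <- function(ci) pmin(ci$upper, 10) - pmax(ci$lower, -10)
  expect_true(all(widths(ev$ci) <= widths(an$ci) + 1e-2))
})

test_that("readout candidates are scored from the base PLS analysis", {
  an <- decay_analysis()
  samples <- lapply(an$profiles, profile_samples)
  times <- seq(0.5, 5, length.out = 15)
  base_pls <- pls_summary(an$model, samples, an$design, "x", times,
                          theta_hat = an$fit$par)
  cands <- tibble::tibble(id = "readout:x", type = "readout",
                          added_readouts = list("x"),
                          interventions = list(list()))
  sc <- score_candidates(base_pls, cands)
  expect_equal(sc$s_tot, base_pls$x$s_tot)
  expect_equal(sc$J_tot, base_pls$x$J_tot)
  expect_true(sc$pareto)

  # inhibition candidates need the simulation context
  inh <- tibble::tibble(id = "inhibit:k", type = "inhibition",
                        added_readouts = list(character(0)),
                        interventions = list(list(intervention("k", 1e-4))))
  expect_error(score_candidates(base_pls, inh), class = "plsens_scoring_error")
  sc2 <- score_candidates(base_pls, dplyr::bind_rows(cands, inh),
                          model = an$model, samples = samples,
                          design = an$design, times = times,
                          theta_hat = an$fit$par)
  expect_equal(nrow(sc2), 2)
  expect_true(all(sc2$s_tot >= 0))
})
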