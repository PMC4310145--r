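test_that("chi_squared matches hand computation and is permutation/additivity consistent", {
  data <- tibble::tibble(time = 1, readout = "x", mean = 1, sd = 0.5, n_rep = 1)
  pred0 <- tibble::tibble(time = 1, readout = "x", value = 0)
  expect_equal(chi_squared(data, pred0), 4)                       # (1-0)^2/0.25
  expect_equal(chi_squared(data, dplyr::mutate(pred0, value = 1)), 0)

  set.seed(3)
  big <- tibble::tibble(
    time = rep(1:5, 2), readout = rep(c("x", "y"), each = 5),
    mean = rnorm(10), sd = runif(10, 0.1, 1), n_rep = 1
  )
  pred <- dplyr::mutate(big[c("time", "readout")], value = rnorm(10))
  full <- chi_squared(big, pred)
  shuffled <- sample(1:10)
  expect_equal(chi_squared(big[shuffled, ], pred), full)
  parts <- sapply(c("x", "y"), function(r)
    chi_squared(big[big$readout == r, ], pred[pred$readout == r, ]))
  expect_equal(sum(parts), full)

  expect_error(chi_squared(big, pred[1:3, ]), class = "plsens_alignment_error")
  expect_error(chi_squared(dplyr::mutate(big, sd = 0), pred),
               class = "plsens_validation_error")
})

test_that("replicate normalisation maps F0 to 0, the maximum to 1, and floors sigma", {
  t <- seq(0, 1, by = 0.1)
  f1 <- 2 + 8 * sin(pi * t)      # peak mid-trace
  f2 <- 1 + 11 * sin(pi * t * 0.95)
  raw <- tibble::tibble(time = t, rep1 = f1, rep2 = f2)
  ds <- suppressMessages(normalize_replicates(raw))
  expect_equal(ds$mean[1], 0)
  expect_equal(max((f1 - f1[1]) / (max(f1) - f1[1])), 1)
  expect_true(all(ds$sd > 0))
  expect_equal(unique(ds$n_rep), 2)

  # identical replicates: sd would be 0 everywhere without the floor
  same <- tibble::tibble(time = t, rep1 = f1, rep2 = f1)
  expect_message(ds2 <- normalize_replicates(same), "floor")
  expect_true(all(ds2$sd >= 1e-3 * max(abs(ds2$mean))))

  expect_error(normalize_replicates(tibble::tibble(time = t, rep1 = rep(2, 11),
                                                   rep2 = f1)),
               class = "plsens_degenerate_trace_error")
})

test_that("noise-free data are recovered exactly and the provided start is not perturbed", {
  model <- decay_model()
  design <- decay_design()
  data <- generate_dataset(model, decay_truth, design,
                           noise = noise_spec(allow_exact = TRUE), seed = 1)
  # single start from the truth returns the truth
  fit1 <- fit_mle(model, data, design, start = decay_truth, n_starts = 1,
                  seed = 1, shake = FALSE)
  expect_lt(fit1$chi2_min, 1e-8)
  expect_equal(fit1$par, decay_truth, tolerance = 1e-6)

  # multi-start from a wrong guess still lands on the truth
  wrong <- c(A = 0.4, k = -1)
  fit2 <- fit_mle(model, data, design, start = wrong, n_starts = 8, seed = 2)
  expect_lt(fit2$chi2_min, 1e-4)
  expect_lt(max(abs(fit2$par - decay_truth)), 1e-3)
})

test_that("the fitted objective never exceeds the objective at the chosen start", {
  an <- decay_analysis()
  fit <- an$fit
  pred_at_start <- predict_observations(an$model, fit$start, an$data, an$design)
  expect_lte(fit$chi2_min, chi_squared(an$data, pred_at_start) + 1e-9)
  expect_true(all(fit$starts$chi2 >= fit$chi2_min - 1e-9))
})

test_that("fits are reproducible under a fixed seed", {
  model <- decay_model()
  design <- decay_design()
  data <- generate_dataset(model, decay_truth, design,
                           noise = noise_spec(sd_abs = 0.05), seed = 4)
  f1 <- fit_mle(model, data, design, start = c(A = 0.5, k = 0.5),
                n_starts = 5, seed = 9)
  f2 <- fit_mle(model, data, design, start = c(A = 0.5, k = 0.5),
                n_starts = 5, seed = 9)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$starts$chi2, f2$starts$chi2)
})

test_that("repeated synthetic fits give chi2_min near the residual degrees of freedom", {
  model <- decay_model()
  design <- decay_design(n = 25)
  chis <- vapply(1:12, function(i) {
    data <- generate_dataset(model, decay_truth, design,
                             noise = noise_spec(sd_abs = 0.05), seed = 100 + i)
    fit_mle(model, data, design, start = decay_truth, n_starts = 1,
            seed = 1, shake = FALSE)$chi2_min
  }, numeric(1))
  n <- 25
  expect_gt(median(chis), (n - 2) / 2)
  expect_lt(median(chis), (n - 2) * 2)
})

test_that("tidy and glance expose the fit in broom shape", {
  an <- decay_analysis()
  td <- tidy(an$fit)
  expect_equal(td$term, c("A", "k"))
  gl <- glance(an$fit)
  expect_equal(gl$n_obs, nrow(an$data))
  expect_equal(gl$chi2_min, an$fit$chi2_min)
})
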