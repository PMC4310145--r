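test_that("noise-free generation reproduces the simulation exactly", {
  model <- decay_model()
  design <- decay_design()
  ds <- generate_dataset(model, decay_truth, design,
                         noise = noise_spec(allow_exact = TRUE), seed = 1)
  pred <- predict_observations(model, decay_truth, ds, design)
  expect_equal(ds$mean, pred$value, tolerance = 1e-12)
  expect_match(attr(ds, "provenance"), "^synthetic:")
})

test_that("generated datasets are byte-identical under a fixed seed", {
  fx1 <- make_fixture("insilico_baseline")
  fx2 <- make_fixture("insilico_baseline")
  expect_identical(fx1$data, fx2$data)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(fx1$data, p1)
  write_dataset(fx2$data, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the recorded sigma matches the empirical spread of repeated draws", {
  model <- decay_model()
  # the per-readout SD is constant across the grid, so each dataset supplies
  # 100 iid noise draws; 100 seeds give 10^4 draws in total
  design <- experiment_design("x", seq(0.05, 5, length.out = 100),
                              stimulus_profile("constant", 0))
  clean <- generate_dataset(model, decay_truth, design,
                            noise = noise_spec(allow_exact = TRUE), seed = 1)
  draws <- unlist(lapply(1:100, function(i)
    generate_dataset(model, decay_truth, design,
                     noise = noise_spec(sd_rel = 0.1), seed = i)$mean -
      clean$mean))
  sigma <- unique(generate_dataset(model, decay_truth, design,
                                   noise = noise_spec(sd_rel = 0.1),
                                   seed = 1)$sd)
  expect_length(draws, 10000)
  expect_lt(abs(sd(draws) - sigma) / sigma, 0.03)
})

test_that("bundled scenarios encode the documented observation settings", {
  base <- make_fixture("insilico_baseline")
  expect_equal(base$designs$base$observed, "D")
  expect_equal(length(base$designs$base$times), 16)
  expect_equal(base$truth, insilico_truth())

  full <- make_fixture("insilico_full_readout")
  expect_setequal(full$designs$base$observed, c("A", "B", "C", "D"))

  ds <- make_fixture("dsalina_baseline")
  expect_equal(ds$designs$base$observed, "F")
  expect_equal(length(ds$designs$base$times), 200)
  expect_equal(ds$truth, dsalina_mle())
  expect_equal(unique(ds$data$sd), 0.02)

  aug <- make_fixture("dsalina_augmented")
  expect_setequal(unique(aug$data$condition), c("base", "insilico_x3"))
  expect_equal(aug$designs$insilico_x3$observed, "x3")
  # baseline records are shared between the two scenarios
  expect_equal(aug$data[aug$data$condition == "base", ], ds$data)
})

test_that("chi-squared at the generating truth is consistent with the noise model", {
  fx <- make_fixture("dsalina_baseline")
  pred <- predict_observations(fx$model, fx$truth, fx$data, fx$designs)
  chi2 <- chi_squared(fx$data, pred)
  n <- nrow(fx$data)
  expect_lt(abs(chi2 - n), 3 * sqrt(2 * n))
})
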