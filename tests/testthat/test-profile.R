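test_that("profiling a separable quadratic recovers the marginal parabola", {
  pr <- profile_objective(quad_separable, c(a = 2, b = 1), "a",
                          control = profile_control(range = 2))
  expected <- (pr$grid$value - 2)^2
  expect_lt(max(abs(pr$grid$chi2_pl - expected)), 1e-6)
})

test_that("profiling a correlated quadratic matches the analytic conditional minimum", {
  # min over b of (a-b)^2 + 0.01 b^2 = 0.01 a^2 / 1.01 — flat near zero
  pr <- profile_objective(quad_correlated, c(a = 0, b = 0), "a",
                          control = profile_control(range = 3))
  expected <- 0.01 * pr$grid$value^2 / 1.01
  expect_lt(max(abs(pr$grid$chi2_pl - expected)), 1e-6)
})

test_that("a parabolic profile gives the closed-form chi-square interval", {
  objfun <- function(theta) (theta[["a"]] - 2)^2
  pr <- profile_objective(objfun, c(a = 2), "a",
                          control = profile_control(range = 3))
  ci <- confidence_interval(pr, alpha = 0.05, df = 1)
  half <- sqrt(qchisq(0.95, 1))
  expect_equal(ci$lower, 2 - half, tolerance = 1e-5)
  expect_equal(ci$upper, 2 + half, tolerance = 1e-5)
  expect_equal(ci$identifiability, "identifiable")
})

test_that("a flat profile yields an unbounded interval and extended-range samples", {
  objfun <- function(theta) 0 * theta[["a"]]
  pr <- profile_objective(objfun, c(a = 0), "a")
  ci <- confidence_interval(pr)
  expect_identical(ci$lower, -Inf)
  expect_identical(ci$upper, Inf)
  expect_equal(ci$identifiability, "practically-non-identifiable")

  smp <- profile_samples(pr, extension = 3)
  # samples span the requested +/- 3 decades with >= 10 points per decade
  expect_equal(range(smp$.value), c(-3, 3), tolerance = 1e-6)
  expect_gte(nrow(smp), 61)
  expect_true(all(smp$.extended[smp$.value != 0]))
})

test_that("sample selection equals a brute-force filter of the profile grid", {
  an <- decay_analysis()
  pr <- an$profiles$k
  delta <- qchisq(0.95, 1)
  smp <- profile_samples(pr, alpha = 0.05, df = 1)
  ref <- min(pr$chi2_min, pr$grid$chi2_pl[pr$grid$converged])
  manual <- pr$grid$converged & (pr$grid$chi2_pl - ref < delta) &
    abs(pr$grid$value - pr$theta_hat[["k"]]) <= 3 + 1e-9
  expect_equal(nrow(smp), sum(manual))
  expect_setequal(smp$.value, pr$grid$value[manual])
  # identifiable parameter: all samples inside the confidence interval
  ci <- confidence_interval(pr)
  expect_true(all(smp$.value >= ci$lower - 1e-6 & smp$.value <= ci$upper + 1e-6))
  expect_false(any(smp$.extended))
})

test_that("profile grid invariants hold on a fitted model", {
  an <- decay_analysis()
  for (pr in an$profiles) {
    expect_false(is.unsorted(pr$grid$value, strictly = TRUE))
    ref <- min(pr$chi2_min, pr$grid$chi2_pl[pr$grid$converged])
    expect_true(all(pr$grid$chi2_pl[pr$grid$converged] >= ref - 1e-6))
    centre <- which.min(abs(pr$grid$value - pr$theta_hat[[pr$param]]))
    expect_lt(pr$grid$chi2_pl[centre] - pr$chi2_min, 1e-3)
    expect_true(profile_wings_monotone(pr))
  }
  # both parameters of the decay model are identifiable at this noise level
  expect_true(all(an$ci$identifiability == "identifiable"))
  expect_true(all(an$ci$lower < an$ci$estimate & an$ci$estimate < an$ci$upper))
})

test_that("profile export carries the nuisance path alongside the grid", {
  an <- decay_analysis()
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(an$profiles$A, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(back, c("param", "grid_log10", "chi2_pl", "converged", "A", "k"))
  expect_equal(back$grid_log10, an$profiles$A$grid$value)
  expect_equal(back$A, back$grid_log10) # profiled column equals the grid
})
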