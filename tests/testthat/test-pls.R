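make_ensemble <- function(times, trajectories, mle) {
  structure(list(prediction = "p", param = "a", times = times,
                 trajectories = trajectories, mle = mle),
            class = "pls_ensemble")
}

test_that("the PLS index is the squared normalised ensemble spread", {
  times <- c(1, 2)
  # identical trajectories: no spread, s == 0
  same <- make_ensemble(times, rbind(c(1, 2), c(1, 2)), c(1, 2))
  expect_equal(pls_index(same), c(0, 0))

  # extremes {1, 3} with time-averaged reference 2 -> s = ((3-1)/2)^2 = 1
  ens <- make_ensemble(times, rbind(c(1, 1), c(3, 3)), c(2, 2))
  expect_equal(pls_index(ens), c(1, 1))

  zero <- make_ensemble(times, rbind(c(1, 1)), c(0, 0))
  expect_error(pls_index(zero), class = "plsens_degenerate_denominator_error")
})

test_that("the PLS index is invariant under rescaling of the prediction", {
  set.seed(8)
  times <- sort(runif(7, 0, 1))
  tr <- matrix(runif(35), nrow = 5)
  mle <- runif(7) + 0.5
  base <- pls_index(make_ensemble(times, tr, mle))
  for (c in c(0.01, 3, 1e4)) {
    expect_equal(pls_index(make_ensemble(times, c * tr, c * mle)), base,
                 tolerance = 1e-12)
  }
})

test_that("restricting a sample set never increases the PLS index", {
  set.seed(9)
  times <- 1:6
  tr <- matrix(rnorm(60), nrow = 10)
  mle <- rep(1, 6)
  full <- pls_index(make_ensemble(times, tr, mle))
  for (i in 1:5) {
    sub <- sort(sample(10, 4))
    restricted <- pls_index(make_ensemble(times, tr[sub, , drop = FALSE], mle))
    expect_true(all(restricted <= full + 1e-12))
  }
})

test_that("pls_total sums all entries and validates shapes", {
  expect_equal(pls_total(matrix(0, 3, 4)), 0)
  expect_equal(pls_total(matrix(0.25, 1, 1)), 0.25)
  set.seed(2)
  s <- matrix(runif(12), 3, 4)
  brute <- 0
  for (i in 1:3) for (k in 1:4) brute <- brute + s[i, k]
  expect_equal(pls_total(s), brute)
  expect_equal(pls_total(list(a = s[1, ], b = s[2, ], c = s[3, ])), brute)
  expect_error(pls_total(list(a = 1:3, b = 1:2)), class = "plsens_validation_error")
})

test_that("PLS entropy attains its closed-form values", {
  # six equal indices: maximum entropy log(6)
  eq6 <- matrix(rep(0.2, 6), ncol = 1)
  expect_equal(pls_entropy(eq6)$J_k, log(6), tolerance = 1e-12)
  # a single nonzero index: zero entropy
  one <- matrix(c(0, 0.7, 0), ncol = 1)
  expect_equal(pls_entropy(one)$J_k, 0)
  # two equal shares: log 2
  expect_equal(pls_entropy(matrix(c(0.5, 0.5), ncol = 1))$J_k, log(2))
  # normalised columns sum to one wherever the column sum is positive
  set.seed(5)
  s <- matrix(runif(20), 4, 5); s[, 3] <- 0
  ent <- suppressMessages(pls_entropy(s))
  expect_equal(colSums(ent$s_tilde)[-3], rep(1, 4), ignore_attr = TRUE)
  expect_equal(ent$J_k[3], 0)
  expect_true(all(ent$J_k >= 0 & ent$J_k <= log(4) + 1e-12))
  expect_equal(ent$J_tot, sum(ent$J_k))
  expect_error(pls_entropy(matrix(-1)), class = "plsens_validation_error")
})

test_that("a point sample set reproduces the reference trajectory", {
  an <- decay_analysis()
  pr <- an$profiles$k
  hat <- pr$theta_hat
  one <- profile_samples(pr)[1, ]
  one[names(hat)] <- as.list(hat)
  attr(one, "param") <- "k"; attr(one, "theta_hat") <- hat
  class(one) <- c("pls_samples", class(one))
  times <- seq(0.5, 5, length.out = 20)
  ens <- prediction_ensemble(an$model, one, an$design, "x", times)
  expect_equal(nrow(ens$trajectories), 1)
  expect_equal(as.numeric(ens$trajectories[1, ]), ens$mle, tolerance = 1e-9)
  expect_equal(pls_index(ens), rep(0, 20))
})

test_that("ensemble size equals the accepted sample count", {
  an <- decay_analysis()
  smp <- profile_samples(an$profiles$A)
  times <- seq(0.5, 5, length.out = 10)
  ens <- prediction_ensemble(an$model, smp, an$design, "x", times)
  expect_equal(nrow(ens$trajectories), nrow(smp))
})

test_that("pls_summary assembles per-prediction matrices consistent with single ensembles", {
  an <- decay_analysis()
  samples <- lapply(an$profiles, profile_samples)
  times <- seq(0.5, 5, length.out = 15)
  res <- pls_summary(an$model, samples, an$design, "x", times,
                     theta_hat = an$fit$par)
  expect_named(res, "x")
  r <- res$x
  expect_equal(dim(r$s), c(2, 15))
  expect_true(all(r$s >= 0))
  expect_equal(r$s_tot, sum(r$s))
  expect_equal(r$J_tot, sum(r$J_k))
  # rows agree with individually built ensembles
  for (p in c("A", "k")) {
    ens <- prediction_ensemble(an$model, samples[[p]], an$design, "x", times,
                               theta_hat = an$fit$par)
    expect_equal(r$s[p, ], pls_index(ens), ignore_attr = TRUE,
                 tolerance = 1e-10)
  }
  cs <- criterion_space(res)
  expect_equal(cs$s_tot, r$s_tot)
})
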