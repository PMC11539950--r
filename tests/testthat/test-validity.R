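test_that("remainder fit matches the shared least-squares core", {
  set.seed(1)
  x_r <- matrix(rnorm(40 * 3), 40, 3)
  r <- rnorm(40)
  rem <- fit_remainder(r, x_r)
  ref <- ols_fit(x_r, r)
  expect_equal(rem$alpha, ref$coefficients, tolerance = 1e-10)
  expect_equal(rem$r_hat, ref$fitted, tolerance = 1e-10)
})

test_that("orthogonal and in-span remainders hit the two extremes", {
  set.seed(2)
  x_r <- qr.Q(qr(matrix(rnorm(30 * 2), 30, 2)))
  # remainder orthogonal to the model space: nothing is predictable
  r_perp <- rnorm(30)
  r_perp <- r_perp - x_r %*% crossprod(x_r, r_perp)
  vr <- validity_check(drop(r_perp), x_r, epsilon_prime = 1e-6)
  expect_equal(vr$ratio, 1, tolerance = 1e-10)
  expect_true(vr$passed)
  # remainder inside the model space: fully predictable
  r_in <- drop(x_r %*% c(2, -1))
  vr2 <- validity_check(r_in, x_r, epsilon_prime = 1e-6)
  expect_equal(vr2$loss_r_hat, 0, tolerance = 1e-16)
  expect_false(vr2$passed)
  # identically-zero remainder: ratio defined as 1, check passes
  vr3 <- validity_check(rep(0, 30), x_r, epsilon_prime = 0)
  expect_equal(vr3$ratio, 1)
  expect_true(vr3$passed)
})

test_that("gamma converts to an absolute tolerance through ||r_tilde||^2", {
  expect_equal(epsilon_prime_from_gamma(0, c(3, 4)), 0)
  expect_equal(epsilon_prime_from_gamma(0.01, c(1, 2, 2)), 0.09)
  expect_equal(epsilon_prime_from_gamma(1, c(1, 2, 2)), 9)
  expect_error(epsilon_prime_from_gamma(-0.1, c(1, 2)), "nonnegative")
})

test_that("validity report invariants hold on random instances", {
  set.seed(3)
  for (i in 1:10) {
    x_r <- matrix(rnorm(50 * 3), 50, 3)
    r <- rnorm(50)
    vr <- validity_check(r, x_r, epsilon_prime = 0.5)
    expect_lte(vr$loss_r_hat, vr$loss_r_zero + 1e-10)
    expect_gte(vr$ratio, 0)
    expect_lte(vr$ratio, 1)
    expect_equal(vr$gamma_true, 1 - vr$ratio)
    expect_equal(vr$passed, vr$loss_r_hat >= vr$loss_r_zero - 0.5)
  }
})

test_that("true-percentage is invariant to dataset rescaling", {
  d <- sim_iv_data(400, "valid", seed = 8)
  spec <- iv_spec(c("x1", "z1", "z1^2"), c("x1", "t_hat"),
                  c("x1", "z1", "z1^2"), normalize = TRUE)
  f1 <- fit_two_stage(d, spec, gamma = 0.01)
  d10 <- dplyr::mutate(d, x1 = 10 * x1, z1 = 10 * z1, t = 10 * t, y = 10 * y)
  f2 <- fit_two_stage(d10, spec, gamma = 0.01)
  expect_equal(f1$validity$ratio, f2$validity$ratio, tolerance = 1e-6)
})

test_that("relevance check behaves like nested least squares", {
  d <- sim_iv_data(8000, "valid", seed = 12)
  # valid design: z enters the treatment with unit coefficients
  rel <- relevance_check(d, c("x1", "z1", "z1^2"))
  expect_true(rel$passed)
  # per-observation loss gap: Var(z) + Var(z^2) = 3 from the instrument terms,
  # plus ~1 because the z^2 column also absorbs E[t] = 1, which the
  # intercept-free covariate-only model cannot touch
  expect_lt(abs((rel$loss_without - rel$loss_with) / nrow(d) - 4), 1)
  # nested models with epsilon = 0: adding regressors never hurts
  rel0 <- relevance_check(d, c("x1", "z1"), "x1", epsilon = 0)
  expect_true(rel0$passed)
  expect_lte(rel0$loss_with, rel0$loss_without)
  # pure-noise instrument on a mean-zero treatment: fails at the default
  # 5% threshold in every replicate
  set.seed(13)
  fails <- vapply(1:20, function(i) {
    n <- 1000
    x <- rnorm(n)
    e <- gen_errors(n, 0.8)
    di <- tibble::tibble(x1 = x, z1 = rnorm(n), t = x + e$e1,
                         y = x + (x + e$e1) + e$e2)
    !relevance_check(di, c("x1", "z1", "z1^2"))$passed
  }, logical(1))
  expect_true(all(fails))
  expect_error(relevance_check(d, c("x1", "z1"), c("x1", "z1")),
               "must not reference")
})
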