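test_that("stage one recovers the generating coefficients", {
  d <- sim_iv_data(1e4, "valid", seed = 21)
  s1 <- fit_stage_one(d, preset_spec("quadratic"))
  expect_true(all(abs(s1$omega - 1) < 0.05))
  expect_true(s1$relevance$passed)
  # degenerate target
  d0 <- dplyr::mutate(d[1:50, ], t = 0)
  s0 <- fit_stage_one(d0, preset_spec("quadratic"))
  expect_true(all(abs(s0$omega) < 1e-12))
  expect_true(all(abs(s0$t_hat) < 1e-12))
  # identical to the shared least-squares core
  x_t <- build_design_matrix(d, preset_spec("quadratic"), stage = "one")
  expect_identical(s1$omega, ols_fit(x_t, d$t)$coefficients)
})

test_that("constraint minimizer coincides with the objective minimizer under nesting", {
  # LM/LM: stage-two columns lie inside the remainder model's span
  for (seed in 1:5) {
    d <- sim_iv_data(200, "valid", seed = seed)
    x_t <- build_design_matrix(d, c("x1", "z1"))
    t_hat <- ols_fit(x_t, d$t)$fitted
    x_y <- build_design_matrix(d, c("x1", "t_hat"), t_hat = t_hat)
    h <- hat_matrix(x_t)
    cmin <- min_constraint_value(x_y, h, d$y)
    bhat <- ols_fit(x_y, d$y)$coefficients
    expect_lt(max(abs(cmin$beta_cmin - bhat)), 1e-6)
    expect_gte(cmin$value, 0)
  }
})

test_that("constraint minimizer reduces to OLS when the projector is full", {
  set.seed(6)
  x_y <- matrix(rnorm(20 * 2), 20, 2)
  y <- rnorm(20)
  h_full <- hat_matrix(diag(20))   # H = I
  cmin <- min_constraint_value(x_y, h_full, y)
  expect_equal(drop(cmin$beta_cmin), unname(ols_fit(x_y, y)$coefficients),
               tolerance = 1e-8)
})

test_that("constraint minimizer agrees with a brute-force grid", {
  d <- sim_iv_data(60, "valid", seed = 31)
  x_t <- build_design_matrix(d, c("x1", "z1"))
  t_hat <- ols_fit(x_t, d$t)$fitted
  x_y <- build_design_matrix(d, c("x1", "t_hat"), t_hat = t_hat)
  h <- hat_matrix(build_design_matrix(d, c("x1", "z1", "z1^2")))
  cmin <- min_constraint_value(x_y, h, d$y)
  grid <- expand.grid(b1 = seq(-3, 3, by = 0.01), b2 = seq(-3, 3, by = 0.01))
  qx <- crossprod(h$Q, x_y)
  qy <- drop(crossprod(h$Q, d$y))
  vals <- colSums((qy - qx %*% t(as.matrix(grid)))^2)
  expect_lt(abs(cmin$value - min(vals)), 1e-2)
})

test_that("a vacuous constraint reproduces traditional two-stage least squares", {
  d <- sim_iv_data(300, "valid", seed = 41)
  spec <- preset_spec("quadratic")
  trad <- fit_traditional(d, spec)
  x_y <- build_design_matrix(d, spec, stage = "two", t_hat = trad$t_hat)
  h <- hat_matrix(build_design_matrix(d, spec, stage = "remainder"))
  s2 <- constrained_stage_two(d$y, x_y, h, Inf)
  expect_identical(s2$status, "inactive")
  expect_equal(unname(s2$beta), unname(trad$beta), tolerance = 1e-10)
  expect_error(constrained_stage_two(d$y, x_y, h, -1), "nonnegative")
})

test_that("the constrained solution is the global minimizer (grid oracle)", {
  # 2-parameter second stage with nonlinear t_hat feature so that the
  # constraint can genuinely bind
  for (seed in c(9, 19, 29)) {
    d <- sim_iv_data(60, "valid", seed = seed)
    x_t <- build_design_matrix(d, c("x1", "z1"))
    t_hat <- ols_fit(x_t, d$t)$fitted
    x_y <- build_design_matrix(d, c("t_hat", "t_hat^2"), t_hat = t_hat)
    h <- hat_matrix(build_design_matrix(d, c("x1", "z1", "z1^2")))
    uncon <- ols_fit(x_y, d$y)
    cv0 <- constraint_quadratic(uncon$coefficients, x_y, h, d$y)
    cmin <- min_constraint_value(x_y, h, d$y)$value
    eps <- cmin + 0.25 * (cv0 - cmin)   # forces the active case
    s2 <- constrained_stage_two(d$y, x_y, h, eps)
    expect_identical(s2$status, "active")
    expect_lt(abs(s2$constraint_value - eps), max(1e-8 * eps, 1e-12))
    # no feasible grid point beats the solver ...
    oracle <- grid_search_qcqp(d$y, x_y, h, eps, s2$beta)
    expect_lte(s2$objective_value, oracle$value + 1e-9)
    # ... and a dense scan of the active boundary pins the optimum down
    bnd <- boundary_search_qcqp(d$y, x_y, h, eps)
    expect_lt(abs(s2$objective_value - bnd$value), 1e-3)
  }
})

test_that("objective value is non-increasing in the tolerance", {
  d <- sim_iv_data(80, "valid", seed = 51)
  x_t <- build_design_matrix(d, c("x1", "z1"))
  t_hat <- ols_fit(x_t, d$t)$fitted
  x_y <- build_design_matrix(d, c("t_hat", "t_hat^2"), t_hat = t_hat)
  h <- hat_matrix(build_design_matrix(d, c("x1", "z1", "z1^2")))
  cmin <- min_constraint_value(x_y, h, d$y)$value
  eps_grid <- cmin + c(0.3, 1, 3, 10, Inf)
  objs <- vapply(eps_grid, function(e)
    constrained_stage_two(d$y, x_y, h, e)$objective_value, numeric(1))
  expect_true(all(diff(objs) <= 1e-8))
  trad_sse <- ols_fit(x_y, d$y)$sse
  expect_equal(objs[length(objs)], trad_sse, tolerance = 1e-10)
})

test_that("infeasibility is declared exactly when even the best beta fails", {
  d <- sim_iv_data(1000, "non_instrument", seed = 61, phi = 1)
  spec <- preset_spec("quadratic")
  fit <- fit_two_stage(d, spec, gamma = 0.01)
  expect_identical(fit$stage_two$status, "infeasible")
  expect_null(fit$stage_two$beta)
  expect_gt(fit$stage_two$constraint_min, fit$epsilon_prime)
  expect_false(fit$validity$passed)
  # epsilon' = 0 with a positive minimum: infeasible by the same rule
  x_t <- build_design_matrix(d, spec, stage = "one")
  t_hat <- ols_fit(x_t, d$t)$fitted
  x_y <- build_design_matrix(d, spec, stage = "two", t_hat = t_hat)
  h <- hat_matrix(build_design_matrix(d, spec, stage = "remainder"))
  s0 <- constrained_stage_two(d$y, x_y, h, 0)
  expect_identical(s0$status, "infeasible")
  # gamma = 1 makes the constraint weaker than the zero-model bound
  fit1 <- fit_two_stage(d, spec, gamma = 1)
  expect_true(fit1$stage_two$status != "infeasible")
})

test_that("valid instruments keep a feasible constrained fit", {
  d <- sim_iv_data(1000, "valid", seed = 71)
  fit <- fit_two_stage(d, preset_spec("quadratic"), gamma = 0.01)
  expect_true(fit$stage_two$status != "infeasible")
  expect_true(fit$validity$passed)
  expect_true(fit$stage_one$relevance$passed)
  td <- tidy(fit)
  expect_identical(names(td), c("stage", "term", "estimate"))
  expect_equal(nrow(td), 5)
  gl <- glance(fit)
  expect_identical(gl$status, fit$stage_two$status)
})

test_that("traditional fit matches the classical just-identified IV ratio", {
  for (seed in 1:5) {
    d <- sim_iv_data(500, "valid", seed = seed)
    spec <- iv_spec(c("x1", "z1"), c("x1", "t_hat"), c("x1", "z1"))
    trad <- fit_traditional(d, spec)
    expect_equal(unname(trad$beta[["t_hat"]]), classical_iv_beta(d),
                 tolerance = 1e-8)
  }
})

test_that("without confounding, two-stage and direct regression agree", {
  d <- sim_iv_data(2e4, "valid", seed = 81, rho = 0)
  spec <- preset_spec("quadratic")
  trad <- fit_traditional(d, spec)
  ols_beta <- ols_fit(cbind(d$x1, d$t), d$y)$coefficients[2]
  expect_lt(abs(trad$beta[["t_hat"]] - ols_beta), 0.1)
})

test_that("robustness design recovers the unit causal effect", {
  betas <- vapply(1:50, function(i) {
    d <- sim_iv_data(1000, "robustness", seed = 100 + i, pi_strength = 1,
                     f_name = "quadratic")
    fit_traditional(d, preset_spec("quadratic"))$beta[["t_hat"]]
  }, numeric(1))
  expect_lt(abs(median(betas) - 1), 0.1)
})
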