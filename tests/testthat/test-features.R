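test_that("design matrix reproduces the quadratic predictor matrix", {
  d <- toy_data(50, seed = 2)
  m <- build_design_matrix(d, c("x1", "z1", "z1^2"))
  expect_identical(colnames(m), c("x1", "z1", "z1^2"))
  expect_equal(unname(m), unname(cbind(d$x1, d$z1, d$z1^2)))
})

test_that("identity term on one covariate returns the column unchanged", {
  d <- toy_data(30, seed = 3)
  m <- build_design_matrix(d, "x1")
  expect_equal(drop(m), d$x1, ignore_attr = TRUE)
})

test_that("normalization z-scores every feature column", {
  d <- toy_data(500, seed = 4)
  m <- build_design_matrix(d, c("x1", "z1", "z1^2", "z1^3"), normalize = TRUE)
  expect_true(all(abs(colMeans(m)) < 1e-12))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-12))
})

test_that("z and z^2 columns are empirically uncorrelated under a normal z", {
  d <- sim_iv_data(1e4, "valid", seed = 6)
  m <- build_design_matrix(d, c("z1", "z1^2"))
  expect_lt(abs(cor(m[, 1], m[, 2])), 0.1)
})

test_that("stage-two specs can never smuggle in the instrument", {
  expect_error(iv_spec(c("x1", "z1"), c("x1", "z1", "t_hat"), c("x1", "z1")),
               "validity violation")
  expect_error(iv_spec(c("x1", "z1"), c("x1", "exp(z1)"), c("x1", "z1")),
               "validity violation")
  d <- toy_data(30, seed = 1)
  expect_error(build_design_matrix(d, c("x1", "z1"), stage = "two"),
               "validity violation")
  # t_hat belongs to stage two only
  expect_error(iv_spec(c("x1", "t_hat"), c("x1", "t_hat"), c("x1", "z1")),
               "t_hat")
  expect_error(iv_spec(c("x1", "z1", "z1"), c("x1", "t_hat"), c("x1", "z1")),
               "duplicate")
})

test_that("transform terms evaluate to their mathematical definitions", {
  d <- tibble::tibble(x1 = c(-2, 0, 3), z1 = c(1, -4, 0.5),
                      t = c(1, 2, 3), y = c(0, 1, 0))
  expect_equal(drop(build_design_matrix(d, "exp(z1)")), exp(d$z1),
               ignore_attr = TRUE)
  expect_equal(drop(build_design_matrix(d, "logistic(z1)")),
               1 / (1 + exp(-d$z1)), ignore_attr = TRUE)
  expect_equal(drop(build_design_matrix(d, "sqrt|z1|")), sqrt(abs(d$z1)),
               ignore_attr = TRUE)
  expect_equal(drop(build_design_matrix(d, "x1*z1")), d$x1 * d$z1,
               ignore_attr = TRUE)
  # log|.| is clipped away from zero, so a zero input stays finite
  d$z1[2] <- 0
  lg <- build_design_matrix(tibble::tibble(x1 = 1:3, z1 = c(1, 0, 2),
                                           t = 1:3, y = 1:3)[1:3, ],
                            "log|z1|")
  expect_true(all(is.finite(lg)))
  expect_equal(lg[2], log(1e-12))
})

test_that("standardization is exact, idempotent and invertible", {
  s <- standardize_columns(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(mean(s$x), 0)
  expect_equal(sd(s$x), 1)
  s2 <- standardize_columns(s$x)
  expect_true(max(abs(s2$x - s$x)) < 1e-12)
  m <- matrix(rnorm(60), 20, 3)
  expect_true(max(abs(unstandardize_columns(standardize_columns(m)) - m)) < 1e-12)
  mz <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(standardize_columns(mz), "b")
})

test_that("collinear feature sets are rejected, not silently fit", {
  d <- toy_data(40, seed = 5)
  d$x2 <- 2 * d$x1
  expect_error(build_design_matrix(d, c("x1", "x2")), "rank deficient")
})

test_that("feature specs round-trip through JSON", {
  spec <- iv_spec(c("x1", "z1", "z1^2"), c("x1", "t_hat"),
                  c("x1", "z1", "z1^2"), normalize = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  spec_to_json(spec, path)
  expect_equal(spec_from_json(path), spec)
})
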