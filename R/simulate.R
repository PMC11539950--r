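#' Simulate data for the instrumental-variable study designs
#'
#' Seeded generators for the three data-generation processes used throughout
#' the package's simulation studies. All designs share a scalar covariate
#' `x ~ N(0,1)`, a scalar candidate instrument `z ~ N(0,1)` independent of `x`,
#' and a bivariate-normal error pair `(e1, e2)` with unit variances and
#' correlation `rho`; the correlation plays the role of unmeasured confounding,
#' since `e1` enters the treatment and `e2` the outcome.
#'
#' The designs are:
#' \describe{
#'   \item{`"valid"`}{`t = x + z + z^2 + e1`, `y = x + t + e2`. The instrument
#'     affects the outcome only through the treatment.}
#'   \item{`"non_instrument"`}{as `"valid"` plus a hidden mediator
#'     `x_un_dep = z^3` entering the outcome: `y = x + phi * z^3 + t + e2`.
#'     `phi` scales the mediator's strength. The mediator column is *not*
#'     part of the returned data — it is unknown to the analyst.}
#'   \item{`"robustness"`}{`t = x + pi * f(z) + e1`, `y = x + beta_true * t + e2`
#'     with `f` one of six nonlinear forms (see `f_name`); `pi` scales the
#'     instrument's strength.}
#' }
#'
#' Draws happen in a fixed order (x, then z, then the error pair) from a single
#' seeded stream, so changing `phi`, `pi`, `f_name`, `beta_true` or `rho` never
#' changes the underlying normal draws. This makes runs with different signal
#' parameters exactly paired, which the confusion-matrix and robustness studies
#' rely on.
#'
#' @param n Sample size (>= 10).
#' @param dgp One of `"valid"`, `"non_instrument"`, `"robustness"`.
#' @param seed Integer seed; identical arguments give identical data.
#' @param phi Mediator strength (non-instrument design only).
#' @param pi_strength Instrument strength (robustness design only).
#' @param f_name Nonlinear first-stage form for the robustness design: one of
#'   `"quadratic"` (z^2), `"cubic"` (z^3), `"exp"`, `"log"` (log|z|),
#'   `"sqrt"` (sqrt|z|), `"logistic"` (1/(1+exp(-z))).
#' @param rho Correlation between the two error terms (default 0.8).
#' @param beta_true True second-stage treatment coefficient in the robustness
#'   design (default 1).
#'
#' @return A tibble with columns `x1`, `z1`, `t`, `y`.
#' @examples
#' d <- sim_iv_data(1000, "valid", seed = 1)
#' var(d$t) # close to 5 = Var(x) + Var(z) + Var(z^2) + Var(e1)
#' @export
sim_iv_data <- function(n, dgp = c("valid", "non_instrument", "robustness"),
                        seed, phi = 1, pi_strength = 1,
                        f_name = c("quadratic", "cubic", "exp", "log",
                                   "sqrt", "logistic"),
                        rho = 0.8, beta_true = 1) {
  dgp <- match.arg(dgp)
  stopifnot(n >= 10, rho > -1, rho < 1)
  if (dgp == "robustness") f_name <- match.arg(f_name)

  set.seed(as.integer(seed))
  x <- rnorm(n)
  z <- rnorm(n)
  e <- gen_error_pair(n, rho)

  if (dgp == "robustness") {
    t <- x + pi_strength * dgp_f(f_name)(z) + e$e1
    y <- x + beta_true * t + e$e2
  } else {
    t <- x + z + z^2 + e$e1
    med <- if (dgp == "non_instrument") phi * z^3 else 0
    y <- x + med + t + e$e2
  }
  tibble::tibble(x1 = x, z1 = z, t = t, y = y)
}

#' Correlated error pair
#'
#' Draws `n` rows from a bivariate normal with zero means, unit variances and
#' correlation `rho`, using the current RNG state. Exposed so that tests can
#' check the confounding structure in isolation.
#'
#' @param n Number of draws.
#' @param rho Correlation in (-1, 1).
#' @param seed Optional seed; if `NULL` the current RNG state is used.
#' @return A tibble with columns `e1`, `e2`.
#' @export
gen_errors <- function(n, rho = 0.8, seed = NULL) {
  stopifnot(rho > -1, rho < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tibble::as_tibble(gen_error_pair(n, rho))
}

gen_error_pair <- function(n, rho) {
  u1 <- rnorm(n)
  u2 <- rnorm(n)
  list(e1 = u1, e2 = rho * u1 + sqrt(1 - rho^2) * u2)
}

# the six nonlinear first-stage forms of the robustness study
dgp_f <- function(f_name) {
  switch(f_name,
    quadratic = function(z) z^2,
    cubic     = function(z) z^3,
    exp       = function(z) exp(z),
    log       = function(z) log(pmax(abs(z), 1e-12)),
    sqrt      = function(z) sqrt(abs(z)),
    logistic  = function(z) 1 / (1 + exp(-z)),
    abort(paste0("unknown f_name: ", f_name))
  )
}

#' Preset feature specifications for the simulation designs
#'
#' The predictor-matrix combinations used by the package's simulation studies,
#' as named [iv_spec()] objects, so that experiment code cannot drift from the
#' intended matrices:
#' \describe{
#'   \item{`"quadratic"`}{`X_t = (x, z, z^2)`, `X_y = (x, t_hat)`,
#'     `X_r = (x, z, z^2)` — the valid/non-instrument confusion study.}
#'   \item{`"linear_insufficient"`}{`X_t = (x, z)`, `X_r = (x, z, z^2)` — the
#'     deliberately misspecified linear first stage.}
#'   \item{`"quadratic_aug"`}{`X_t = (x, z, z^2)`, `X_r = (x, z, z^2, z^3)` —
#'     the corrected first stage with a one-degree-richer remainder model.}
#'   \item{`"cubic_aug"`}{`X_t = (x, z, z^2, z^3)`, `X_r` up to `z^4` — the
#'     attempted (and unsuccessful) fix of a non-instrument.}
#'   \item{`"cubic"`}{`X_t = X_r = (x, z, z^2, z^3)` — used by the robustness
#'     study for the non-quadratic first-stage forms.}
#' }
#'
#' @param name Preset name.
#' @return An [iv_spec()] object.
#' @export
preset_spec <- function(name = c("quadratic", "linear_insufficient",
                                 "quadratic_aug", "cubic_aug", "cubic")) {
  name <- match.arg(name)
  switch(name,
    quadratic = iv_spec(
      stage_one = c("x1", "z1", "z1^2"),
      stage_two = c("x1", "t_hat"),
      remainder = c("x1", "z1", "z1^2")),
    linear_insufficient = iv_spec(
      stage_one = c("x1", "z1"),
      stage_two = c("x1", "t_hat"),
      remainder = c("x1", "z1", "z1^2")),
    quadratic_aug = iv_spec(
      stage_one = c("x1", "z1", "z1^2"),
      stage_two = c("x1", "t_hat"),
      remainder = c("x1", "z1", "z1^2", "z1^3")),
    cubic_aug = iv_spec(
      stage_one = c("x1", "z1", "z1^2", "z1^3"),
      stage_two = c("x1", "t_hat"),
      remainder = c("x1", "z1", "z1^2", "z1^3", "z1^4")),
    cubic = iv_spec(
      stage_one = c("x1", "z1", "z1^2", "z1^3"),
      stage_two = c("x1", "t_hat"),
      remainder = c("x1", "z1", "z1^2", "z1^3"))
  )
}
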