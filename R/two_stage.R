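#' Fit stage one: predict the treatment
#'
#' Unconstrained least-squares fit of the treatment on the stage-one feature
#' matrix (covariates and instrument features), with the prediction-based
#' relevance check attached. A failed relevance check is reported in the
#' result, not raised — the analyst decides what to do with a weak instrument.
#'
#' @param data Data frame with `x*`, `z*`, `t` columns.
#' @param spec An [iv_spec()] (its `stage_one` terms are used).
#' @param epsilon Relevance threshold; default 5\% of the covariate-only loss.
#' @return An object of class `iv_stage1`: `omega` (coefficients), `t_hat`,
#'   `sse`, `relevance` (list from [relevance_check()]), `terms`.
#' @export
fit_stage_one <- function(data, spec, epsilon = NULL) {
  x_t <- build_design_matrix(data, spec, stage = "one")
  fit <- ols_fit(x_t, data$t)
  rel <- tryCatch(relevance_check(data, spec, epsilon = epsilon),
                  error = function(e) list(passed = NA, loss_with = fit$sse,
                                           loss_without = NA_real_,
                                           epsilon = NA_real_))
  structure(list(omega = fit$coefficients, t_hat = fit$fitted, sse = fit$sse,
                 relevance = rel,
                 terms = if (inherits(spec, "iv_spec")) spec$stage_one else spec),
            class = "iv_stage1")
}

# least-squares solve that tolerates a singular normal matrix:
# minimum-norm solution via SVD with tolerance 1e-10 * sigma_max
svd_lstsq <- function(a, b) {
  sv <- svd(a)
  keep <- sv$d > 1e-10 * sv$d[1]
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep]))
}

#' Minimum attainable value of the validity-constraint quadratic
#'
#' Minimizes `r' H r` (with `r = y - Xy beta`) over `beta`. Writing `Q` for an
#' orthonormal basis of the remainder model's column space, this is the least
#' squares problem `min || Q'y - (Q'Xy) beta ||^2`; when `Xy' H Xy` is singular
#' the minimum-norm solution is returned. If even this minimum exceeds
#' `epsilon_prime`, the constrained second stage is infeasible and the proposed
#' instrument is flagged.
#'
#' @param x_y Stage-two design matrix.
#' @param hat An [hat_matrix()] for the remainder model.
#' @param y Outcome vector.
#' @return A list with `beta_cmin` and `value` (the minimum, always >= 0).
#' @export
min_constraint_value <- function(x_y, hat, y) {
  a <- crossprod(hat$Q, as.matrix(x_y))
  b <- drop(crossprod(hat$Q, as.numeric(y)))
  beta <- svd_lstsq(a, b)
  val <- sum((b - a %*% beta)^2)
  list(beta_cmin = beta, value = max(val, 0))
}

#' Constrained second stage: outcome loss under the validity constraint
#'
#' Solves
#' \deqn{\min_\beta \|y - X_y\beta\|^2 \quad \mathrm{s.t.} \quad
#'       (y - X_y\beta)' H (y - X_y\beta) \le \epsilon',}
#' the quadratically constrained quadratic program at the heart of the
#' validity-constrained estimator. Both quadratics are positive semidefinite,
#' so the problem is convex and the KKT conditions are necessary and
#' sufficient; the returned solution is the global minimizer.
#'
#' Algorithm: (1) if the unconstrained least-squares solution satisfies the
#' constraint, it is returned with status `"inactive"`; (2) otherwise the
#' constraint's own minimum ([min_constraint_value()]) is computed — if it
#' exceeds `epsilon_prime` the problem is `"infeasible"` and no coefficients
#' are returned; (3) otherwise the constraint binds (`"active"`): the
#' stationarity system `(X'X + \lambda X'HX)\beta = X'y + \lambda X'Hy` is
#' solved along the multiplier path, and the secular equation (constraint
#' value as a monotone decreasing function of `\lambda \ge 0`) is solved by
#' bracketing and safeguarded root finding. By convexity the KKT point is
#' unique, so no tie-breaking between stationary points arises.
#'
#' @param y Outcome vector.
#' @param x_y Stage-two design matrix (full column rank).
#' @param hat Remainder-model projector from [hat_matrix()].
#' @param epsilon_prime Nonnegative constraint level (may be `Inf`, in which
#'   case the fit is the traditional unconstrained second stage).
#' @return An object of class `iv_stage2`: `beta` (or `NULL` if infeasible),
#'   `y_hat`, `r`, `status` in `{"inactive","active","infeasible"}`,
#'   `objective_value`, `constraint_value`, `epsilon_prime`, `lambda`,
#'   `constraint_min` (only when computed).
#' @export
constrained_stage_two <- function(y, x_y, hat, epsilon_prime) {
  if (!is.numeric(epsilon_prime) || length(epsilon_prime) != 1 ||
      is.na(epsilon_prime) || epsilon_prime < 0)
    abort("epsilon_prime must be a single nonnegative number")
  y <- as.numeric(y)
  x_y <- as.matrix(x_y)

  uncon <- ols_fit(x_y, y)
  cv0 <- hat_quad(hat, uncon$residuals)
  feas_tol <- epsilon_prime * (1 + 1e-8) + 1e-12
  if (cv0 <= feas_tol) {
    return(new_stage2(uncon$coefficients, x_y, y, "inactive", cv0,
                      epsilon_prime, lambda = 0))
  }

  cmin <- min_constraint_value(x_y, hat, y)
  if (cmin$value > feas_tol) {
    return(structure(list(beta = NULL, y_hat = NULL, r = NULL,
                          status = "infeasible",
                          objective_value = NA_real_,
                          constraint_value = NA_real_,
                          constraint_min = cmin$value,
                          epsilon_prime = epsilon_prime, lambda = NA_real_),
                     class = "iv_stage2"))
  }

  # active case: secular equation in the multiplier
  g0 <- crossprod(x_y)                 # X'X, positive definite
  c0 <- crossprod(x_y, y)
  a <- crossprod(hat$Q, x_y)           # so X'HX = a'a, X'Hy = a'b
  b <- drop(crossprod(hat$Q, y))
  g1 <- crossprod(a)
  c1 <- crossprod(a, b)
  beta_of <- function(lam) solve(g0 + lam * g1, c0 + lam * c1)
  cons_of <- function(lam) sum((b - a %*% beta_of(lam))^2)

  lo <- 0
  hi <- 1
  it <- 0
  while (cons_of(hi) > epsilon_prime) {
    lo <- hi
    hi <- hi * 4
    it <- it + 1
    if (it > 80)
      abort("multiplier search failed to bracket the active constraint level")
  }
  root <- tryCatch(
    stats::uniroot(function(l) cons_of(l) - epsilon_prime, c(lo, hi),
                   tol = .Machine$double.eps^0.75, maxiter = 2000),
    error = function(e) abort(paste0("solver failure in the active-case ",
                                     "multiplier search: ", conditionMessage(e))))
  beta <- drop(beta_of(root$root))
  new_stage2(beta, x_y, y, "active", cons_of(root$root), epsilon_prime,
             lambda = root$root, constraint_min = cmin$value)
}

new_stage2 <- function(beta, x_y, y, status, cv, eps, lambda,
                       constraint_min = NA_real_) {
  beta <- drop(beta)
  names(beta) <- colnames(x_y)
  y_hat <- drop(x_y %*% beta)
  r <- y - y_hat
  # refine the label: an inactive solution sitting numerically on the boundary
  # is reported as active
  act_tol <- max(1e-8 * eps, 1e-12)
  if (is.finite(eps) && abs(cv - eps) <= act_tol) status <- "active"
  structure(list(beta = beta, y_hat = y_hat, r = r, status = status,
                 objective_value = sum(r^2), constraint_value = cv,
                 constraint_min = constraint_min,
                 epsilon_prime = eps, lambda = lambda),
            class = "iv_stage2")
}

#' @export
print.iv_stage2 <- function(x, ...) {
  cat("<iv_stage2> constrained second stage —", x$status, "\n")
  if (!is.null(x$beta)) {
    cat("  beta:", paste(sprintf("%s=%.4f", names(x$beta), x$beta),
                         collapse = ", "), "\n")
    cat(sprintf("  objective %.4f, constraint %.6g <= eps' %.6g\n",
                x$objective_value, x$constraint_value, x$epsilon_prime))
  } else {
    cat(sprintf("  no feasible solution: min constraint %.6g > eps' %.6g\n",
                x$constraint_min, x$epsilon_prime))
  }
  invisible(x)
}

#' Traditional two-stage least squares
#'
#' The unconstrained baseline: least-squares stage one, then least-squares
#' stage two on covariates and the predicted treatment. Its remainder
#' `r_tilde = y - y_hat` is what calibrates the absolute validity tolerance
#' via [epsilon_prime_from_gamma()].
#'
#' @param data Data frame with `x*`, `z*`, `t`, `y`.
#' @param spec An [iv_spec()].
#' @return A list with `omega`, `beta`, `t_hat`, `y_hat`, `r_tilde`.
#' @export
fit_traditional <- function(data, spec) {
  x_t <- build_design_matrix(data, spec, stage = "one")
  s1 <- ols_fit(x_t, data$t)
  x_y <- build_design_matrix(data, spec, stage = "two", t_hat = s1$fitted)
  s2 <- ols_fit(x_y, data$y)
  list(omega = s1$coefficients, beta = s2$coefficients,
       t_hat = s1$fitted, y_hat = s2$fitted, r_tilde = s2$residuals)
}

#' Validity-constrained two-stage estimator
#'
#' The full procedure: (1) unconstrained stage one gives `t_hat` and the
#' relevance check; (2) the traditional second stage gives the calibration
#' remainder `r_tilde` and `epsilon' = gamma * ||r_tilde||^2`; (3) the
#' constrained second stage ([constrained_stage_two()]) minimizes outcome loss
#' subject to the validity constraint, with the projector taken from the
#' remainder design matrix; (4) the empirical validity check is reported for
#' the resulting remainder. An infeasible second stage means no coefficient
#' vector can make the remainder sufficiently unpredictable: the proposed
#' instrument is flagged as invalid.
#'
#' @param data Data frame with `x*`, `z*`, `t`, `y` columns.
#' @param spec An [iv_spec()] with the three stages' terms.
#' @param gamma Relative validity tolerance in `[0, 1)`; 0.01 is the study
#'   default at n = 1000.
#' @param epsilon Relevance threshold passed to [fit_stage_one()].
#' @param epsilon_prime Absolute tolerance override; if supplied, `gamma` is
#'   ignored for the constraint (still recorded).
#' @return An object of class `iv_two_stage` with components `stage_one`
#'   (`iv_stage1`), `stage_two` (`iv_stage2`), `validity` (`iv_validity`),
#'   `r_tilde`, `gamma`, `epsilon_prime`, `spec`, `n`.
#' @examples
#' d <- sim_iv_data(500, "valid", seed = 7)
#' fit <- fit_two_stage(d, preset_spec("quadratic"), gamma = 0.01)
#' fit$stage_two$status
#' @export
fit_two_stage <- function(data, spec, gamma = 0.01, epsilon = NULL,
                          epsilon_prime = NULL) {
  s1 <- fit_stage_one(data, spec, epsilon = epsilon)
  x_y <- build_design_matrix(data, spec, stage = "two", t_hat = s1$t_hat)
  trad <- ols_fit(x_y, data$y)
  r_tilde <- trad$residuals
  if (is.null(epsilon_prime))
    epsilon_prime <- epsilon_prime_from_gamma(gamma, r_tilde)
  x_r <- build_design_matrix(data, spec, stage = "remainder")
  h <- hat_matrix(x_r)
  s2 <- constrained_stage_two(data$y, x_y, h, epsilon_prime)
  # validity report: on the constrained remainder when one exists, otherwise
  # posthoc on the traditional remainder (which is what failed)
  r_report <- if (s2$status == "infeasible") r_tilde else s2$r
  vr <- validity_check(r_report, x_r, epsilon_prime, gamma)
  if (s2$status == "infeasible") vr$passed <- FALSE
  structure(list(stage_one = s1, stage_two = s2, validity = vr,
                 r_tilde = r_tilde, gamma = gamma,
                 epsilon_prime = epsilon_prime, spec = spec,
                 n = nrow(data)),
            class = "iv_two_stage")
}

#' @export
print.iv_two_stage <- function(x, ...) {
  cat(sprintf("<iv_two_stage> validity-constrained two-stage fit (n = %d)\n",
              x$n))
  cat("  stage one omega:",
      paste(sprintf("%s=%.4f", names(x$stage_one$omega), x$stage_one$omega),
            collapse = ", "), "\n")
  cat("  relevance passed:", x$stage_one$relevance$passed, "\n")
  print(x$stage_two)
  cat(sprintf("  validity: true percentage %.2f%%, passed %s\n",
              100 * x$validity$ratio, x$validity$passed))
  invisible(x)
}
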