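#' Fit the remainder model
#'
#' Least-squares fit of the second-stage remainder `r` on the remainder design
#' matrix `X_r` (features of covariates and instrument). Its fitted values
#' `r_hat` are the best prediction of the remainder the declared model class
#' can produce; the validity check compares their loss to the zero model's.
#' The model class is fixed and user-declared — no adaptive model search is
#' performed, which is the package's guard against overfitting the remainder.
#'
#' @param r Remainder vector (`y - y_hat`).
#' @param x_r Remainder design matrix.
#' @return A list with `alpha` (coefficients) and `r_hat` (fitted values).
#' @export
fit_remainder <- function(r, x_r) {
  fit <- ols_fit(x_r, r)
  list(alpha = fit$coefficients, r_hat = fit$fitted)
}

#' Convert the relative tolerance gamma to the absolute tolerance epsilon'
#'
#' The validity constraint is absolute — `loss(r, r_hat) >= loss(r, 0) - eps'`
#' — but it is easier to reason about a relative tolerance `gamma` ("the model
#' may explain at most this fraction of the remainder"). The two are linked
#' through the traditional two-stage remainder `r_tilde`, whose zero-model loss
#' anchors the scale: `eps' = gamma * loss(r_tilde, 0)`.
#'
#' @param gamma Relative tolerance, a nonnegative fraction (1\% at n = 1000 is
#'   the default used by the simulation studies).
#' @param r_tilde Remainder from the *unconstrained* traditional two-stage fit.
#' @return The absolute tolerance `epsilon_prime`.
#' @examples
#' epsilon_prime_from_gamma(0.01, c(1, 2, 2)) # 0.01 * 9 = 0.09
#' @export
epsilon_prime_from_gamma <- function(gamma, r_tilde) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0)
    abort("gamma must be a single nonnegative number")
  gamma * squared_loss(r_tilde, 0)
}

#' Empirical validity check on a remainder
#'
#' Fits the remainder model and tests whether the remainder can be predicted
#' better than a model that is identically zero, up to tolerance
#' `epsilon_prime`:
#' `passed <=> loss(r, r_hat) >= loss(r, 0) - epsilon_prime`.
#' Because `r_hat` is a least-squares projection, `loss(r, r_hat) <=
#' loss(r, 0)` always holds — the check can only fail by predicting the
#' remainder *too well*, which is evidence against the exclusion restriction
#' (or of a misspecified first stage).
#'
#' The report also carries the "true percentage" `ratio = loss(r, r_hat) /
#' loss(r, 0)` and its complement `gamma_true = 1 - ratio`, the fraction of the
#' remainder's squared norm the instrument model explains.
#'
#' @param r Remainder vector.
#' @param x_r Remainder design matrix.
#' @param epsilon_prime Absolute tolerance (see [epsilon_prime_from_gamma()]).
#' @param gamma Relative tolerance that produced `epsilon_prime`, recorded in
#'   the report (optional).
#' @return An object of class `iv_validity`: a list with `loss_r_zero`,
#'   `loss_r_hat`, `ratio`, `gamma_true`, `epsilon_prime`, `gamma`, `passed`.
#' @export
validity_check <- function(r, x_r, epsilon_prime, gamma = NA_real_) {
  stopifnot(epsilon_prime >= 0)
  loss_zero <- squared_loss(r, 0)
  if (loss_zero == 0) {
    # a remainder that is identically zero is unpredictable by convention
    return(new_validity_report(0, 0, 1, epsilon_prime, gamma, TRUE))
  }
  rem <- fit_remainder(r, x_r)
  loss_hat <- squared_loss(r, rem$r_hat)
  passed <- loss_hat >= loss_zero - epsilon_prime
  new_validity_report(loss_zero, loss_hat, loss_hat / loss_zero,
                      epsilon_prime, gamma, passed)
}

new_validity_report <- function(loss_zero, loss_hat, ratio, eps, gamma, passed) {
  structure(list(loss_r_zero = loss_zero, loss_r_hat = loss_hat,
                 ratio = ratio, gamma_true = 1 - ratio,
                 epsilon_prime = eps, gamma = gamma, passed = passed),
            class = "iv_validity")
}

#' @export
print.iv_validity <- function(x, ...) {
  cat("<iv_validity> empirical validity check\n")
  cat(sprintf("  loss(r, 0)     = %.4f\n", x$loss_r_zero))
  cat(sprintf("  loss(r, r_hat) = %.4f\n", x$loss_r_hat))
  cat(sprintf("  true percentage = %.2f%%  (gamma_true = %.4f)\n",
              100 * x$ratio, x$gamma_true))
  cat(sprintf("  epsilon' = %.6g%s\n", x$epsilon_prime,
              if (is.na(x$gamma)) "" else sprintf(" (gamma = %g)", x$gamma)))
  cat("  passed:", x$passed, "\n")
  invisible(x)
}

#' @method tidy iv_validity
#' @export
tidy.iv_validity <- function(x, ...) {
  tibble::tibble(
    loss_r_zero = x$loss_r_zero, loss_r_hat = x$loss_r_hat,
    ratio = x$ratio, gamma_true = x$gamma_true,
    epsilon_prime = x$epsilon_prime, gamma = x$gamma, passed = x$passed)
}

#' Prediction-based relevance check
#'
#' Tests the sample relevance assumption: the treatment must be predictable
#' from covariates and instrument together at least `epsilon` better (in
#' squared loss) than from the covariates alone.
#'
#' @param data Data frame with `x*`, `z*` and `t` columns.
#' @param terms_with Stage-one terms including instrument features.
#' @param terms_without Covariate-only terms; defaults to the `x`-terms of
#'   `terms_with`. Must not reference any instrument column.
#' @param epsilon Absolute improvement threshold; default 5\% of the
#'   covariate-only loss.
#' @return A list with `passed`, `loss_with`, `loss_without`, `epsilon`.
#' @export
relevance_check <- function(data, terms_with, terms_without = NULL,
                            epsilon = NULL) {
  if (inherits(terms_with, "iv_spec")) terms_with <- terms_with$stage_one
  if (is.null(terms_without)) {
    keep <- !vapply(terms_with,
                    function(tm) any(grepl("^z", term_vars(tm))),
                    logical(1))
    terms_without <- terms_with[keep]
  }
  if (any(grepl("^z", unlist(lapply(terms_without, term_vars)))))
    abort("terms_without must not reference an instrument column")
  if (length(terms_without) == 0)
    abort("covariate-only baseline has no terms")
  x_with <- build_design_matrix(data, terms_with, stage = "one")
  x_without <- build_design_matrix(data, terms_without, stage = "one")
  loss_with <- ols_fit(x_with, data$t)$sse
  loss_without <- ols_fit(x_without, data$t)$sse
  if (is.null(epsilon)) epsilon <- 0.05 * loss_without
  list(passed = loss_with <= loss_without - epsilon,
       loss_with = loss_with, loss_without = loss_without, epsilon = epsilon)
}
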