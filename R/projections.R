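#' Orthogonal projector onto a design matrix's column space
#'
#' Computes the hat (projection) matrix of a full-column-rank design matrix via
#' a QR decomposition — the normal equations are never formed or inverted
#' explicitly, since the polynomial feature sets used here can be strongly
#' correlated (z and z^3 correlate about 0.77 under a standard normal z).
#'
#' The dense `n x n` matrix is materialized only for `n <= 5000`; beyond that
#' every operation runs through the thin orthogonal factor `Q` (`H = Q Q'`),
#' with identical results.
#'
#' @param xd Design matrix with full column rank.
#' @return An object of class `iv_hat` with fields `Q` (n x k orthonormal
#'   basis), `rank`, `n`, and `H` (dense projector, or `NULL` when `n > 5000`).
#' @export
hat_matrix <- function(xd) {
  xd <- as.matrix(xd)
  qrx <- qr(xd)
  if (qrx$rank < ncol(xd))
    abort("design matrix is rank deficient; projector is not defined")
  q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  h <- if (nrow(xd) <= 5000) tcrossprod(q) else NULL
  structure(list(Q = q, rank = qrx$rank, n = nrow(xd), H = h),
            class = "iv_hat")
}

#' @export
print.iv_hat <- function(x, ...) {
  cat("<iv_hat> projector onto a rank-", x$rank, " subspace of R^", x$n,
      if (is.null(x$H)) " (factored form)" else " (dense form)", "\n", sep = "")
  invisible(x)
}

# H %*% v without requiring the dense projector
hat_apply <- function(hat, v) hat$Q %*% crossprod(hat$Q, v)

# v' H v (= ||Q'v||^2), the ellipsoidal quadratic form
hat_quad <- function(hat, v) sum(crossprod(hat$Q, v)^2)

#' Ordinary least squares fit
#'
#' QR-based least squares of `target` on `xd`, returning the pieces the
#' estimators need: coefficients, fitted values (`H target`), residuals and
#' the squared loss (SSE).
#'
#' @param xd Full-column-rank design matrix with more rows than columns.
#' @param target Numeric response vector.
#' @return A list with `coefficients`, `fitted`, `residuals`, `sse`.
#' @export
ols_fit <- function(xd, target) {
  xd <- as.matrix(xd)
  target <- as.numeric(target)
  stopifnot(nrow(xd) == length(target))
  if (nrow(xd) <= ncol(xd))
    abort("need more observations than design-matrix columns")
  qrx <- qr(xd)
  if (qrx$rank < ncol(xd))
    abort("design matrix is rank deficient; least-squares fit is not unique")
  coefs <- qr.coef(qrx, target)
  fitted <- drop(xd %*% coefs)
  res <- target - fitted
  list(coefficients = coefs, fitted = fitted, residuals = res,
       sse = sum(res^2))
}

#' Squared loss against a fixed prediction
#'
#' `loss(a, b) = sum((a - b)^2)`; `b = 0` gives the zero-model loss that the
#' validity check uses as its baseline.
#'
#' @param target,prediction Numeric vectors (`prediction` may be a scalar 0).
#' @return The summed squared loss.
#' @export
squared_loss <- function(target, prediction = 0) sum((target - prediction)^2)

#' The ellipsoidal validity-constraint quadratic
#'
#' Evaluates `beta' Xy' H Xy beta - 2 beta' Xy' H y + y' H y`, which equals
#' `r' H r` for the remainder `r = y - Xy beta`: the part of the remainder's
#' squared norm that lies inside the remainder model's column space, i.e. how
#' much of the remainder the instrument-and-covariate model could explain. It
#' is nonnegative, and the second-stage constraint bounds it by `epsilon_prime`.
#'
#' @param beta Stage-two coefficient vector.
#' @param x_y Stage-two design matrix.
#' @param hat An [hat_matrix()] projector for the remainder model (or a plain
#'   symmetric projection matrix).
#' @param y Outcome vector.
#' @return The scalar value of the quadratic form.
#' @export
constraint_quadratic <- function(beta, x_y, hat, y) {
  r <- as.numeric(y) - drop(as.matrix(x_y) %*% beta)
  if (inherits(hat, "iv_hat")) return(hat_quad(hat, r))
  drop(crossprod(r, as.matrix(hat) %*% r))
}
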