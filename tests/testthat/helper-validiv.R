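# small deterministic instruments-and-treatment dataset for algebra tests
toy_data <- function(n = 40, seed = 1, rho = 0.8) {
  sim_iv_data(n, "valid", seed = seed, rho = rho)
}

# dense grid search over a 2-parameter constrained problem: the brute-force
# oracle for the QCQP solver
grid_search_qcqp <- function(y, x_y, hat, eps, center, half_width = 0.6,
                             by = 0.005) {
  g1 <- seq(center[1] - half_width, center[1] + half_width, by = by)
  g2 <- seq(center[2] - half_width, center[2] + half_width, by = by)
  bg <- as.matrix(expand.grid(g1, g2))
  preds <- x_y %*% t(bg)
  obj <- colSums((y - preds)^2)
  qb <- crossprod(hat$Q, x_y) %*% t(bg)
  cons <- colSums((drop(crossprod(hat$Q, y)) - qb)^2)
  feas <- cons <= eps
  if (!any(feas)) return(list(value = Inf, beta = NULL))
  i <- which(feas)[which.min(obj[feas])]
  list(value = obj[i], beta = bg[i, ])
}

# dense search over the boundary of the constraint ellipse: for a 2-parameter
# problem with the constraint active, the optimum lies on the ellipse
# (beta - beta_cmin)' M (beta - beta_cmin) = eps - cmin, which we parametrize
# exactly and scan at fine angular resolution
boundary_search_qcqp <- function(y, x_y, hat, eps, n_angles = 2e5) {
  a <- crossprod(hat$Q, x_y)
  b <- drop(crossprod(hat$Q, y))
  m <- crossprod(a)
  cm <- min_constraint_value(x_y, hat, y)
  rad <- sqrt(max(eps - cm$value, 0))
  rinv <- solve(chol(m))
  th <- seq(0, 2 * pi, length.out = n_angles)
  pts <- cm$beta_cmin + rad * rinv %*% rbind(cos(th), sin(th))
  obj <- colSums((y - x_y %*% pts)^2)
  i <- which.min(obj)
  list(value = obj[i], beta = pts[, i])
}

# classical just-identified linear IV estimate of the treatment coefficient:
# partial the covariate out of z, t, y, then take the ratio of covariances
classical_iv_beta <- function(d) {
  rz <- resid(lm(z1 ~ x1 + 0, data = d))
  rt <- resid(lm(t ~ x1 + 0, data = d))
  ry <- resid(lm(y ~ x1 + 0, data = d))
  sum(rz * ry) / sum(rz * rt)
}
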