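#' Covariate-only baseline loss for the Rashomon constraint
#'
#' Best achievable stage-one squared loss using the covariates alone — the
#' anchor for the one-stage method's Rashomon-set constraint, which admits any
#' stage-one model whose treatment-prediction loss beats this baseline by at
#' least `epsilon`. With no covariate terms, an intercept-only model is used,
#' so the baseline is the total sum of squares about the mean.
#'
#' @param data Data frame with `x*` and `t` columns.
#' @param terms_x_only Covariate-only terms; defaults to the `x`-terms of
#'   `spec$stage_one` when an [iv_spec()] is given.
#' @return The baseline squared loss (scalar).
#' @export
rashomon_baseline <- function(data, terms_x_only) {
  if (inherits(terms_x_only, "iv_spec")) {
    keep <- !vapply(terms_x_only$stage_one,
                    function(tm) any(grepl("^z", term_vars(tm))), logical(1))
    terms_x_only <- terms_x_only$stage_one[keep]
  }
  if (any(grepl("^z", unlist(lapply(terms_x_only, term_vars)))))
    abort("rashomon baseline terms must not reference an instrument column")
  if (length(terms_x_only) == 0)
    return(sum((data$t - mean(data$t))^2))
  x <- build_design_matrix(data, terms_x_only, stage = "one")
  ols_fit(x, data$t)$sse
}

#' One-stage joint estimator
#'
#' Minimizes the outcome loss over both stages' coefficients simultaneously:
#' \deqn{\min_{\omega,\beta} \|y - X_y(\hat t(\omega))\beta\|^2}
#' subject to (i) the Rashomon (relevance) constraint
#' `loss(t, t_hat) <= loss(t, x-only baseline) - epsilon` and (ii) the
#' validity constraint `r' H r <= epsilon_prime`. The joint problem is
#' nonconvex in general, so it is attacked by block-coordinate descent: for
#' fixed `omega` the `beta` subproblem is exactly the convex
#' [constrained_stage_two()] (solved globally); for fixed `beta` the `omega`
#' subproblem is solved by projected descent on the Rashomon ellipsoid
#' (backtracking line search; retraction toward the unconstrained stage-one
#' optimum in the `X_t'X_t` metric). Multiple restarts are used, always
#' including the two-stage/traditional stage-one solution, plus seeded random
#' points inside the Rashomon set; the best feasible point found is returned.
#'
#' Because each `beta` step is solved globally and each `omega` step only
#' accepts decreases, the objective is non-increasing along every restart.
#' Every returned solution is re-checked against both constraints
#' independently of the solver path.
#'
#' @param data Data frame with `x*`, `z*`, `t`, `y`.
#' @param spec An [iv_spec()].
#' @param gamma Relative validity tolerance (as in [fit_two_stage()]).
#' @param epsilon Rashomon margin; default 5\% of the covariate-only baseline
#'   loss. `epsilon = 0` makes the relevance constraint vacuous for any model
#'   at least as good as the baseline.
#' @param restarts Number of starts (>= 1, default 10).
#' @param seed Seed for the random restarts; identical seed and configuration
#'   give identical results.
#' @param max_iter Maximum outer (alternation) iterations per restart.
#' @param tol Relative objective-improvement stopping tolerance.
#' @return An object of class `iv_one_stage`: `omega`, `beta`, `t_hat`,
#'   `objective_value`, `rashomon_slack`, `validity_constraint_value`,
#'   `epsilon_prime`, `status` in `{"feasible","infeasible","solver_failed"}`,
#'   `restarts_used`.
#' @export
fit_one_stage <- function(data, spec, gamma = 0.01, epsilon = NULL,
                          restarts = 10, seed = 1, max_iter = 200,
                          tol = 1e-9) {
  stopifnot(restarts >= 1)
  set.seed(as.integer(seed))

  x_t <- build_design_matrix(data, spec, stage = "one")
  x_r <- build_design_matrix(data, spec, stage = "remainder")
  h <- hat_matrix(x_r)
  t_vec <- data$t
  y_vec <- data$y

  s1 <- ols_fit(x_t, t_vec)            # unconstrained stage-one optimum
  gmat <- crossprod(x_t)               # metric of the Rashomon ellipsoid
  baseline <- rashomon_baseline(data, spec)
  if (is.null(epsilon)) epsilon <- 0.05 * baseline
  rash_cap <- baseline - epsilon       # loss(t, t_hat) must stay below this

  if (s1$sse > rash_cap + 1e-12 * max(1, rash_cap)) {
    # even the best stage-one model misses the Rashomon set: the instrument
    # adds too little treatment-prediction power
    return(new_one_stage(NULL, NULL, NULL, NA_real_, rash_cap - s1$sse,
                         NA_real_, NA_real_, "infeasible", 0L))
  }

  # validity tolerance calibrated once, from the traditional fit
  trad <- fit_traditional(data, spec)
  epsilon_prime <- epsilon_prime_from_gamma(gamma, trad$r_tilde)

  objective_for <- function(omega) {
    t_hat <- drop(x_t %*% omega)
    x_y <- build_design_matrix(data, spec, stage = "two", t_hat = t_hat)
    s2 <- constrained_stage_two(y_vec, x_y, h, epsilon_prime)
    list(s2 = s2, t_hat = t_hat,
         value = if (s2$status == "infeasible") Inf else s2$objective_value)
  }

  # retraction onto the Rashomon set: shrink toward the stage-one optimum
  retract <- function(omega) {
    quad <- drop(crossprod(omega - s1$coefficients,
                           gmat %*% (omega - s1$coefficients)))
    room <- rash_cap - s1$sse
    if (quad <= room || room <= 0) return(omega)
    s1$coefficients + sqrt(room / quad) * (omega - s1$coefficients)
  }

  rand_start <- function() {
    dir <- rnorm(length(s1$coefficients))
    quad <- drop(crossprod(dir, gmat %*% dir))
    room <- max(rash_cap - s1$sse, 0)
    s1$coefficients + runif(1) * sqrt(room / quad) * dir
  }

  starts <- c(list(s1$coefficients),
              replicate(restarts - 1, rand_start(), simplify = FALSE))

  best <- NULL
  best_val <- Inf
  used <- 0L
  failed <- FALSE
  for (omega0 in starts) {
    used <- used + 1L
    omega <- retract(omega0)
    cur <- objective_for(omega)
    it <- 0
    repeat {
      it <- it + 1
      if (it > max_iter) { failed <- failed || !is.finite(cur$value); break }
      # omega step: projected descent with numeric gradient and backtracking
      if (is.finite(cur$value)) {
        grad <- num_grad(function(w) {
          t_hat <- drop(x_t %*% w)
          x_y <- build_design_matrix(data, spec, stage = "two", t_hat = t_hat)
          sum((y_vec - drop(x_y %*% cur$s2$beta))^2)
        }, omega)
        step <- 1 / max(sum(grad^2), 1e-12)^0.5
        improved <- FALSE
        for (ls in 1:30) {
          cand <- retract(omega - step * grad)
          nxt <- objective_for(cand)
          if (is.finite(nxt$value) && nxt$value < cur$value - 1e-14) {
            omega <- cand; prev_val <- cur$value; cur <- nxt; improved <- TRUE
            break
          }
          step <- step / 2
        }
        if (!improved) break
        if ((prev_val - cur$value) <= tol * max(1, abs(prev_val))) break
      } else {
        # current omega yields an infeasible beta subproblem: nudge toward the
        # stage-one optimum, which can restore validity feasibility
        omega <- s1$coefficients + 0.5 * (omega - s1$coefficients)
        cur <- objective_for(omega)
        if (it > 60) break
      }
    }
    if (is.finite(cur$value) && cur$value < best_val) {
      best_val <- cur$value
      best <- list(omega = omega, cur = cur)
    }
  }

  if (is.null(best)) {
    status <- if (failed) "solver_failed" else "infeasible"
    return(new_one_stage(NULL, NULL, NULL, NA_real_, NA_real_, NA_real_,
                         epsilon_prime, status, used))
  }

  omega <- best$omega
  s2 <- best$cur$s2
  t_hat <- best$cur$t_hat
  # independent re-check of both constraints (no trust in solver internals)
  stage1_loss <- squared_loss(t_vec, t_hat)
  cv <- constraint_quadratic(s2$beta,
                             build_design_matrix(data, spec, stage = "two",
                                                 t_hat = t_hat),
                             h, y_vec)
  ok <- stage1_loss <= rash_cap * (1 + 1e-8) + 1e-12 &&
    cv <= epsilon_prime * (1 + 1e-8) + 1e-12
  new_one_stage(omega, s2$beta, t_hat, s2$objective_value,
                rash_cap - stage1_loss, cv, epsilon_prime,
                if (ok) "feasible" else "solver_failed", used)
}

new_one_stage <- function(omega, beta, t_hat, obj, slack, cv, eps, status,
                          used) {
  structure(list(omega = omega, beta = beta, t_hat = t_hat,
                 objective_value = obj, rashomon_slack = slack,
                 validity_constraint_value = cv, epsilon_prime = eps,
                 status = status, restarts_used = used),
            class = "iv_one_stage")
}

num_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    up <- x; up[i] <- up[i] + eps
    dn <- x; dn[i] <- dn[i] - eps
    g[i] <- (f(up) - f(dn)) / (2 * eps)
  }
  g
}

#' @export
print.iv_one_stage <- function(x, ...) {
  cat("<iv_one_stage> joint estimator —", x$status,
      sprintf("(%d restart%s)\n", x$restarts_used,
              if (x$restarts_used == 1) "" else "s"))
  if (!is.null(x$beta)) {
    cat("  beta:", paste(sprintf("%s=%.4f", names(x$beta), x$beta),
                         collapse = ", "), "\n")
    cat(sprintf("  objective %.4f; rashomon slack %.4f; validity %.6g <= %.6g\n",
                x$objective_value, x$rashomon_slack,
                x$validity_constraint_value, x$epsilon_prime))
  }
  invisible(x)
}
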