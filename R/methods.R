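#' Tidy a constrained two-stage fit
#'
#' One row per coefficient across both stages, in the usual broom layout.
#'
#' @param x An `iv_two_stage` object.
#' @param ... Unused.
#' @return A tibble with columns `stage`, `term`, `estimate`.
#' @method tidy iv_two_stage
#' @export
tidy.iv_two_stage <- function(x, ...) {
  s1 <- tibble::tibble(stage = "one", term = names(x$stage_one$omega),
                       estimate = unname(x$stage_one$omega))
  if (is.null(x$stage_two$beta)) return(s1)
  dplyr::bind_rows(
    s1,
    tibble::tibble(stage = "two", term = names(x$stage_two$beta),
                   estimate = unname(x$stage_two$beta)))
}

#' Glance at a constrained two-stage fit
#'
#' @param x An `iv_two_stage` object.
#' @param ... Unused.
#' @return A one-row tibble: sample size, constraint status, objective and
#'   constraint values, tolerances, the validity check's true percentage and
#'   pass flag, and the relevance check's verdict.
#' @method glance iv_two_stage
#' @export
glance.iv_two_stage <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    status = x$stage_two$status,
    objective_value = x$stage_two$objective_value,
    constraint_value = x$stage_two$constraint_value,
    epsilon_prime = x$epsilon_prime,
    gamma = x$gamma,
    true_percentage = 100 * x$validity$ratio,
    validity_passed = x$validity$passed,
    relevance_passed = x$stage_one$relevance$passed)
}

#' @method tidy iv_one_stage
#' @export
tidy.iv_one_stage <- function(x, ...) {
  if (is.null(x$omega)) return(tibble::tibble(stage = character(),
                                              term = character(),
                                              estimate = double()))
  dplyr::bind_rows(
    tibble::tibble(stage = "one", term = names(x$omega),
                   estimate = unname(x$omega)),
    tibble::tibble(stage = "two", term = names(x$beta),
                   estimate = unname(x$beta)))
}

#' @method glance iv_one_stage
#' @export
glance.iv_one_stage <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    objective_value = x$objective_value,
    rashomon_slack = x$rashomon_slack,
    validity_constraint_value = x$validity_constraint_value,
    epsilon_prime = x$epsilon_prime,
    restarts_used = x$restarts_used)
}

#' Plot a robustness study
#'
#' Median treatment-coefficient estimate with its empirical 95\% band against
#' instrument strength, one panel per first-stage form, colored by method.
#' The dashed line marks the generating coefficient (1).
#'
#' @param object An `iv_robustness` tibble from [run_robustness()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot iv_robustness
#' @export
autoplot.iv_robustness <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pi, y = .data$median_beta,
                               color = .data$method, fill = .data$method)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        color = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci95_low,
                                      ymax = .data$ci95_high),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~f) +
    ggplot2::labs(x = "instrument strength (pi)",
                  y = "estimated treatment coefficient",
                  color = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object An `iv_confusion` object from [run_confusion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot iv_confusion
#' @export
autoplot.iv_confusion <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("infeasible", "feasible"),
                              names_to = "verdict", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$verdict, y = .data$truth,
                                     fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), color = "white") +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = "constrained-fit verdict", y = "generating process") +
    ggplot2::theme_minimal()
}
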