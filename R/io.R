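#' Read an IV dataset from CSV
#'
#' Expects a header row with covariate columns `x1, x2, ...`, instrument
#' columns `z1, z2, ...`, a treatment column `t` and an outcome column `y`.
#' Missing columns, non-numeric cells and missing values are reported with
#' row numbers.
#'
#' @param path CSV file path.
#' @return A tibble with the validated columns, `x*` and `z*` first.
#' @export
read_iv_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  xz <- sort(grep("^[xz][0-9]+$", names(d), value = TRUE))
  missing <- setdiff(c("t", "y"), names(d))
  if (length(missing))
    abort(paste0("dataset is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  if (!any(grepl("^x[0-9]+$", xz))) abort("dataset has no covariate (x*) column")
  if (!any(grepl("^z[0-9]+$", xz))) abort("dataset has no instrument (z*) column")
  d <- d[, c(xz, "t", "y")]
  for (nm in names(d)) {
    if (!is.numeric(d[[nm]]))
      abort(paste0("column '", nm, "' is not numeric"))
    bad <- which(!is.finite(d[[nm]]))
    if (length(bad))
      abort(paste0("column '", nm, "' has missing/non-finite values at row(s) ",
                   paste(utils::head(bad, 5), collapse = ", ")))
  }
  d
}

#' Write an IV dataset to CSV
#'
#' Full-precision write (readr's shortest round-trip representation), so a
#' written-and-reread dataset reproduces the in-memory values.
#'
#' @param data Data frame with `x*`, `z*`, `t`, `y` columns.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_iv_csv <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

# turn fitted objects into plain lists that serialize cleanly
result_payload <- function(x, ...) UseMethod("result_payload")

#' @export
result_payload.iv_two_stage <- function(x, ...) {
  list(
    method = "two_stage",
    n = x$n,
    gamma = x$gamma,
    epsilon_prime = x$epsilon_prime,
    spec = unclass(x$spec),
    omega = as.list(x$stage_one$omega),
    relevance = x$stage_one$relevance,
    beta = if (is.null(x$stage_two$beta)) NULL else as.list(x$stage_two$beta),
    status = x$stage_two$status,
    objective_value = x$stage_two$objective_value,
    constraint_value = x$stage_two$constraint_value,
    validity_report = unclass(x$validity))
}

#' @export
result_payload.iv_one_stage <- function(x, ...) {
  list(
    method = "one_stage",
    status = x$status,
    restarts_used = x$restarts_used,
    omega = if (is.null(x$omega)) NULL else as.list(x$omega),
    beta = if (is.null(x$beta)) NULL else as.list(x$beta),
    objective_value = x$objective_value,
    rashomon_slack = x$rashomon_slack,
    validity_constraint_value = x$validity_constraint_value,
    epsilon_prime = x$epsilon_prime)
}

#' @export
result_payload.iv_validity <- function(x, ...) c(list(method = "check"),
                                                 unclass(x))

#' @export
result_payload.iv_confusion <- function(x, ...) {
  list(
    method = "confusion",
    n_sims_per_row = attr(x, "n_sims"), n = attr(x, "n"),
    phi = attr(x, "phi"), gamma = attr(x, "gamma"), seed = attr(x, "seed"),
    rows = c("Not an instrument", "Valid instrument"),
    columns = c("Predicted to be invalid. (There is no feasible solution.)",
                "Predicted to be valid. (There is a feasible solution.)"),
    counts = list(as.integer(c(x$infeasible[1], x$feasible[1])),
                  as.integer(c(x$infeasible[2], x$feasible[2]))))
}

#' Write a fitted result to JSON
#'
#' Serializes any of the package's result objects (two-stage or one-stage
#' fits, validity reports, confusion matrices) with a schema version and, when
#' available, the configuration needed to replay the run. Numbers are written
#' at full precision; an infeasible fit carries `"beta": null`.
#'
#' @param result A fitted object.
#' @param path Destination path, or `NULL` to return the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
write_iv_json <- function(result, path = NULL) {
  payload <- c(list(schema = "validiv/1"), result_payload(result))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
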