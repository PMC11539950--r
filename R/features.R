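#' Declarative feature specification for the three IV model stages
#'
#' An `iv_spec` names the feature columns of the three design matrices used by
#' the estimators: `stage_one` predicts the treatment from covariates and the
#' instrument, `stage_two` predicts the outcome from covariates and the
#' predicted treatment `t_hat`, and `remainder` is the model class allowed to
#' try to predict the second-stage remainder from covariates and instrument.
#'
#' Terms are strings over the dataset's columns (`x1`, `x2`, ..., `z1`, ...)
#' plus the pseudo-variable `t_hat` (stage two only). Supported forms:
#' `"x1"` (identity), `"z1^3"` (power), `"exp(z1)"`, `"log|z1|"`, `"sqrt|z1|"`,
#' `"logistic(z1)"`, and products such as `"x1*z1"` or `"x1*t_hat"`.
#'
#' Stage-two terms may never reference an instrument column: a direct
#' dependence of the outcome model on `z` would contradict what it means for
#' `z` to be an instrument, so such specs are rejected at construction and
#' again at every matrix build. Conversely `t_hat` is only meaningful in stage
#' two.
#'
#' @param stage_one,stage_two,remainder Character vectors of terms.
#' @param intercept Add a leading column of ones to every matrix. The default
#'   (`FALSE`) matches the predictor matrices used by the simulation studies,
#'   e.g. `X_t = (x, z, z^2)`.
#' @param normalize Z-score every feature column before fitting (recommended
#'   when losses must be compared across datasets on different scales; the
#'   simulation reproductions keep raw scale).
#' @return An object of class `iv_spec`.
#' @examples
#' iv_spec(c("x1", "z1", "z1^2"), c("x1", "t_hat"), c("x1", "z1", "z1^2"))
#' @export
iv_spec <- function(stage_one, stage_two, remainder,
                    intercept = FALSE, normalize = FALSE) {
  spec <- structure(
    list(stage_one = as.character(stage_one),
         stage_two = as.character(stage_two),
         remainder = as.character(remainder),
         intercept = isTRUE(intercept),
         normalize = isTRUE(normalize)),
    class = "iv_spec")
  for (st in c("stage_one", "stage_two", "remainder")) {
    terms <- spec[[st]]
    if (anyDuplicated(terms))
      abort(paste0("duplicate terms in ", st, " spec"))
    vars <- unlist(lapply(terms, term_vars))
    if (st == "stage_two" && any(grepl("^z", vars)))
      abort("validity violation: stage-two terms may not reference the instrument (z*)")
    if (st != "stage_two" && any(vars == "t_hat"))
      abort(paste0("t_hat is only available in stage two (found in ", st, ")"))
  }
  spec
}

#' @export
print.iv_spec <- function(x, ...) {
  cat("<iv_spec>\n")
  cat("  stage one:", paste(x$stage_one, collapse = ", "), "\n")
  cat("  stage two:", paste(x$stage_two, collapse = ", "), "\n")
  cat("  remainder:", paste(x$remainder, collapse = ", "), "\n")
  cat("  intercept:", x$intercept, " normalize:", x$normalize, "\n")
  invisible(x)
}

# variables referenced by one term string
term_vars <- function(term) {
  factors <- strsplit(term, "*", fixed = TRUE)[[1]]
  vapply(factors, function(f) {
    f <- trimws(f)
    m <- regmatches(f, regexec(
      "^(?:(exp|logistic)\\(([A-Za-z_0-9]+)\\)|(log|sqrt)\\|([A-Za-z_0-9]+)\\||([A-Za-z_0-9]+)(?:\\^([0-9]+))?)$",
      f))[[1]]
    if (length(m) == 0) abort(paste0("cannot parse term: '", term, "'"))
    v <- c(m[3], m[5], m[6])
    v[v != ""][1]
  }, character(1), USE.NAMES = FALSE)
}

# evaluate one term on a data frame (t_hat supplied separately)
eval_term <- function(term, data, t_hat = NULL) {
  factors <- trimws(strsplit(term, "*", fixed = TRUE)[[1]])
  col <- 1
  for (f in factors) {
    m <- regmatches(f, regexec(
      "^(?:(exp|logistic)\\(([A-Za-z_0-9]+)\\)|(log|sqrt)\\|([A-Za-z_0-9]+)\\||([A-Za-z_0-9]+)(?:\\^([0-9]+))?)$",
      f))[[1]]
    fun <- if (m[2] != "") m[2] else if (m[4] != "") m[4] else "identity"
    var <- c(m[3], m[5], m[6])
    var <- var[var != ""][1]
    pow <- if (length(m) >= 7 && m[7] != "") as.integer(m[7]) else 1L
    base <- if (var == "t_hat") {
      if (is.null(t_hat)) abort("term references t_hat but no t_hat was supplied")
      t_hat
    } else {
      if (!var %in% names(data))
        abort(paste0("term references '", var, "' which is not a column of the data"))
      data[[var]]
    }
    val <- switch(fun,
      identity = base^pow,
      exp = exp(base),
      logistic = 1 / (1 + exp(-base)),
      # |z| clipped away from zero so log is always finite (the event has
      # probability zero under the generators but must be deterministic)
      log = log(pmax(abs(base), 1e-12)),
      sqrt = sqrt(abs(base)))
    col <- col * val
  }
  col
}

#' Build a design matrix from a feature specification
#'
#' Evaluates the terms of one stage of an [iv_spec()] on a dataset, in spec
#' order, optionally z-scoring columns and prepending an intercept. The result
#' is checked for full column rank; a rank-deficient matrix (collinear
#' features) is an error rather than a silent pseudo-inverse fit.
#'
#' @param data Data frame with covariate columns `x*`, instrument columns `z*`,
#'   and (for model fitting) `t`, `y`.
#' @param spec An [iv_spec()] or a character vector of terms.
#' @param stage Which stage's terms to build when `spec` is an `iv_spec`:
#'   `"one"`, `"two"` or `"remainder"`.
#' @param t_hat Predicted-treatment vector; required iff the terms reference
#'   `t_hat`.
#' @param normalize,intercept Overrides; default to the spec's settings.
#' @return A numeric matrix with one column per term (plus `(Intercept)` if
#'   requested), with term strings as column names.
#' @export
build_design_matrix <- function(data, spec, stage = c("one", "two", "remainder"),
                                t_hat = NULL, normalize = NULL, intercept = NULL) {
  stage <- match.arg(stage)
  if (inherits(spec, "iv_spec")) {
    terms <- switch(stage, one = spec$stage_one, two = spec$stage_two,
                    remainder = spec$remainder)
    if (is.null(normalize)) normalize <- spec$normalize
    if (is.null(intercept)) intercept <- spec$intercept
  } else {
    terms <- as.character(spec)
    if (is.null(normalize)) normalize <- FALSE
    if (is.null(intercept)) intercept <- FALSE
  }
  if (stage == "two") {
    vars <- unlist(lapply(terms, term_vars))
    if (any(grepl("^z", vars)))
      abort("validity violation: stage-two matrix would contain an instrument column")
  }
  cols <- lapply(terms, eval_term, data = data, t_hat = t_hat)
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  if (normalize) m <- standardize_columns(m)$x
  if (intercept) {
    m <- cbind(1, m)
    colnames(m)[1] <- "(Intercept)"
  }
  qrm <- qr(m)
  if (qrm$rank < ncol(m))
    abort(paste0("design matrix is rank deficient (multicollinear features): rank ",
                 qrm$rank, " < ", ncol(m), " columns"))
  m
}

#' Z-score the columns of a matrix
#'
#' Centers and scales each column to mean 0, standard deviation 1, returning
#' the centers and scales so the transform can be inverted.
#'
#' @param x Numeric matrix.
#' @return A list with elements `x` (transformed matrix), `centers`, `scales`.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  centers <- colMeans(x)
  scales <- apply(x, 2, sd)
  bad <- which(scales < .Machine$double.eps^0.5)
  if (length(bad))
    abort(paste0("zero-variance column cannot be standardized: ",
                 paste(colnames(x)[bad] %||% bad, collapse = ", ")))
  out <- sweep(sweep(x, 2, centers), 2, scales, "/")
  list(x = out, centers = centers, scales = scales)
}

#' Invert a column standardization
#'
#' @param std A list as returned by [standardize_columns()].
#' @return The matrix on its original scale.
#' @export
unstandardize_columns <- function(std) {
  sweep(sweep(std$x, 2, std$scales, "*"), 2, std$centers, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / deserialize a feature specification
#'
#' `spec_to_json()` writes an [iv_spec()] as a JSON object with keys
#' `stage_one`, `stage_two`, `remainder`, `intercept`, `normalize`;
#' `spec_from_json()` reads it back.
#'
#' @param spec An [iv_spec()].
#' @param path File path; for `spec_to_json`, `NULL` returns the JSON string.
#' @return `spec_to_json`: the path (or JSON string) invisibly;
#'   `spec_from_json`: an [iv_spec()].
#' @export
spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "iv_spec"))
  js <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  iv_spec(obj$stage_one, obj$stage_two, obj$remainder,
          intercept = isTRUE(obj$intercept), normalize = isTRUE(obj$normalize))
}
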