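#' Define an ordered Likert response scale
#'
#' The EMA items analysed by this package are answered on an ordered
#' categorical scale whose category labels are also the numeric scores used
#' when computing means (for a standard 5-point scale the values are
#' 1, 2, 3, 4, 5).
#'
#' @param n_categories Number of response categories (at least 2).
#' @param values Strictly increasing numeric scores attached to the
#'   categories; defaults to `1:n_categories`.
#'
#' @return An object of class `likert_scale` with fields `n_categories` and
#'   `values`.
#' @export
#' @examples
#' likert_scale()           # the 5-point scale used throughout
#' likert_scale(3)          # a 3-point scale, categories scored 1, 2, 3
likert_scale <- function(n_categories = 5L, values = seq_len(n_categories)) {
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 2L) {
    abort("`n_categories` must be an integer >= 2.")
  }
  values <- as.numeric(values)
  if (length(values) != n_categories) {
    abort("`values` must have one score per category.")
  }
  if (anyNA(values) || any(diff(values) <= 0)) {
    abort("`values` must be strictly increasing and non-missing.")
  }
  structure(
    list(n_categories = n_categories, values = values),
    class = "likert_scale"
  )
}

#' @export
print.likert_scale <- function(x, ...) {
  cat("<likert_scale> ", x$n_categories, " categories: ",
      paste(x$values, collapse = ", "), "\n", sep = "")
  invisible(x)
}

is_likert_scale <- function(x) inherits(x, "likert_scale")
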