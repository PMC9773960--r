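#' Probability distribution over ordered Likert categories
#'
#' A light container for a probability vector over the categories of a
#' [likert_scale()]. Probabilities must be nonnegative and sum to one
#' (within 1e-9; they are renormalised to remove rounding fuzz).
#'
#' @param probs Numeric vector of length `scale$n_categories`.
#' @param scale A [likert_scale()].
#'
#' @return An object of class `categorical_distribution` with fields `probs`
#'   and `scale`.
#' @seealso [dist_mean()], [relative_frequencies()]
#' @export
#' @examples
#' d <- categorical_distribution(c(.5, 0, 0, 0, .5), likert_scale())
#' dist_mean(d)  # 3
categorical_distribution <- function(probs, scale = likert_scale(length(probs))) {
  stopifnot(is_likert_scale(scale))
  probs <- as.numeric(probs)
  if (length(probs) != scale$n_categories) {
    abort("`probs` must have one entry per scale category.")
  }
  if (anyNA(probs) || any(probs < -1e-12)) {
    abort("`probs` must be nonnegative and non-missing.")
  }
  probs <- pmax(probs, 0)
  s <- sum(probs)
  if (abs(s - 1) > 1e-9) {
    abort(sprintf("`probs` must sum to 1 (got %.12f).", s))
  }
  structure(
    list(probs = probs / s, scale = scale),
    class = "categorical_distribution"
  )
}

#' Mean of a categorical distribution
#'
#' The expectation of the numeric category scores under the distribution;
#' always lies within the scale's value range.
#'
#' @param dist A [categorical_distribution()].
#' @return A single number.
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "categorical_distribution"))
  sum(dist$probs * dist$scale$values)
}

#' @export
print.categorical_distribution <- function(x, ...) {
  cat("<categorical_distribution> on", x$scale$n_categories, "categories\n")
  print(round(stats::setNames(x$probs, x$scale$values), 4))
  cat("mean:", format(dist_mean(x)), "\n")
  invisible(x)
}

# Accept either a categorical_distribution or a bare probability vector.
as_prob_vector <- function(x, arg = "x") {
  if (inherits(x, "categorical_distribution")) return(x$probs)
  if (is.numeric(x)) {
    if (abs(sum(x) - 1) > 1e-9 || any(x < -1e-12)) {
      abort(sprintf("`%s` must be a probability vector summing to 1.", arg))
    }
    return(pmax(as.numeric(x), 0))
  }
  abort(sprintf("`%s` must be a categorical_distribution or numeric vector.", arg))
}
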