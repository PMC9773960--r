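#' Peak-end retrospective summary of an EMA series
#'
#' The peak-end rule summarises an episode by averaging its most intense
#' moment with its final moments. Here the "end" component is the mean of
#' the answered beeps on the final scheduled day (up to 3; whatever is
#' present is used), and the "peak" component is the highest answered score
#' over the whole series (`variant = "peak"`) or the lowest
#' (`variant = "trough"`, used for participants who under-reported their
#' positive affect). The summary is the mean of the two components.
#'
#' If the final scheduled day is entirely unanswered the summary cannot be
#' constructed and a missing result with a reason is returned.
#'
#' @param series An [ema_series()].
#' @param variant `"peak"` (highest score) or `"trough"` (lowest score).
#' @return List of class `peak_end_summary` with `value`, `variant`,
#'   `end_component`, `extreme_component`, `n_last_day`, and `reason`
#'   (`NA` unless the value is missing).
#' @export
#' @examples
#' obs <- data.frame(day = rep(1:2, each = 3), beep = rep(1:3, 2),
#'                   score = c(5, 1, 1, 2, 3, 4))
#' peak_end_summary(ema_series("p", "positive", obs))$value  # (3 + 5)/2 = 4
peak_end_summary <- function(series, variant = c("peak", "trough")) {
  variant <- match.arg(variant)
  all_scores <- observed_scores(series)
  if (length(all_scores) == 0L) {
    abort(sprintf("No observed scores for participant %s (%s).",
                  series$participant_id, series$valence))
  }
  last <- series$observations[series$observations$day == series$days, ]
  last_scores <- last$score[!is.na(last$score)]
  if (length(last_scores) == 0L) {
    return(structure(
      list(value = NA_real_, variant = variant, end_component = NA_real_,
           extreme_component = NA_real_, n_last_day = 0L,
           reason = "final_day_missing"),
      class = "peak_end_summary"))
  }
  end_component <- mean(last_scores)
  extreme_component <- if (variant == "peak") max(all_scores) else min(all_scores)
  structure(
    list(
      value = (end_component + extreme_component) / 2,
      variant = variant,
      end_component = end_component,
      extreme_component = extreme_component,
      n_last_day = length(last_scores),
      reason = NA_character_
    ),
    class = "peak_end_summary")
}

#' @export
print.peak_end_summary <- function(x, ...) {
  if (is.na(x$value)) {
    cat(sprintf("<peak_end_summary> missing (%s)\n", x$reason))
  } else {
    cat(sprintf("<peak_end_summary> %s: (%.3g + %g)/2 = %.3g (final-day n = %d)\n",
                x$variant, x$end_component, x$extreme_component, x$value,
                x$n_last_day))
  }
  invisible(x)
}

#' Difference between retrospective summary and peak-end summary
#'
#' `ra_summary - peak_end_value`, the same sign convention as
#' [raw_difference()]: positive values mean the retrospective report is
#' higher. Missing peak-end summaries propagate to a missing difference.
#'
#' @param ra Retrospective record (list or one-row data frame with
#'   `ra_summary`).
#' @param pe A [peak_end_summary()].
#' @return A single number, or `NA` if the peak-end summary is missing.
#' @export
peak_end_difference <- function(ra, pe) {
  stopifnot(inherits(pe, "peak_end_summary"))
  ra <- as.list(ra)
  if (is.na(pe$value)) return(NA_real_)
  as.numeric(ra$ra_summary) - pe$value
}
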