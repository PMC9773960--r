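#' Observed EMA distribution: relative response frequencies
#'
#' Divides the number of answered beeps per category by the total number of
#' answered beeps, giving the per-participant "observed EMA distribution"
#' over the Likert categories. Missing beeps are excluded.
#'
#' @param series An [ema_series()].
#' @return A [categorical_distribution()].
#' @export
#' @examples
#' s <- ema_series("p", "positive",
#'                 data.frame(day = 1, beep = 1:3, score = c(1, 1, 5)),
#'                 days = 1, beeps_per_day = 3)
#' relative_frequencies(s)
relative_frequencies <- function(series) {
  counts <- score_counts(series)
  n <- sum(counts)
  if (n == 0L) {
    abort(sprintf("No observed scores for participant %s (%s).",
                  series$participant_id, series$valence))
  }
  categorical_distribution(counts / n, series$scale)
}

#' Per-participant EMA descriptives
#'
#' Mean, mode(s), interquartile range, full range, and completion rate of
#' one participant's EMA scores, computed over answered beeps only.
#' All most-frequent categories are reported as modes when tied.
#'
#' @param series An [ema_series()].
#' @param quantile_type Quantile algorithm passed to [stats::quantile()] for
#'   the interquartile range; the default (7) is linear interpolation.
#' @return An object of class `ema_descriptives`: a list with fields
#'   `participant_id`, `valence`, `mean`, `modes`, `iqr`, `q_lower`,
#'   `q_upper`, `range_min`, `range_max`, `n_observed`, `n_scheduled`,
#'   `completion`.
#' @export
ema_descriptives <- function(series, quantile_type = 7) {
  s <- observed_scores(series)
  if (length(s) == 0L) {
    abort(sprintf("No observed scores for participant %s (%s).",
                  series$participant_id, series$valence))
  }
  counts <- score_counts(series)
  qs <- unname(quantile(s, c(.25, .75), type = quantile_type))
  modes <- series$scale$values[counts == max(counts) & counts > 0]
  structure(
    list(
      participant_id = series$participant_id,
      valence = series$valence,
      mean = mean(s),
      modes = modes,
      iqr = qs[2] - qs[1],
      q_lower = qs[1],
      q_upper = qs[2],
      range_min = min(s),
      range_max = max(s),
      n_observed = length(s),
      n_scheduled = series$n_scheduled,
      completion = length(s) / series$n_scheduled
    ),
    class = "ema_descriptives"
  )
}

#' @export
print.ema_descriptives <- function(x, ...) {
  cat(sprintf(
    "<ema_descriptives> %s/%s mean %.2f, modes {%s}, IQR %.2f, range %g-%g, completion %.2f\n",
    x$participant_id, x$valence, x$mean, paste(x$modes, collapse = ","),
    x$iqr, x$range_min, x$range_max, x$completion))
  invisible(x)
}

#' Raw difference between retrospective summary and EMA mean
#'
#' `raw_diff = ra_summary - ema_mean`: positive values mean the
#' retrospective report is higher than the average of the momentary reports.
#'
#' @param ra A retrospective record: list or one-row data frame with
#'   `participant_id`, `valence`, `ra_summary`.
#' @param desc The matching [ema_descriptives()].
#' @return A list of class `difference_record` with `participant_id`,
#'   `valence`, `ema_mean`, `ra_summary`, `raw_diff`.
#' @export
#' @examples
#' # RA 4.7 against an EMA mean of 1.80 gives a raw difference of 2.90
raw_difference <- function(ra, desc) {
  stopifnot(inherits(desc, "ema_descriptives"))
  ra <- as.list(ra)
  if (!identical(as.character(ra$participant_id), desc$participant_id) ||
      !identical(as.character(ra$valence), desc$valence)) {
    abort(sprintf(
      "Mismatched records: RA is %s/%s but descriptives are %s/%s.",
      ra$participant_id, ra$valence, desc$participant_id, desc$valence))
  }
  structure(
    list(
      participant_id = desc$participant_id,
      valence = desc$valence,
      ema_mean = desc$mean,
      ra_summary = as.numeric(ra$ra_summary),
      raw_diff = as.numeric(ra$ra_summary) - desc$mean
    ),
    class = "difference_record"
  )
}

#' Where does the retrospective score fall relative to the EMA spread?
#'
#' Classifies a retrospective summary as inside the interquartile range,
#' inside the full observed range (but outside the IQR), or strictly outside
#' the observed range. Boundaries are inclusive, so a score equal to the
#' observed minimum or maximum is `within_range`.
#'
#' @param ra_summary Retrospective summary score.
#' @param desc An [ema_descriptives()].
#' @return One of `"within_iqr"`, `"within_range"`, `"outside_range"`.
#' @export
classify_ra_position <- function(ra_summary, desc) {
  stopifnot(inherits(desc, "ema_descriptives"))
  ra_summary <- as.numeric(ra_summary)
  if (ra_summary >= desc$q_lower && ra_summary <= desc$q_upper) {
    "within_iqr"
  } else if (ra_summary >= desc$range_min && ra_summary <= desc$range_max) {
    "within_range"
  } else {
    "outside_range"
  }
}

#' Quadrant of a participant's pair of raw difference scores
#'
#' Places a participant in the four-quadrant layout spanned by their raw
#' difference for positive affect (x) and negative affect (y). Exact zeros
#' on either axis are classified as `"axis"` rather than assigned to a
#' quadrant.
#'
#' @param diff_pos Raw difference score for positive affect.
#' @param diff_neg Raw difference score for negative affect.
#' @return One of `"top_right"`, `"top_left"`, `"bottom_left"`,
#'   `"bottom_right"`, `"axis"`.
#' @export
quadrant_classify <- function(diff_pos, diff_neg) {
  if (is.na(diff_pos) || is.na(diff_neg)) {
    abort("Both valences are needed for quadrant classification.")
  }
  if (diff_pos == 0 || diff_neg == 0) return("axis")
  if (diff_pos > 0 && diff_neg > 0) "top_right"
  else if (diff_pos < 0 && diff_neg > 0) "top_left"
  else if (diff_pos < 0 && diff_neg < 0) "bottom_left"
  else "bottom_right"
}
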