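#' One participant-by-valence sequence of EMA scores
#'
#' Holds the full beep schedule (every scheduled `day` x `beep` slot) for one
#' participant and one affect valence, with `NA` marking beeps that were not
#' answered. The schedule defaults to the 3-beeps-a-day, 14-day design (42
#' scheduled prompts).
#'
#' @param participant_id Identifier (coerced to character).
#' @param valence `"positive"` or `"negative"`.
#' @param observations Data frame with columns `day`, `beep`, `score`. Rows
#'   for unanswered beeps may be present with `score = NA` or omitted
#'   entirely; omitted slots are filled in as explicit `NA` gaps.
#' @param scale A [likert_scale()].
#' @param days,beeps_per_day Schedule dimensions. Default to the maxima seen
#'   in `observations`.
#'
#' @return An object of class `ema_series` with fields `participant_id`,
#'   `valence`, `scale`, `observations` (a tibble ordered by day, beep, one
#'   row per scheduled beep), `days`, `beeps_per_day`, and `n_scheduled`.
#' @export
#' @examples
#' obs <- data.frame(day = rep(1:2, each = 3), beep = rep(1:3, 2),
#'                   score = c(1, 2, NA, 3, 3, 2))
#' s <- ema_series("p1", "negative", obs)
#' n_observed(s)
ema_series <- function(participant_id, valence, observations,
                       scale = likert_scale(),
                       days = NULL, beeps_per_day = NULL) {
  stopifnot(is_likert_scale(scale))
  valence <- as.character(valence)
  if (!valence %in% c("positive", "negative")) {
    abort(sprintf("Unknown valence '%s' (expected 'positive' or 'negative').",
                  valence))
  }
  obs <- tibble::as_tibble(observations)
  if (!all(c("day", "beep", "score") %in% names(obs))) {
    abort("`observations` needs columns day, beep, score.")
  }
  obs$day <- as.integer(obs$day)
  obs$beep <- as.integer(obs$beep)
  obs$score <- as.numeric(obs$score)
  if (any(obs$day < 1L, na.rm = TRUE) || any(obs$beep < 1L, na.rm = TRUE)) {
    abort("`day` and `beep` are 1-based positive integers.")
  }
  if (anyDuplicated(obs[c("day", "beep")])) {
    dup <- which(duplicated(obs[c("day", "beep")]))[1]
    abort(sprintf("Duplicate (day, beep) slot at row %d: day %d, beep %d.",
                  dup, obs$day[dup], obs$beep[dup]))
  }
  bad <- !is.na(obs$score) & !obs$score %in% scale$values
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("Score %g at row %d is not on the scale (%s).",
                  obs$score[i], i, paste(scale$values, collapse = ", ")))
  }
  days <- as.integer(days %||% max(obs$day, 1L))
  beeps_per_day <- as.integer(beeps_per_day %||% max(obs$beep, 1L))
  if (max(obs$day, 1L) > days || max(obs$beep, 1L) > beeps_per_day) {
    abort("Observations fall outside the declared schedule.")
  }
  grid <- tidyr::expand_grid(day = seq_len(days), beep = seq_len(beeps_per_day))
  obs <- dplyr::left_join(grid, obs, by = c("day", "beep"))
  obs <- dplyr::arrange(obs, .data$day, .data$beep)

  structure(
    list(
      participant_id = as.character(participant_id),
      valence = valence,
      scale = scale,
      observations = obs,
      days = days,
      beeps_per_day = beeps_per_day,
      n_scheduled = nrow(obs)
    ),
    class = "ema_series"
  )
}

#' @export
print.ema_series <- function(x, ...) {
  cat(sprintf("<ema_series> %s / %s: %d of %d beeps answered\n",
              x$participant_id, x$valence, n_observed(x), x$n_scheduled))
  invisible(x)
}

#' Number of answered beeps in a series
#' @param series An [ema_series()].
#' @return Integer count of non-missing scores.
#' @export
n_observed <- function(series) {
  stopifnot(inherits(series, "ema_series"))
  sum(!is.na(series$observations$score))
}

observed_scores <- function(series) {
  s <- series$observations$score
  s[!is.na(s)]
}

# Counts of observed scores per scale category.
score_counts <- function(series) {
  s <- observed_scores(series)
  vapply(series$scale$values, function(v) sum(s == v), integer(1))
}
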