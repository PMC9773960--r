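# Build an ema_series from a plain score vector (NA = unanswered beep).
make_series <- function(scores, participant_id = "p1", valence = "positive",
                        beeps_per_day = 3, scale = likert_scale()) {
  days <- ceiling(length(scores) / beeps_per_day)
  length(scores) <- days * beeps_per_day
  ema_series(
    participant_id, valence,
    data.frame(day = rep(seq_len(days), each = beeps_per_day),
               beep = rep(seq_len(beeps_per_day), days),
               score = scores),
    scale = scale, days = days, beeps_per_day = beeps_per_day)
}

# Expand per-category counts into a score vector.
scores_from_counts <- function(counts, values = seq_along(counts)) {
  rep(values, times = counts)
}

ra_record <- function(participant_id = "p1", valence = "positive",
                      ra_summary = 3) {
  list(participant_id = participant_id, valence = valence,
       ra_summary = ra_summary)
}

# Random observed distribution as counts over K categories (at least one
# observation), mimicking relative frequencies from a 42-beep series.
random_counts <- function(K, n = 42) {
  w <- rgamma(K, shape = runif(K, 0.3, 1.5))
  counts <- as.vector(rmultinom(1, n, w / sum(w)))
  if (sum(counts) == 0) counts[1] <- n
  counts
}
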