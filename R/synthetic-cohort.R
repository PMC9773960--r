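#' Configuration for a synthetic EMA study
#'
#' Defaults emulate the design this package analyses: 3 beeps a day for 14
#' days (42 scheduled prompts) on a 5-point scale, with about a fifth of
#' the cohort answering too few beeps to clear the 65% completion threshold.
#'
#' @param n_participants Cohort size (default 91).
#' @param days,beeps_per_day Beep schedule (defaults 14 and 3).
#' @param scale A [likert_scale()].
#' @param missing_rate Per-beep probability of a missing answer for
#'   ordinarily compliant participants.
#' @param low_completion_fraction Expected fraction of participants with
#'   elevated missingness (drawn per participant).
#' @param low_completion_missing_range Range of the elevated per-beep
#'   missingness probability, drawn uniformly per low-completion
#'   participant; the default keeps their completion around the 0.38-0.55
#'   band seen among low completers.
#' @param alpha Per-participant significance level carried into analyses.
#' @param seed Integer seed; fully determines all randomness in
#'   [generate_cohort()].
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_participants = 91L, days = 14L, beeps_per_day = 3L,
                         scale = likert_scale(), missing_rate = 0.10,
                         low_completion_fraction = 0.21,
                         low_completion_missing_range = c(0.45, 0.62),
                         alpha = 0.05, seed = 1L) {
  stopifnot(is_likert_scale(scale),
            days * beeps_per_day >= 3,
            missing_rate >= 0, missing_rate < 1,
            low_completion_fraction >= 0, low_completion_fraction <= 1,
            length(low_completion_missing_range) == 2)
  structure(
    list(n_participants = as.integer(n_participants), days = as.integer(days),
         beeps_per_day = as.integer(beeps_per_day), scale = scale,
         missing_rate = missing_rate,
         low_completion_fraction = low_completion_fraction,
         low_completion_missing_range = low_completion_missing_range,
         alpha = alpha, seed = as.integer(seed)),
    class = "study_config")
}

#' Participant reporting-strategy model
#'
#' A generative rule linking a simulated participant's EMA scores to the
#' retrospective summary they report:
#' * `mean` - the arithmetic mean of their answered beeps (noise-free by
#'   default);
#' * `noisy_mean` - the mean plus Gaussian report noise;
#' * `peak_end` - the peak-end summary ([peak_end_summary()]);
#' * `salience_weighted` - a weighted mean giving each score weight
#'   `1 + salience_weight * (score - min)/(max - min)`, up-weighting
#'   intense experiences.
#'
#' All summaries are quantised to the nearest 0.1 (the granularity of a
#' 10-item mean) and clipped to the scale range.
#'
#' @param kind One of `"mean"`, `"noisy_mean"`, `"peak_end"`,
#'   `"salience_weighted"`.
#' @param salience_weight Nonnegative weight for the salience strategy.
#' @param report_noise_sd Gaussian noise SD on the summary scale before
#'   quantisation; defaults to 0 for `mean` and 0.15 otherwise.
#' @return A list of class `strategy_model`.
#' @export
strategy_model <- function(kind = c("mean", "noisy_mean", "peak_end",
                                    "salience_weighted"),
                           salience_weight = 1, report_noise_sd = NULL) {
  kind <- match.arg(kind)
  report_noise_sd <- report_noise_sd %||% if (kind == "mean") 0 else 0.15
  stopifnot(salience_weight >= 0, report_noise_sd >= 0)
  structure(list(kind = kind, salience_weight = salience_weight,
                 report_noise_sd = report_noise_sd),
            class = "strategy_model")
}

# Dirichlet hyperparameters moment-matched to the cohort-level descriptives
# the generator emulates: positive affect centred mid-scale (mean of
# per-person means ~2.7, SD ~0.66), negative affect concentrated at the low
# categories (~1.51, SD ~0.35). SD of profile means = sd(shape)/sqrt(A + 1).
profile_hyperparams <- list(
  positive = list(shape = c(0.18, 0.30, 0.27, 0.16, 0.09), concentration = 2.3),
  negative = list(shape = c(0.68, 0.18, 0.095, 0.035, 0.01), concentration = 5.3)
)

#' Draw a latent affect profile
#'
#' Draws a participant's latent response-probability profile from a
#' Dirichlet family whose hyperparameters are moment-matched so that
#' cohorts of profiles reproduce the typical group descriptives: positive
#' affect spread around the scale midpoint, negative affect concentrated in
#' the lowest categories. Uses the current RNG stream; seed the session (or
#' call through [generate_cohort()]) for reproducibility.
#'
#' @param valence `"positive"` or `"negative"`.
#' @param scale A [likert_scale()]; profiles are defined for 5 categories.
#' @return A list of class `affect_profile` with `valence` and `base_probs`
#'   (a [categorical_distribution()]).
#' @export
sample_profile <- function(valence = c("positive", "negative"),
                           scale = likert_scale()) {
  valence <- match.arg(valence)
  hp <- profile_hyperparams[[valence]]
  if (scale$n_categories != length(hp$shape)) {
    abort("Built-in profiles are defined for the 5-point scale.")
  }
  g <- rgamma(length(hp$shape), shape = hp$shape * hp$concentration, rate = 1)
  if (sum(g) <= 0) g <- hp$shape  # numerically impossible in practice
  structure(
    list(valence = valence,
         base_probs = categorical_distribution(g / sum(g), scale)),
    class = "affect_profile")
}

#' Simulate one participant's EMA series from a profile
#'
#' Scores are independent draws from the profile's category probabilities
#' (the downstream comparisons are distribution-based, so no serial
#' dependence is modelled); each scheduled beep is answered independently
#' with probability `1 - missing rate`. Low-completion participants get an
#' elevated missingness probability drawn from the configured range.
#'
#' @param profile An [sample_profile()] result.
#' @param config A [study_config()].
#' @param participant_id Identifier for the generated series.
#' @param low_completion If `TRUE`, use the elevated missingness band.
#' @return An [ema_series()].
#' @export
simulate_series <- function(profile, config, participant_id = "sim",
                            low_completion = FALSE) {
  stopifnot(inherits(profile, "affect_profile"),
            inherits(config, "study_config"))
  n <- config$days * config$beeps_per_day
  miss <- if (low_completion) {
    runif(1, config$low_completion_missing_range[1],
          config$low_completion_missing_range[2])
  } else {
    config$missing_rate
  }
  scores <- sample(config$scale$values, n, replace = TRUE,
                   prob = profile$base_probs$probs)
  observed <- runif(n) >= miss
  scores[!observed] <- NA_real_
  ema_series(
    participant_id, profile$valence,
    tibble::tibble(day = rep(seq_len(config$days), each = config$beeps_per_day),
                   beep = rep(seq_len(config$beeps_per_day), config$days),
                   score = scores),
    scale = config$scale, days = config$days,
    beeps_per_day = config$beeps_per_day)
}

#' Generate a retrospective summary from a series under a strategy
#'
#' Applies the participant's reporting strategy to their answered beeps,
#' adds Gaussian report noise, then quantises to the nearest 0.1 and clips
#' to the scale range. For the peak-end strategy with a fully missing final
#' scheduled day, the last day with any answered beep stands in for the end
#' component (the participant still remembers how the period ended).
#'
#' @param series An [ema_series()].
#' @param strategy A [strategy_model()].
#' @return A list with `participant_id`, `valence`, `ra_summary`, and
#'   `true_summary` (the noise-free, unquantised strategy value).
#' @export
generate_ra <- function(series, strategy) {
  stopifnot(inherits(series, "ema_series"), inherits(strategy, "strategy_model"))
  s <- observed_scores(series)
  if (length(s) == 0L) {
    abort(sprintf("No observed scores for participant %s (%s).",
                  series$participant_id, series$valence))
  }
  truth <- switch(
    strategy$kind,
    mean = ,
    noisy_mean = mean(s),
    peak_end = {
      pe <- peak_end_summary(series, "peak")
      if (is.na(pe$value)) {
        # fall back to the last day that has any answered beep
        obs <- series$observations[!is.na(series$observations$score), ]
        last_day <- max(obs$day)
        end <- mean(obs$score[obs$day == last_day])
        (end + max(s)) / 2
      } else {
        pe$value
      }
    },
    salience_weighted = {
      w <- if (max(s) > min(s)) {
        1 + strategy$salience_weight * (s - min(s)) / (max(s) - min(s))
      } else {
        rep(1, length(s))
      }
      sum(w * s) / sum(w)
    })
  vals <- series$scale$values
  reported <- truth + rnorm(1, 0, strategy$report_noise_sd)
  reported <- pmin(pmax(round(reported, 1), min(vals)), max(vals))
  list(participant_id = series$participant_id, valence = series$valence,
       ra_summary = reported, true_summary = truth)
}

#' Generate a full synthetic cohort
#'
#' Builds EMA, retrospective, and ground-truth tables for a cohort in which
#' each participant applies one reporting strategy (the same for both
#' valences, drawn from `strategy_mix`). Output tables use the same layout
#' the readers consume ([read_ema_table()], [read_ra_table()]); the truth
#' table records each participant's true strategy and noise-free summary
#' for strategy-recovery experiments. `config$seed` fully determines the
#' output.
#'
#' @param config A [study_config()].
#' @param strategy_mix Named numeric vector of strategy proportions over
#'   `"mean"`, `"noisy_mean"`, `"peak_end"`, `"salience_weighted"`; must
#'   sum to 1. The default mixes a mostly-mean cohort with salience-driven
#'   reporters.
#' @param strategies Optional named list of [strategy_model()] objects
#'   overriding the defaults per kind.
#' @return A list of class `synthetic_cohort` with tibbles `ema`
#'   (`participant_id`, `valence`, `day`, `beep`, `score`, including
#'   explicit `NA` rows for unanswered beeps), `ra`, `truth`
#'   (`participant_id`, `valence`, `strategy`, `true_summary_value`,
#'   `low_completion`), and the `config`.
#' @export
generate_cohort <- function(config = study_config(),
                            strategy_mix = c(mean = 0.4, noisy_mean = 0.25,
                                             peak_end = 0.2,
                                             salience_weighted = 0.15),
                            strategies = NULL) {
  stopifnot(inherits(config, "study_config"))
  kinds <- c("mean", "noisy_mean", "peak_end", "salience_weighted")
  if (is.null(names(strategy_mix)) || !all(names(strategy_mix) %in% kinds) ||
      any(strategy_mix < 0) || abs(sum(strategy_mix) - 1) > 1e-9) {
    abort("`strategy_mix` must be named proportions over the strategy kinds summing to 1.")
  }
  models <- stats::setNames(lapply(kinds, strategy_model), kinds)
  for (k in names(strategies)) models[[k]] <- strategies[[k]]

  withr::local_seed(config$seed)
  n <- config$n_participants
  ids <- sprintf("p%03d", seq_len(n))
  assigned <- sample(names(strategy_mix), n, replace = TRUE,
                     prob = strategy_mix)
  low <- runif(n) < config$low_completion_fraction

  ema <- vector("list", 2L * n)
  ra <- vector("list", 2L * n)
  truth <- vector("list", 2L * n)
  i <- 0L
  for (p in seq_len(n)) {
    for (valence in c("positive", "negative")) {
      i <- i + 1L
      profile <- sample_profile(valence, config$scale)
      series <- simulate_series(profile, config, ids[p],
                                low_completion = low[p])
      rec <- generate_ra(series, models[[assigned[p]]])
      ema[[i]] <- dplyr::mutate(series$observations,
                                participant_id = ids[p], valence = valence,
                                .before = 1)
      ra[[i]] <- tibble::tibble(participant_id = ids[p], valence = valence,
                                ra_summary = rec$ra_summary)
      truth[[i]] <- tibble::tibble(participant_id = ids[p], valence = valence,
                                   strategy = assigned[p],
                                   true_summary_value = rec$true_summary,
                                   low_completion = low[p])
    }
  }
  structure(
    list(ema = dplyr::bind_rows(ema), ra = dplyr::bind_rows(ra),
         truth = dplyr::bind_rows(truth), config = config),
    class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes `ema.csv`, `ra.csv` and `truth.csv` in the formats the readers
#' consume. Identical configurations and seeds give byte-identical files.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ema = file.path(dir, "ema.csv"),
             ra = file.path(dir, "ra.csv"),
             truth = file.path(dir, "truth.csv"))
  readr::write_csv(cohort$ema, paths[["ema"]])
  readr::write_csv(cohort$ra, paths[["ra"]])
  readr::write_csv(cohort$truth, paths[["truth"]])
  invisible(paths)
}
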