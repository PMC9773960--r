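#' Analysis run configuration
#'
#' Thresholds and numerical conventions for a cohort analysis.
#'
#' @param alpha Per-participant significance level (uncorrected).
#' @param jsd_extreme_threshold Absolute JSD above which a case is flagged
#'   `high_jsd`; `NULL` (default) uses the cohort `jsd_extreme_quantile`.
#' @param jsd_extreme_quantile Cohort quantile defining the `high_jsd` flag
#'   when no absolute threshold is given.
#' @param raw_diff_extreme_threshold Absolute raw difference above which a
#'   case is flagged `high_raw_diff` (default 2 scale points).
#' @param completion_threshold Completion fraction below which a case is
#'   flagged `low_completion` (default 27/42; strictly-below rule, so
#'   exactly 27 answered beeps of 42 is not flagged).
#' @param df_rule Degrees-of-freedom rule for [chi_squared_gof()].
#' @param monte_carlo,n_sim Monte-Carlo p-value option for the test.
#' @param jsd_log_base Logarithm base for [jensen_shannon()].
#' @param quantile_type Quantile algorithm for the interquartile range.
#' @param seed Seed recorded in provenance (and used by any stochastic
#'   options such as Monte-Carlo p-values).
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, jsd_extreme_threshold = NULL,
                       jsd_extreme_quantile = 0.95,
                       raw_diff_extreme_threshold = 2.0,
                       completion_threshold = 27 / 42,
                       df_rule = "support_minus_1",
                       monte_carlo = FALSE, n_sim = 2000,
                       jsd_log_base = 2, quantile_type = 7, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, raw_diff_extreme_threshold > 0,
            completion_threshold > 0, completion_threshold <= 1)
  structure(
    list(alpha = alpha, jsd_extreme_threshold = jsd_extreme_threshold,
         jsd_extreme_quantile = jsd_extreme_quantile,
         raw_diff_extreme_threshold = raw_diff_extreme_threshold,
         completion_threshold = completion_threshold, df_rule = df_rule,
         monte_carlo = monte_carlo, n_sim = n_sim,
         jsd_log_base = jsd_log_base, quantile_type = quantile_type,
         seed = as.integer(seed)),
    class = "run_config")
}

#' Run the full cohort analysis
#'
#' For every participant-by-valence pair present in both tables: EMA
#' descriptives, observed distribution, raw difference, position of the
#' retrospective score relative to the EMA spread, the mean-constrained
#' optimized distribution, chi-squared test and Jensen-Shannon divergence,
#' the peak-end summary and its difference (trough variant when the raw
#' difference is negative, peak variant otherwise), and extreme-case flags.
#' Series with no answered beeps are kept as unevaluable rows and logged.
#'
#' @param ema Path to an EMA table, a data frame in that layout, or a list
#'   of [ema_series()] from [read_ema_table()].
#' @param ra Path to a retrospective table, a data frame, or a tibble from
#'   [read_ra_table()].
#' @param config A [run_config()].
#' @param scale A [likert_scale()].
#' @param days,beeps_per_day Optional schedule override passed to
#'   [read_ema_table()].
#' @return A list of class `ema_cohort_report`: tibbles `participants`,
#'   `cohort_summary`, `quadrants`, `extremes`, `warnings`, a `counts`
#'   bookkeeping tibble per valence (rejections, non-rejections,
#'   unevaluable, within-IQR/range), and the `config`.
#' @export
run_analysis <- function(ema, ra, config = run_config(),
                         scale = likert_scale(),
                         days = NULL, beeps_per_day = NULL) {
  stopifnot(inherits(config, "run_config"))
  series_list <- if (inherits(ema, "ema_series_list")) ema
    else read_ema_table(ema, scale, days = days, beeps_per_day = beeps_per_day)
  ra_tbl <- if (is.data.frame(ra) && setequal(
    names(ra), c("participant_id", "valence", "ra_summary"))) {
    tibble::as_tibble(ra)
  } else {
    read_ra_table(ra, scale)
  }
  warnings <- list()
  note <- function(id, valence, code, message) {
    warnings[[length(warnings) + 1L]] <<- tibble::tibble(
      participant_id = id, valence = valence, code = code, message = message)
  }

  rows <- list()
  for (series in series_list) {
    id <- series$participant_id
    valence <- series$valence
    ra_row <- ra_tbl[ra_tbl$participant_id == id & ra_tbl$valence == valence, ]
    if (nrow(ra_row) == 0L) {
      note(id, valence, "no_ra_record", "No retrospective record; skipped.")
      next
    }
    base <- tibble::tibble(participant_id = id, valence = valence,
                           ra_summary = ra_row$ra_summary[1])
    if (n_observed(series) == 0L) {
      note(id, valence, "no_data", "All beeps missing; unevaluable.")
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        base, completion = 0, n_observed = 0L, evaluable = FALSE)
      next
    }
    desc <- ema_descriptives(series, quantile_type = config$quantile_type)
    dif <- raw_difference(ra_row[1, ], desc)
    cmp <- compare_participant(series, ra_row[1, ], alpha = config$alpha,
                               df_rule = config$df_rule,
                               monte_carlo = config$monte_carlo,
                               n_sim = config$n_sim,
                               jsd_base = config$jsd_log_base)
    if (cmp$degenerate) {
      note(id, valence, "degenerate_fit",
           "Summary score at a scale endpoint with other categories observed; automatic rejection.")
    }
    variant <- if (dif$raw_diff < 0) "trough" else "peak"
    pe <- peak_end_summary(series, variant)
    if (is.na(pe$value)) {
      note(id, valence, "peak_end_missing",
           "Final scheduled day entirely missing; no peak-end summary.")
    }
    rows[[length(rows) + 1L]] <- dplyr::mutate(
      base,
      completion = desc$completion, n_observed = desc$n_observed,
      evaluable = TRUE,
      ema_mean = desc$mean,
      ema_modes = paste(desc$modes, collapse = ";"),
      ema_mode_scalar = mean(desc$modes),
      ema_iqr = desc$iqr,
      range_min = desc$range_min, range_max = desc$range_max,
      raw_diff = dif$raw_diff,
      position = classify_ra_position(base$ra_summary, desc),
      chi2_stat = cmp$chi2_stat, df = cmp$df, chi2_p = cmp$p_value,
      jsd = cmp$jsd,
      reject_mean_hypothesis = cmp$reject_mean_hypothesis,
      degenerate_fit = cmp$degenerate,
      peak_end_variant = variant,
      peak_end_value = pe$value,
      peak_end_diff = peak_end_difference(ra_row[1, ], pe))
  }
  unmatched_ra <- dplyr::anti_join(
    ra_tbl,
    tibble::tibble(
      participant_id = vapply(series_list, `[[`, "", "participant_id"),
      valence = vapply(series_list, `[[`, "", "valence")),
    by = c("participant_id", "valence"))
  for (i in seq_len(nrow(unmatched_ra))) {
    note(unmatched_ra$participant_id[i], unmatched_ra$valence[i],
         "no_ema_series", "No EMA series for this retrospective record.")
  }
  if (length(rows) == 0L) abort("No analysable participant/valence pairs.")
  pt <- dplyr::bind_rows(rows)

  jsd_cut <- config$jsd_extreme_threshold %||%
    unname(quantile(pt$jsd, config$jsd_extreme_quantile, na.rm = TRUE,
                    type = config$quantile_type))
  pt <- dplyr::mutate(
    pt,
    flag_outside_range = .data$evaluable & .data$position == "outside_range",
    flag_high_jsd = .data$evaluable & .data$jsd >= jsd_cut & .data$jsd > 0,
    flag_high_raw_diff = .data$evaluable &
      abs(.data$raw_diff) > config$raw_diff_extreme_threshold,
    flag_low_completion = .data$completion < config$completion_threshold,
    extreme = .data$flag_outside_range | .data$flag_high_jsd |
      .data$flag_high_raw_diff)
  pt <- dplyr::arrange(pt, .data$participant_id, .data$valence)

  report <- structure(
    list(
      participants = pt,
      cohort_summary = cohort_summary_table(pt),
      quadrants = quadrant_table(pt),
      extremes = extreme_table(pt),
      counts = count_table(pt),
      warnings = if (length(warnings)) dplyr::bind_rows(warnings)
        else tibble::tibble(participant_id = character(), valence = character(),
                            code = character(), message = character()),
      config = config,
      jsd_extreme_cut = jsd_cut),
    class = "ema_cohort_report")
  report
}

#' @export
print.ema_cohort_report <- function(x, ...) {
  n <- dplyr::n_distinct(x$participants$participant_id)
  cat(sprintf("<ema_cohort_report> %d participants, %d participant-valence rows\n",
              n, nrow(x$participants)))
  print(x$counts)
  invisible(x)
}

# Table-1-style cohort summary: Mean / Mode / IQR / Range descriptives,
# mean (sd) per valence. Tied modes enter as the mean of the tied values.
cohort_summary_table <- function(pt) {
  pt <- pt[pt$evaluable, ]
  stat_rows <- list(
    Mean = "ema_mean", Mode = "ema_mode_scalar",
    `Interquartile range` = "ema_iqr")
  out <- lapply(names(stat_rows), function(lbl) {
    col <- stat_rows[[lbl]]
    dplyr::summarise(
      dplyr::group_by(pt, .data$valence),
      statistic = lbl, mean = mean(.data[[col]]), sd = stats::sd(.data[[col]]),
      .groups = "drop")
  })
  rng <- dplyr::summarise(
    dplyr::group_by(pt, .data$valence), statistic = "Range",
    mean = mean(.data$range_max - .data$range_min),
    sd = stats::sd(.data$range_max - .data$range_min), .groups = "drop")
  long <- dplyr::bind_rows(c(out, list(rng)))
  wide <- tidyr::pivot_wider(long, names_from = "valence",
                             values_from = c("mean", "sd"))
  wide[match(c("Mean", "Mode", "Interquartile range", "Range"),
             wide$statistic), ]
}

quadrant_table <- function(pt) {
  wide <- tidyr::pivot_wider(
    pt[pt$evaluable, c("participant_id", "valence", "raw_diff")],
    names_from = "valence", values_from = "raw_diff")
  for (col in c("positive", "negative")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  both <- wide[!is.na(wide$positive) & !is.na(wide$negative), ]
  q <- vapply(seq_len(nrow(both)), function(i) {
    quadrant_classify(both$positive[i], both$negative[i])
  }, character(1))
  lvls <- c("top_right", "top_left", "bottom_left", "bottom_right", "axis")
  tibble::tibble(quadrant = lvls,
                 n = as.integer(table(factor(q, levels = lvls))))
}

extreme_table <- function(pt) {
  ex <- pt[pt$evaluable & pt$extreme, ]
  reason <- function(i) {
    paste(c(if (ex$flag_outside_range[i]) "outside_range",
            if (ex$flag_high_jsd[i]) "high_jsd",
            if (ex$flag_high_raw_diff[i]) "high_raw_diff"), collapse = ";")
  }
  tibble::tibble(
    participant_id = ex$participant_id, valence = ex$valence,
    reason = vapply(seq_len(nrow(ex)), reason, character(1)),
    completion = ex$completion, ema_mean = ex$ema_mean,
    range_min = ex$range_min, range_max = ex$range_max,
    ra_summary = ex$ra_summary, raw_diff = ex$raw_diff,
    peak_end_variant = ex$peak_end_variant, peak_end_diff = ex$peak_end_diff,
    low_completion = ex$flag_low_completion)
}

count_table <- function(pt) {
  dplyr::summarise(
    dplyr::group_by(pt, .data$valence),
    n = dplyr::n(),
    rejected = sum(.data$reject_mean_hypothesis & .data$evaluable, na.rm = TRUE),
    not_rejected = sum(!.data$reject_mean_hypothesis & .data$evaluable,
                       na.rm = TRUE),
    unevaluable = sum(!.data$evaluable),
    within_iqr = sum(.data$evaluable & .data$position == "within_iqr"),
    within_range = sum(.data$evaluable & .data$position != "outside_range"),
    outside_range = sum(.data$evaluable & .data$position == "outside_range"),
    .groups = "drop")
}

#' Strategy-recovery experiment
#'
#' Generates synthetic cohorts with known reporting strategies, runs the
#' full analysis on each, and reports - per true strategy - how often the
#' mean hypothesis is rejected and the average divergence. The rejection
#' rate among true mean-strategy reporters estimates the decision rule's
#' type-I error; rates for the other strategies estimate its power against
#' those recall styles.
#'
#' @param config A [study_config()]; replicate `r` uses seed
#'   `config$seed + r - 1`.
#' @param strategy_mix Passed to [generate_cohort()].
#' @param replicates Number of independent cohorts; 0 gives an empty
#'   report.
#' @param run_cfg A [run_config()].
#' @param strategies Optional strategy overrides (see [generate_cohort()]).
#' @return A list of class `recovery_report` with `by_strategy` (tibble:
#'   `strategy`, `n_tests`, `n_rejected`, `rejection_rate`, `mean_jsd`)
#'   and `detail` (per replicate, strategy and valence).
#' @export
run_recovery_experiment <- function(config = study_config(),
                                    strategy_mix = c(mean = 1),
                                    replicates = 10,
                                    run_cfg = run_config(alpha = config$alpha),
                                    strategies = NULL) {
  detail <- list()
  for (r in seq_len(replicates)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r - 1L
    cohort <- generate_cohort(cfg_r, strategy_mix, strategies = strategies)
    report <- run_analysis(cohort$ema, cohort$ra, config = run_cfg,
                           scale = config$scale)
    joined <- dplyr::inner_join(
      report$participants[report$participants$evaluable, ],
      cohort$truth, by = c("participant_id", "valence"))
    detail[[r]] <- dplyr::summarise(
      dplyr::group_by(joined, .data$strategy, .data$valence),
      replicate = r, n_tests = dplyr::n(),
      n_rejected = sum(.data$reject_mean_hypothesis),
      mean_jsd = mean(.data$jsd), .groups = "drop")
  }
  detail_tbl <- if (length(detail)) dplyr::bind_rows(detail) else
    tibble::tibble(strategy = character(), valence = character(),
                   replicate = integer(), n_tests = integer(),
                   n_rejected = integer(), mean_jsd = numeric())
  by_strategy <- dplyr::summarise(
    dplyr::group_by(detail_tbl, .data$strategy),
    mean_jsd = stats::weighted.mean(.data$mean_jsd, .data$n_tests),
    n_tests = sum(.data$n_tests), n_rejected = sum(.data$n_rejected),
    rejection_rate = .data$n_rejected / .data$n_tests,
    .groups = "drop")
  by_strategy <- by_strategy[c("strategy", "n_tests", "n_rejected",
                               "rejection_rate", "mean_jsd")]
  structure(list(by_strategy = by_strategy, detail = detail_tbl),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$by_strategy)
  invisible(x)
}
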