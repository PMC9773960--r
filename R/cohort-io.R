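#' Read a long-format EMA table
#'
#' Reads a comma-separated table with header columns `participant_id`,
#' `valence`, `day`, `beep`, `score` into one [ema_series()] per
#' participant-by-valence. Empty cells, `NA` and `.` are treated as missing
#' scores; beeps absent from the file are kept as explicit gaps so every
#' series covers the full schedule. The schedule defaults to the maxima of
#' `day` and `beep` seen in the file.
#'
#' Rows with an unknown valence label, a score off the scale, or a
#' duplicated (participant, valence, day, beep) slot are rejected with the
#' offending row number.
#'
#' @param path File path, or a data frame already in the same layout.
#' @param scale A [likert_scale()].
#' @param days,beeps_per_day Optional schedule dimensions overriding the
#'   inferred maxima.
#' @return A named list of [ema_series()] (names `"<id>.<valence>"`).
#' @export
read_ema_table <- function(path, scale = likert_scale(),
                           days = NULL, beeps_per_day = NULL) {
  df <- read_input_table(path, c("participant_id", "valence", "day", "beep", "score"))
  if (nrow(df) == 0L) return(structure(list(), class = "ema_series_list"))

  df$participant_id <- as.character(df$participant_id)
  df$valence <- as.character(df$valence)
  bad_val <- !df$valence %in% c("positive", "negative")
  if (any(bad_val)) {
    abort(sprintf("Unknown valence '%s' at row %d.",
                  df$valence[which(bad_val)[1]], which(bad_val)[1]))
  }
  df$score <- parse_score(df$score, path)
  bad_score <- !is.na(df$score) & !df$score %in% scale$values
  if (any(bad_score)) {
    i <- which(bad_score)[1]
    abort(sprintf("Score %g at row %d is not on the scale (%s).",
                  df$score[i], i, paste(scale$values, collapse = ", ")))
  }
  key <- df[c("participant_id", "valence", "day", "beep")]
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    abort(sprintf(
      "Duplicate record at row %d: participant %s, %s affect, day %s, beep %s.",
      i, df$participant_id[i], df$valence[i], df$day[i], df$beep[i]))
  }

  days <- days %||% max(as.integer(df$day))
  beeps_per_day <- beeps_per_day %||% max(as.integer(df$beep))
  groups <- split(df, list(df$participant_id, df$valence), drop = TRUE)
  out <- lapply(groups, function(g) {
    ema_series(g$participant_id[1], g$valence[1],
               g[c("day", "beep", "score")], scale = scale,
               days = days, beeps_per_day = beeps_per_day)
  })
  structure(out, class = "ema_series_list")
}

#' Read a retrospective-summary table
#'
#' Reads `participant_id`, `valence` plus either a `ra_summary` column or
#' ten item columns `item_1`..`item_10`. When item columns are present the
#' summary is their arithmetic mean (the usual 10-item-per-valence PANAS
#' scoring, giving a 0.1 granularity on a 5-point scale); items must be
#' integers on the scale. Summaries must lie within the scale value range.
#'
#' @param path File path or data frame.
#' @param scale A [likert_scale()].
#' @return A tibble with columns `participant_id`, `valence`, `ra_summary`.
#' @export
read_ra_table <- function(path, scale = likert_scale()) {
  item_cols <- paste0("item_", 1:10)
  df <- read_input_table(path, c("participant_id", "valence"))
  df$participant_id <- as.character(df$participant_id)
  df$valence <- as.character(df$valence)
  bad_val <- !df$valence %in% c("positive", "negative")
  if (any(bad_val)) {
    abort(sprintf("Unknown valence '%s' at row %d.",
                  df$valence[which(bad_val)[1]], which(bad_val)[1]))
  }
  if (all(item_cols %in% names(df))) {
    items <- as.matrix(df[item_cols])
    storage.mode(items) <- "double"
    bad <- is.na(items) | items != round(items) | items < min(scale$values) |
      items > max(scale$values)
    if (any(bad)) {
      i <- which(rowSums(bad) > 0)[1]
      abort(sprintf("Invalid item score at row %d: items must be integers in %g..%g.",
                    i, min(scale$values), max(scale$values)))
    }
    df$ra_summary <- rowMeans(items)
  } else if (!"ra_summary" %in% names(df)) {
    abort("Need either an `ra_summary` column or item_1..item_10 columns.")
  } else {
    df$ra_summary <- as.numeric(df$ra_summary)
  }
  bad_ra <- is.na(df$ra_summary) | df$ra_summary < min(scale$values) |
    df$ra_summary > max(scale$values)
  if (any(bad_ra)) {
    i <- which(bad_ra)[1]
    abort(sprintf("`ra_summary` %s at row %d is outside [%g, %g].",
                  format(df$ra_summary[i]), i, min(scale$values), max(scale$values)))
  }
  tibble::as_tibble(df[c("participant_id", "valence", "ra_summary")])
}

#' Write the cohort report tables
#'
#' Emits the standard report files for a cohort analysis into `out_dir`:
#' `participants.csv` (one row per participant-by-valence),
#' `cohort_summary.csv` (Mean / Mode / Interquartile range / Range
#' descriptives per valence), `quadrants.csv` (counts of the four
#' raw-difference sign combinations), `extremes.csv` (flagged cases),
#' `warnings.csv`, and a `run_provenance.json` block recording the
#' configuration, seed and package version. Descriptives and differences
#' are rounded to 2 decimals and retrospective summaries to 1 decimal.
#'
#' @param report A cohort report from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_report_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "ema_cohort_report"))
  if (nrow(report$participants) == 0L) abort("Empty report: nothing to write.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("Cannot create '%s'.", out_dir))

  round2 <- function(x) round(x, 2)
  pt <- report$participants
  pt <- dplyr::mutate(
    pt,
    dplyr::across(dplyr::any_of(c(
      "completion", "ema_mean", "ema_iqr", "raw_diff", "peak_end_value",
      "peak_end_diff", "jsd", "chi2_stat")), round2),
    ra_summary = round(.data$ra_summary, 1))
  paths <- c(
    participants = file.path(out_dir, "participants.csv"),
    cohort_summary = file.path(out_dir, "cohort_summary.csv"),
    quadrants = file.path(out_dir, "quadrants.csv"),
    extremes = file.path(out_dir, "extremes.csv"),
    warnings = file.path(out_dir, "warnings.csv"),
    provenance = file.path(out_dir, "run_provenance.json"))
  readr::write_csv(pt, paths[["participants"]])
  readr::write_csv(
    dplyr::mutate(report$cohort_summary,
                  dplyr::across(dplyr::where(is.numeric), round2)),
    paths[["cohort_summary"]])
  readr::write_csv(report$quadrants, paths[["quadrants"]])
  readr::write_csv(
    dplyr::mutate(report$extremes,
                  dplyr::across(dplyr::where(is.numeric), round2)),
    paths[["extremes"]])
  readr::write_csv(report$warnings, paths[["warnings"]])
  jsonlite::write_json(
    list(package = "emarecall",
         version = as.character(utils::packageVersion("emarecall")),
         config = report$config[setdiff(names(report$config), "scale")],
         timestamp = format(Sys.time(), tz = "UTC")),
    paths[["provenance"]], auto_unbox = TRUE, null = "null")
  invisible(paths)
}

# ---- internal helpers -------------------------------------------------------

read_input_table <- function(path, required) {
  if (is.data.frame(path)) {
    df <- tibble::as_tibble(path)
  } else {
    if (!file.exists(path)) abort(sprintf("File not found: %s", path))
    df <- readr::read_csv(path, na = c("", "NA", "."),
                          show_col_types = FALSE, progress = FALSE)
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  df
}

parse_score <- function(x, path) {
  if (is.character(x)) {
    x[x %in% c("", "NA", ".")] <- NA
    x <- suppressWarnings(as.numeric(x))
  }
  as.numeric(x)
}
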