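write_tmp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, na = "")
  path
}

test_that("EMA tables round-trip with gaps kept explicit", {
  co <- generate_cohort(study_config(n_participants = 6, seed = 21))
  path <- write_tmp_csv(co$ema)
  series <- read_ema_table(path)
  expect_length(series, 12)
  expect_true(all(vapply(series, function(s) s$n_scheduled, integer(1)) == 42L))
  # multiset of non-missing scores preserved per participant x valence
  for (s in series) {
    orig <- co$ema$score[co$ema$participant_id == s$participant_id &
                           co$ema$valence == s$valence]
    expect_equal(sort(observed_scores(s)), sort(orig[!is.na(orig)]))
  }
})

test_that("omitted beeps become explicit NA gaps", {
  df <- data.frame(participant_id = "a", valence = "positive",
                   day = c(1, 1, 2), beep = c(1, 3, 2), score = c(2, 3, 4))
  series <- read_ema_table(write_tmp_csv(df), days = 2, beeps_per_day = 3)
  s <- series[[1]]
  expect_equal(s$n_scheduled, 6L)
  expect_equal(n_observed(s), 3L)
  expect_equal(s$observations$score, c(2, NA, 3, NA, 4, NA))
})

test_that("a header-only file yields an empty collection", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant_id,valence,day,beep,score", path)
  expect_length(read_ema_table(path), 0)
})

test_that("invalid EMA rows are rejected with their row number", {
  base <- data.frame(participant_id = "a", valence = "positive",
                     day = c(1, 1), beep = c(1, 2), score = c(2, 3))
  dup <- rbind(base, base[2, ])
  expect_error(read_ema_table(write_tmp_csv(dup)), "row 3")
  bad_val <- base
  bad_val$valence[2] <- "neutral"
  expect_error(read_ema_table(write_tmp_csv(bad_val)), "valence 'neutral' at row 2")
  bad_score <- base
  bad_score$score[1] <- 6
  expect_error(read_ema_table(write_tmp_csv(bad_score)), "Score 6 at row 1")
})

test_that("retrospective summaries come from item means or pass through", {
  items <- as.data.frame(as.list(stats::setNames(
    c(5, 5, 5, 5, 5, 4, 4, 4, 5, 5), paste0("item_", 1:10))))
  df <- cbind(data.frame(participant_id = "a", valence = "positive"), items)
  ra <- read_ra_table(write_tmp_csv(df))
  expect_equal(ra$ra_summary, 4.7)

  df[paste0("item_", 1:10)] <- 3
  expect_equal(read_ra_table(write_tmp_csv(df))$ra_summary, 3)

  plain <- data.frame(participant_id = "a", valence = "positive",
                      ra_summary = 3.7)
  expect_equal(read_ra_table(write_tmp_csv(plain))$ra_summary, 3.7)
})

test_that("invalid retrospective records are rejected", {
  bad <- data.frame(participant_id = "a", valence = "positive",
                    ra_summary = 5.4)
  expect_error(read_ra_table(write_tmp_csv(bad)), "outside")
  items <- as.data.frame(as.list(stats::setNames(rep(3, 10), paste0("item_", 1:10))))
  df <- cbind(data.frame(participant_id = "a", valence = "positive"), items)
  df$item_4 <- 3.5
  expect_error(read_ra_table(write_tmp_csv(df)), "integers")
  df$item_4 <- 7
  expect_error(read_ra_table(write_tmp_csv(df)), "integers")
  expect_error(read_ra_table(data.frame(participant_id = "a",
                                        valence = "positive")),
               "ra_summary")
})

test_that("report tables round-trip at printed precision", {
  co <- generate_cohort(study_config(n_participants = 10, seed = 5))
  report <- run_analysis(co$ema, co$ra)
  out <- withr::local_tempdir()
  paths <- write_report_tables(report, out)
  expect_true(all(file.exists(paths)))

  pt <- readr::read_csv(paths[["participants"]], show_col_types = FALSE)
  expect_equal(nrow(pt), nrow(report$participants))
  expect_equal(pt$ema_mean, round(report$participants$ema_mean, 2))
  expect_equal(pt$raw_diff, round(report$participants$raw_diff, 2))
  expect_equal(pt$ra_summary, round(report$participants$ra_summary, 1))

  qt <- readr::read_csv(paths[["quadrants"]], show_col_types = FALSE)
  both <- sum(table(report$participants$participant_id[
    report$participants$evaluable]) == 2)
  expect_equal(sum(qt$n), both)

  cs <- readr::read_csv(paths[["cohort_summary"]], show_col_types = FALSE)
  expect_equal(cs$statistic, c("Mean", "Mode", "Interquartile range", "Range"))
})
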