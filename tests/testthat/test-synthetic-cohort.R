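test_that("cohort generation is fully determined by the seed", {
  cfg <- study_config(n_participants = 8, seed = 33)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$ema, b$ema)
  expect_identical(a$ra, b$ra)
  expect_identical(a$truth, b$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in c("ema.csv", "ra.csv", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("profiles are valence-typed distributions", {
  set.seed(2)
  pr <- sample_profile("negative")
  expect_s3_class(pr$base_probs, "categorical_distribution")
  expect_equal(sum(pr$base_probs$probs), 1, tolerance = 1e-12)
  # identical seeds give identical profiles
  set.seed(5); a <- sample_profile("positive")
  set.seed(5); b <- sample_profile("positive")
  expect_identical(a, b)
})

test_that("profile cohorts land near the emulated group descriptives", {
  set.seed(14)
  pos <- replicate(300, dist_mean(sample_profile("positive")$base_probs))
  neg <- replicate(300, dist_mean(sample_profile("negative")$base_probs))
  expect_gt(mean(pos), 2.5); expect_lt(mean(pos), 2.9)
  expect_gt(mean(neg), 1.3); expect_lt(mean(neg), 1.7)
})

test_that("simulated series follow the schedule and the profile", {
  cfg <- study_config(seed = 1, missing_rate = 0)
  set.seed(4)
  pr <- sample_profile("positive")
  s <- simulate_series(pr, cfg)
  expect_equal(n_observed(s), 42L)
  expect_equal(s$n_scheduled, 42L)

  # law of large numbers: long series converge to the profile
  cfg_long <- study_config(days = 4000, beeps_per_day = 3, missing_rate = 0,
                           seed = 1)
  set.seed(9)
  s_long <- simulate_series(pr, cfg_long)
  freq <- relative_frequencies(s_long)
  expect_lt(max(abs(freq$probs - pr$base_probs$probs)), 0.05)
})

test_that("about a fifth of a configured cohort falls below the completion threshold", {
  co <- generate_cohort(study_config(n_participants = 300, seed = 6))
  completion <- tapply(!is.na(co$ema$score),
                       paste(co$ema$participant_id, co$ema$valence), mean)
  frac <- mean(completion < 27 / 42)
  expect_gt(frac, 0.13)
  expect_lt(frac, 0.29)
})

test_that("generated summaries respect range and 0.1 granularity", {
  co <- generate_cohort(study_config(n_participants = 30, seed = 10))
  expect_true(all(co$ra$ra_summary >= 1 & co$ra$ra_summary <= 5))
  expect_true(all(abs(co$ra$ra_summary * 10 -
                        round(co$ra$ra_summary * 10)) < 1e-9))
})

test_that("strategies reproduce their defining summaries", {
  set.seed(3)
  pr <- sample_profile("positive")
  s <- simulate_series(pr, study_config(seed = 1), "p1")

  # mean strategy, zero noise: only quantisation error remains
  set.seed(1)
  rec <- generate_ra(s, strategy_model("mean"))
  expect_lte(abs(rec$ra_summary - mean(observed_scores(s))), 0.05)
  expect_equal(rec$true_summary, mean(observed_scores(s)))

  # zero salience weight reduces to the mean strategy
  set.seed(1)
  rec0 <- generate_ra(s, strategy_model("salience_weighted",
                                        salience_weight = 0,
                                        report_noise_sd = 0))
  expect_equal(rec0$true_summary, mean(observed_scores(s)))

  # positive salience weight pulls the summary toward intense scores
  set.seed(1)
  rec2 <- generate_ra(s, strategy_model("salience_weighted",
                                        salience_weight = 3,
                                        report_noise_sd = 0))
  expect_gte(rec2$true_summary, mean(observed_scores(s)))

  # peak-end strategy on a right-skewed series sits above the mean
  skewed <- make_series(scores_from_counts(c(28, 8, 3, 2, 1)),
                        valence = "negative")
  set.seed(1)
  rec_pe <- generate_ra(skewed, strategy_model("peak_end",
                                               report_noise_sd = 0))
  expect_gt(rec_pe$true_summary, mean(observed_scores(skewed)))
})

test_that("strategy mixes are validated and recorded in the truth table", {
  expect_error(generate_cohort(study_config(n_participants = 4),
                               strategy_mix = c(mean = 0.5)),
               "summing to 1")
  co <- generate_cohort(study_config(n_participants = 40, seed = 2),
                        strategy_mix = c(mean = 0.5, peak_end = 0.5))
  expect_setequal(unique(co$truth$strategy), c("mean", "peak_end"))
  # one strategy per participant, shared across valences
  per_p <- tapply(co$truth$strategy, co$truth$participant_id,
                  function(x) length(unique(x)))
  expect_true(all(per_p == 1))
})
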