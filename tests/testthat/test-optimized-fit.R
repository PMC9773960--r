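test_that("a target equal to the observed mean returns the observed distribution", {
  p <- c(.2, .3, .1, .25, .15)
  m <- sum(p * 1:5)
  fit <- fit_optimized_distribution(p, target_mean = m)
  expect_equal(fit$q$probs, p, tolerance = 1e-12)
  expect_equal(fit$objective_value, 0)
  expect_true(fit$converged)
  expect_equal(fit$method, "observed")
})

test_that("mass moves to the unobserved extreme category when needed", {
  fit <- fit_optimized_distribution(c(.5, .5, 0), target_mean = 2,
                                    scale = likert_scale(3))
  expect_equal(fit$q$probs, c(.25, .5, .25), tolerance = 1e-9)
  expect_equal(fit$objective_value, 0.5 * log(2), tolerance = 1e-9)
  expect_equal(fit$achieved_mean, 2, tolerance = 1e-9)
  expect_equal(fit$method, "extreme_high")
  expect_true(fit$converged)
})

test_that("a uniform distribution with the central target stays uniform", {
  fit <- fit_optimized_distribution(rep(.2, 5), target_mean = 3)
  expect_equal(fit$q$probs, rep(.2, 5), tolerance = 1e-12)
  expect_equal(fit$objective_value, 0)
})

test_that("fitted distributions keep positive mass on observed categories", {
  set.seed(7)
  for (i in 1:40) {
    counts <- random_counts(5)
    p <- counts / sum(counts)
    m <- runif(1, 1.1, 4.9)
    fit <- fit_optimized_distribution(p, counts = counts, target_mean = m)
    expect_true(all(fit$q$probs[p > 0] > 0))
    expect_true(fit$objective_value >= 0)
  }
})

test_that("converged fits satisfy the mean constraint to 1e-6", {
  set.seed(12)
  for (i in 1:100) {
    K <- sample(3:5, 1)
    counts <- random_counts(K)
    p <- counts / sum(counts)
    m <- runif(1, 1 + 0.05 * (K - 1), K - 0.05 * (K - 1))
    fit <- fit_optimized_distribution(p, counts = counts, target_mean = m,
                                      scale = likert_scale(K))
    expect_true(fit$converged)
    expect_lt(abs(fit$achieved_mean - m), 1e-6)
  }
})

test_that("objective grows with the distance of the target from the observed mean", {
  set.seed(5)
  for (i in 1:10) {
    counts <- random_counts(5)
    p <- counts / sum(counts)
    m0 <- sum(p * 1:5)
    for (direction in c(-1, 1)) {
      lim <- min(if (direction < 0) m0 - 1.02 else 5 - 0.02 - m0, 1.5)
      if (lim < 0.06) next
      targets <- m0 + direction * seq(0.05, lim, length.out = 8)
      objs <- vapply(targets, function(m) {
        fit_optimized_distribution(p, target_mean = m)$objective_value
      }, numeric(1))
      expect_true(all(diff(objs) >= -1e-10))
    }
  }
})

test_that("endpoint targets with mass elsewhere are flagged degenerate", {
  fit <- fit_optimized_distribution(c(.5, .5, 0, 0, 0), target_mean = 1)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_equal(fit$objective_value, Inf)
  expect_equal(fit$q$probs, c(1, 0, 0, 0, 0))

  fit <- fit_optimized_distribution(c(0, 0, 0, .1, .9), target_mean = 5)
  expect_true(fit$degenerate)

  # a point mass whose mean is the endpoint is fine
  fit <- fit_optimized_distribution(c(1, 0, 0, 0, 0), target_mean = 1)
  expect_false(fit$degenerate)
  expect_equal(fit$objective_value, 0)
})

test_that("targets off the scale are rejected as infeasible", {
  expect_error(fit_optimized_distribution(rep(.2, 5), target_mean = 5.3),
               "infeasible")
  expect_error(fit_optimized_distribution(rep(.2, 5), target_mean = 0.7),
               "infeasible")
})

test_that("inconsistent counts are rejected", {
  expect_error(
    fit_optimized_distribution(c(.5, .5, 0), counts = c(10, 20, 0),
                               target_mean = 1.6, scale = likert_scale(3)),
    "not consistent")
})

test_that("optimizer matches the brute-force grid oracle", {
  set.seed(23)
  for (i in 1:12) {
    K <- if (i %% 2 == 0) 3L else 4L
    counts <- random_counts(K)
    p <- counts / sum(counts)
    m <- runif(1, 1 + 0.1 * (K - 1), K - 0.1 * (K - 1))
    fit <- fit_optimized_distribution(p, target_mean = m,
                                      scale = likert_scale(K))
    oracle <- oracle_min_objective(p, as.numeric(1:K), m)
    expect_lt(abs(fit$objective_value - oracle), 1e-4)
  }
})

test_that("tilt solution matches the optimizer on interior fits", {
  # exact two-support-point cases
  expect_equal(tilt_solution(c(.5, .5), 1.8, likert_scale(2))$probs, c(.2, .8),
               tolerance = 1e-9)
  expect_equal(tilt_solution(c(.5, .5), 1.5, likert_scale(2))$probs, c(.5, .5),
               tolerance = 1e-12)

  set.seed(99)
  n_checked <- 0
  for (i in 1:60) {
    counts <- random_counts(5)
    p <- counts / sum(counts)
    supp_v <- (1:5)[p > 0]
    if (length(supp_v) < 2) next
    m <- runif(1, min(supp_v) + 0.05, max(supp_v) - 0.05)
    fit <- fit_optimized_distribution(p, target_mean = m)
    if (fit$method != "interior") next  # optimizer used an unobserved category
    tilt <- tilt_solution(p, m)
    expect_lt(max(abs(tilt$probs - fit$q$probs)), 1e-5)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 20)
})

test_that("tilt solution is not applicable beyond the observed support range", {
  expect_null(tilt_solution(c(.5, .5, 0), 2.5, likert_scale(3)))
  expect_null(tilt_solution(c(0, .5, .5, 0, 0), 1.4))
})
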