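#' Chi-squared goodness of fit of observed counts to a distribution
#'
#' Pearson chi-squared test of observed category counts against expected
#' counts `n * q_k` under a reference distribution `q` (here: the optimized
#' retrospective distribution). The statistic sums over categories with
#' positive expected count; an observed count in a category with zero
#' probability under `q` makes the statistic infinite and is reported as
#' `p_value = 0` with `infinite_stat = TRUE`.
#'
#' Degrees of freedom default to (number of categories with positive
#' expected count) - 1, the standard goodness-of-fit count: the mean
#' restriction comes from an externally given retrospective score, not from
#' a parameter estimated out of the tested counts. The alternative rule
#' subtracting one further degree of freedom is available via `df_rule`.
#' For small expected counts a Monte-Carlo p-value (counts re-drawn from
#' `q`) can be requested instead of the asymptotic tail.
#'
#' @param counts Observed category counts.
#' @param q Reference distribution ([categorical_distribution()] or
#'   probability vector).
#' @param df_rule `"support_minus_1"` (default) or `"support_minus_2"`.
#' @param monte_carlo If `TRUE`, compute the p-value by simulation from `q`.
#' @param n_sim Number of Monte-Carlo replicates.
#' @return List of class `gof_test` with `statistic`, `df`, `p_value`,
#'   `n`, `method`, `infinite_stat`.
#' @export
#' @examples
#' chi_squared_gof(c(10, 10, 0), c(.25, .5, .25))  # statistic 10
chi_squared_gof <- function(counts, q,
                            df_rule = c("support_minus_1", "support_minus_2"),
                            monte_carlo = FALSE, n_sim = 2000) {
  df_rule <- match.arg(df_rule)
  probs <- as_prob_vector(q, "q")
  counts <- as.numeric(counts)
  stopifnot(length(counts) == length(probs), all(counts >= 0))
  n <- sum(counts)
  if (n < 1) abort("Need at least one observed count.")
  pos <- probs > 1e-12
  df <- max(1L, sum(pos) - switch(df_rule, support_minus_1 = 1L,
                                  support_minus_2 = 2L))
  if (any(counts[!pos] > 0)) {
    return(structure(
      list(statistic = Inf, df = df, p_value = 0, n = n,
           method = "asymptotic", infinite_stat = TRUE),
      class = "gof_test"))
  }
  expected <- n * probs[pos]
  stat <- sum((counts[pos] - expected)^2 / expected)
  if (monte_carlo) {
    sims <- rmultinom(n_sim, n, probs)
    exp_all <- n * probs
    sim_stat <- colSums((sims[pos, , drop = FALSE] - expected)^2 / expected)
    p <- (1 + sum(sim_stat >= stat - 1e-12)) / (n_sim + 1)
    method <- "monte_carlo"
  } else {
    p <- pchisq(stat, df, lower.tail = FALSE)
    method <- "asymptotic"
  }
  structure(
    list(statistic = stat, df = df, p_value = p, n = n,
         method = method, infinite_stat = FALSE),
    class = "gof_test")
}

#' @export
print.gof_test <- function(x, ...) {
  cat(sprintf("<gof_test> X2 = %.4g, df = %d, p = %.4g (%s)\n",
              x$statistic, x$df, x$p_value, x$method))
  invisible(x)
}

#' Jensen-Shannon divergence between two categorical distributions
#'
#' Symmetric divergence via the midpoint mixture `m = (p + q)/2`:
#' `JSD = KL(p || m)/2 + KL(q || m)/2`. With base-2 logarithms (the
#' default) it ranges from 0 (identical distributions) to 1 (disjoint
#' supports). The `0 * log 0 = 0` convention applies.
#'
#' @param p,q Distributions on the same scale
#'   ([categorical_distribution()] or probability vectors).
#' @param base Logarithm base; 2 gives the 0-1 range, `exp(1)` gives
#'   the natural-log variant with maximum `log(2)`.
#' @return A single number in `[0, 1]` (for base 2).
#' @export
#' @examples
#' jensen_shannon(c(1, 0, 0), c(0, 0, 1))                 # 1: disjoint
#' jensen_shannon(c(.5, .5, 0), c(.25, .5, .25))          # ~0.1556
jensen_shannon <- function(p, q, base = 2) {
  pv <- as_prob_vector(p, "p")
  qv <- as_prob_vector(q, "q")
  stopifnot(length(pv) == length(qv))
  m <- (pv + qv) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  jsd <- (kl(pv) + kl(qv)) / (2 * log(base))
  min(max(jsd, 0), if (base == 2) 1 else log(2) / log(base))
}

#' Per-participant comparison of retrospective summary and EMA distribution
#'
#' Runs the full single-participant decision: fit the optimized
#' retrospective distribution with the participant's summary score as its
#' mean ([fit_optimized_distribution()]), test the observed counts against
#' it ([chi_squared_gof()]), and quantify the divergence between observed
#' and optimized distributions ([jensen_shannon()]). The null hypothesis is
#' that the observed EMA distribution is identical to the optimized
#' retrospective distribution; a rejection is evidence that the summary
#' score is not the mean of the experiences captured by EMA. Effect size
#' (JSD) and significance are reported separately and may disagree.
#'
#' A degenerate fit (summary score at a scale endpoint while other
#' categories were observed) is an automatic rejection, flagged as such.
#' No multiplicity correction is applied across participants.
#'
#' @param series An [ema_series()].
#' @param ra Retrospective record (list or one-row data frame with
#'   `participant_id`, `valence`, `ra_summary`).
#' @param alpha Per-participant significance level.
#' @param df_rule,monte_carlo,n_sim Passed to [chi_squared_gof()].
#' @param jsd_base Logarithm base for the divergence.
#' @return List of class `comparison_result` with `participant_id`,
#'   `valence`, `p_obs`, `fit`, `test`, `chi2_stat`, `df`, `p_value`,
#'   `jsd`, `alpha`, `reject_mean_hypothesis`, `degenerate`.
#' @export
compare_participant <- function(series, ra, alpha = 0.05,
                                df_rule = "support_minus_1",
                                monte_carlo = FALSE, n_sim = 2000,
                                jsd_base = 2) {
  ra <- as.list(ra)
  counts <- score_counts(series)
  p_obs <- relative_frequencies(series)
  fit <- fit_optimized_distribution(p_obs, counts = counts,
                                    target_mean = as.numeric(ra$ra_summary))
  if (fit$degenerate) {
    test <- list(statistic = Inf, df = NA_integer_, p_value = 0,
                 n = sum(counts), method = "degenerate", infinite_stat = TRUE)
  } else {
    test <- chi_squared_gof(counts, fit$q, df_rule = df_rule,
                            monte_carlo = monte_carlo, n_sim = n_sim)
  }
  jsd <- jensen_shannon(p_obs, fit$q, base = jsd_base)
  structure(
    list(
      participant_id = series$participant_id,
      valence = series$valence,
      p_obs = p_obs,
      fit = fit,
      test = test,
      chi2_stat = test$statistic,
      df = test$df,
      p_value = test$p_value,
      jsd = jsd,
      alpha = alpha,
      reject_mean_hypothesis = test$p_value < alpha,
      degenerate = fit$degenerate
    ),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s/%s: X2 = %.3g (df %s), p = %.3g, JSD = %.3g -> %s\n",
    x$participant_id, x$valence, x$chi2_stat,
    ifelse(is.na(x$df), "-", x$df), x$p_value, x$jsd,
    if (x$reject_mean_hypothesis) "reject mean hypothesis" else "not rejected"))
  invisible(x)
}
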