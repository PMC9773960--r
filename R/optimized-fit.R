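#' Mean-constrained closest distribution ("optimized RA distribution")
#'
#' Finds the categorical distribution `q` that is closest to the observed
#' EMA distribution `p_obs` among all distributions on the same scale whose
#' mean equals `target_mean` (the retrospective summary score). Closeness is
#' the Kullback-Leibler divergence of the observed distribution from `q`,
#'
#'   D(p || q) = sum over categories with p_k > 0 of p_k * log(p_k / q_k),
#'
#' so `q` is also the maximum-likelihood multinomial distribution for the
#' observed counts subject to the mean restriction (minimising D(p||q) and
#' maximising the constrained log-likelihood are the same problem; the
#' count-weighted log-likelihood difference is `n_obs * objective_value`).
#'
#' The problem is convex and is solved exactly from its optimality
#' conditions rather than by iterative search. On the observed support the
#' solution has the reciprocal-linear ("likelihood tilt") form
#' `q_k = p_k / (1 + theta * (value_k - target_mean))`, with `theta` found
#' by a one-dimensional root solve. When the target mean cannot be reached
#' that way - typically when the retrospective score sits beyond (or far
#' toward) the edge of the observed support - the optimum additionally
#' places mass on the most extreme *unobserved* category, for which a closed
#' form exists. Mass on categories never observed costs nothing in
#' likelihood, which is why large retrospective-momentary discrepancies are
#' absorbed by the highest or lowest category rather than by inflating
#' near-observed categories.
#'
#' A target mean exactly at an endpoint of the scale (with observed mass
#' elsewhere) admits only a point-mass solution with infinite divergence;
#' this is reported as a flagged, non-converged degenerate fit rather than
#' an error.
#'
#' @param p_obs Observed distribution: a [categorical_distribution()] or
#'   probability vector.
#' @param counts Optional vector of observed category counts consistent
#'   with `p_obs`; used only to report the count-weighted objective and
#'   `n_obs`.
#' @param target_mean The mean the fitted distribution must have
#'   (the retrospective summary score), within the scale value range.
#' @param scale A [likert_scale()]; defaults to the scale of `p_obs` or a
#'   1..K scale.
#' @param tol Constraint tolerance used for the convergence flag.
#'
#' @return An object of class `optimized_fit`: list with `q` (a
#'   [categorical_distribution()]), `target_mean`, `achieved_mean`,
#'   `objective_value` (KL divergence, nats), `loglik_diff`
#'   (`n_obs * objective_value`, `NA` without counts), `converged`,
#'   `degenerate`, `method` (`"observed"`, `"interior"`, `"extreme_low"`,
#'   `"extreme_high"`, or `"degenerate"`), `n_obs`, and `extreme_mass` (the
#'   probability placed on an unobserved extreme category).
#' @seealso [tilt_solution()] for the restricted-support closed form.
#' @export
#' @examples
#' # Observed scores split between categories 1 and 2, retrospective mean 2:
#' # the fit moves a quarter of the mass to the unobserved category 3.
#' fit <- fit_optimized_distribution(c(.5, .5, 0), target_mean = 2,
#'                                   scale = likert_scale(3))
#' round(fit$q$probs, 3)      # 0.25 0.50 0.25
#' fit$objective_value        # 0.5 * log(2)
fit_optimized_distribution <- function(p_obs, counts = NULL, target_mean,
                                       scale = NULL, tol = 1e-8) {
  if (inherits(p_obs, "categorical_distribution")) {
    scale <- scale %||% p_obs$scale
  }
  p <- as_prob_vector(p_obs, "p_obs")
  scale <- scale %||% likert_scale(length(p))
  stopifnot(is_likert_scale(scale), length(p) == scale$n_categories)
  v <- scale$values
  target_mean <- as.numeric(target_mean)
  if (is.na(target_mean) || target_mean < min(v) - 1e-12 ||
      target_mean > max(v) + 1e-12) {
    abort(sprintf("`target_mean` %g is infeasible on a scale with values in [%g, %g].",
                  target_mean, min(v), max(v)))
  }
  n_obs <- NA_integer_
  if (!is.null(counts)) {
    counts <- as.numeric(counts)
    stopifnot(length(counts) == length(p), all(counts >= 0))
    n_obs <- as.integer(round(sum(counts)))
    if (n_obs > 0 && max(abs(counts / n_obs - p)) > 1e-6) {
      abort("`counts` are not consistent with `p_obs`.")
    }
  }

  mean_p <- sum(p * v)
  supp <- p > 0
  finish <- function(q, method, converged = TRUE, degenerate = FALSE) {
    q <- pmax(q, 0)
    q <- q / sum(q)
    obj <- sum(p[supp] * log(p[supp] / pmax(q[supp], 1e-300)))
    obj <- max(obj, 0)
    structure(
      list(
        q = categorical_distribution(q, scale),
        target_mean = target_mean,
        achieved_mean = sum(q * v),
        objective_value = if (degenerate) Inf else obj,
        loglik_diff = if (is.na(n_obs)) NA_real_
                      else if (degenerate) Inf else n_obs * obj,
        converged = converged && !degenerate &&
          abs(sum(q * v) - target_mean) <= max(tol, 1e-6),
        degenerate = degenerate,
        method = method,
        n_obs = n_obs,
        extreme_mass = sum(q[!supp])
      ),
      class = "optimized_fit"
    )
  }

  # Constraint already satisfied: the observed distribution is the optimum.
  if (abs(target_mean - mean_p) <= 1e-12) {
    return(finish(p, "observed"))
  }

  # Endpoint target with observed mass elsewhere: only the point mass at the
  # endpoint is feasible and its divergence is infinite.
  at_low <- abs(target_mean - min(v)) <= 1e-12
  at_high <- abs(target_mean - max(v)) <= 1e-12
  if (at_low || at_high) {
    q <- numeric(length(p))
    q[if (at_low) which.min(v) else which.max(v)] <- 1
    return(finish(q, "degenerate", converged = FALSE, degenerate = TRUE))
  }

  vs <- v[supp]
  ps <- p[supp]
  vmin_s <- min(vs)
  vmax_s <- max(vs)

  # Interior solve on the observed support: q_k = p_k / (1 + theta (v_k - m)),
  # theta the root of g(theta) = sum p_k (v_k - m) / (1 + theta (v_k - m)).
  interior <- NULL
  if (target_mean > vmin_s && target_mean < vmax_s) {
    d <- vs - target_mean
    g <- function(th) sum(ps * d / (1 + th * d))
    lo <- -1 / (vmax_s - target_mean)
    hi <- 1 / (target_mean - vmin_s)
    eps <- (hi - lo) * 1e-12
    lo_e <- lo + eps
    hi_e <- hi - eps
    # g is strictly decreasing from +Inf to -Inf on (lo, hi).
    while (g(lo_e) <= 0) lo_e <- (lo_e + lo) / 2
    while (g(hi_e) >= 0) hi_e <- (hi_e + hi) / 2
    th <- uniroot(g, c(lo_e, hi_e), tol = .Machine$double.eps^0.9)$root
    # Newton polish for machine-precision constraint satisfaction.
    for (i in 1:4) {
      gp <- -sum(ps * d^2 / (1 + th * d)^2)
      step <- g(th) / gp
      th_new <- th - step
      if (th_new > lo && th_new < hi) th <- th_new
      if (abs(g(th)) < 1e-14) break
    }
    qs <- ps / (1 + th * d)
    # The support solution is globally optimal iff no unobserved category
    # violates the dual feasibility condition 1 + theta (v_k - m) >= 0.
    if (all(1 + th * (v[!supp] - target_mean) >= -1e-10)) {
      q <- numeric(length(p))
      q[supp] <- qs
      interior <- finish(q, "interior")
    }
  }
  if (!is.null(interior)) return(interior)

  # Extreme-category branch: mass on the most extreme unobserved category e
  # (highest when shifting the mean up, lowest when shifting down);
  # support categories take the closed form q_k = p_k (m - v_e)/(v_k - v_e).
  e <- if (target_mean > mean_p) which.max(v) else which.min(v)
  if (p[e] > 0) {
    # Cannot occur for feasible non-degenerate targets; defensive only.
    abort("Internal error: extreme category unexpectedly observed.")
  }
  ve <- v[e]
  q <- numeric(length(p))
  q[supp] <- ps * (target_mean - ve) / (vs - ve)
  q[e] <- max(0, 1 - sum(q[supp]))
  finish(q, if (target_mean > mean_p) "extreme_high" else "extreme_low")
}

#' @export
print.optimized_fit <- function(x, ...) {
  cat(sprintf(
    "<optimized_fit> target %.3f, achieved %.6f, KL %.5f, method %s%s\n",
    x$target_mean, x$achieved_mean, x$objective_value, x$method,
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Closed-form restricted-support solution (likelihood tilt)
#'
#' The mean-constrained KL/likelihood optimum restricted to the observed
#' support has the closed reciprocal-linear form
#' `q_k = p_k / (1 + theta * (value_k - target_mean))` with a single scalar
#' `theta` chosen so the mean constraint holds; the normalisation to 1 then
#' holds automatically. This "tilt" of the observed distribution is exact
#' whenever the target mean lies strictly between the smallest and largest
#' observed category values, and agrees with [fit_optimized_distribution()]
#' whenever the full-simplex optimum places no mass on unobserved
#' categories. It is exposed as an independent cross-check on the main
#' fitting routine (solved here by plain bisection).
#'
#' @param p_obs Observed distribution ([categorical_distribution()] or
#'   probability vector).
#' @param target_mean Required mean.
#' @param scale Optional [likert_scale()].
#' @return A [categorical_distribution()], or `NULL` when the target mean is
#'   not strictly inside the observed-support value range (mass on
#'   unobserved categories is then required and no restricted-support
#'   solution exists).
#' @export
#' @examples
#' tilt_solution(c(.5, .5), 1.8, likert_scale(2))$probs  # 0.2 0.8
tilt_solution <- function(p_obs, target_mean, scale = NULL) {
  if (inherits(p_obs, "categorical_distribution")) {
    scale <- scale %||% p_obs$scale
  }
  p <- as_prob_vector(p_obs, "p_obs")
  scale <- scale %||% likert_scale(length(p))
  v <- scale$values
  supp <- p > 0
  vs <- v[supp]
  ps <- p[supp]
  d <- vs - target_mean
  if (target_mean <= min(vs) || target_mean >= max(vs)) {
    if (abs(target_mean - sum(p * v)) <= 1e-12) return(categorical_distribution(p, scale))
    return(NULL)
  }
  if (abs(sum(ps * d)) <= 1e-14) return(categorical_distribution(p, scale))
  g <- function(th) sum(ps * d / (1 + th * d))
  lo <- -1 / (max(vs) - target_mean)
  hi <- 1 / (target_mean - min(vs))
  a <- lo + (hi - lo) * 1e-9
  b <- hi - (hi - lo) * 1e-9
  while (g(a) <= 0) a <- (a + lo) / 2
  while (g(b) >= 0) b <- (b + hi) / 2
  # bisection, deliberately self-contained
  for (i in 1:200) {
    mid <- (a + b) / 2
    if (g(mid) > 0) a <- mid else b <- mid
    if (b - a < 1e-15 * max(1, abs(a))) break
  }
  th <- (a + b) / 2
  q <- numeric(length(p))
  q[supp] <- ps / (1 + th * d)
  q <- q / sum(q)
  categorical_distribution(q, scale)
}
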