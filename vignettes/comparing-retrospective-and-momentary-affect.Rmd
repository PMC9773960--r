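---
title: "Methods: deciding whether a retrospective summary is the mean of momentary experience"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deciding whether a retrospective summary is the mean of momentary experience}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emarecall)
```

## The question

Ecological momentary assessment (EMA) samples a person's affect in the
moment, typically several times a day over weeks; a retrospective
assessment (RA) asks the same person afterwards for a single summary score
over the same period. RA scores are usually compared to the *mean* of the
EMA scores, and group-level discrepancies are read as recall bias toward
salient experiences. But RA questions are usually *unspecific* — they never
say "report your average" — so each participant is free to apply their own
summary rule. `emarecall` asks the per-person (repeated N = 1) question
instead: *given this participant's whole distribution of momentary scores,
could their retrospective score plausibly be the mean of those
experiences?*

The decision machinery works on a `r 5`-point Likert scale (categories
scored 1–5), a schedule of 3 beeps/day for 14 days (42 scheduled prompts),
and a retrospective score on the same 1–5 range with 0.1 granularity (a
10-item questionnaire mean), but every one of those constants is a
parameter (`likert_scale()`, `study_config()`).

## The per-participant procedure

For one participant and one affect valence:

1. **Observed EMA distribution.** Relative frequencies of the answered
   beeps over the K categories (`relative_frequencies()`); missing beeps
   are excluded.
2. **Optimized RA distribution.** The distribution `q` *closest* to the
   observed one among all distributions whose mean equals the RA score
   (`fit_optimized_distribution()`). Closeness is the Kullback–Leibler
   divergence of the observed distribution `p` from `q`,
   `D(p‖q) = Σ p_k log(p_k/q_k)`, equivalently the multinomial
   log-likelihood difference: `q` is the constrained maximum-likelihood
   model for the observed counts given the mean restriction.
3. **Test.** Pearson chi-squared goodness of fit of the observed counts
   against `n·q` (`chi_squared_gof()`). The null hypothesis is that the
   observed distribution *is* the optimized one; rejection at α = .05
   (uncorrected, per participant) is evidence that the RA score is not the
   mean of the experiences EMA captured.
4. **Effect size.** The Jensen–Shannon divergence between observed and
   optimized distributions (`jensen_shannon()`), base-2 logarithms so the
   range is [0, 1]. Significance and effect size are deliberately reported
   side by side; with 17–42 observations they can and do disagree.
5. **Context.** Raw difference (RA − EMA mean), position of the RA score
   relative to the interquartile and full observed range, the peak-end
   summary and its difference, completion rate, and extreme-case flags.

`run_analysis()` applies this to a whole cohort and emits
participant-level, cohort-summary, quadrant, and extreme-case tables.

## Solving the mean-constrained fit

Minimising `D(p‖q)` subject to `Σ q_k = 1`, `Σ v_k q_k = m`, `q ≥ 0` is a
convex problem and its optimality conditions can be solved exactly, which
is what `fit_optimized_distribution()` does instead of running a
general-purpose iterative optimizer:

* **Interior (likelihood-tilt) branch.** On the observed support the
  optimum has the reciprocal-linear form
  `q_k = p_k / (1 + θ(v_k − m))` — the same weight family that appears in
  empirical-likelihood estimation. The scalar `θ` solves
  `Σ p_k (v_k − m)/(1 + θ(v_k − m)) = 0`, a strictly decreasing function
  with a bracketed root; we use Brent's method plus a few Newton polish
  steps, leaving the constraint satisfied to ~1e−12 (the convergence flag
  requires 1e−6). Note this family is *not* the exponential tilt
  `q_k ∝ p_k e^{λ v_k}`; that family solves the reverse divergence
  `D(q‖p)` and coincides with ours only on two-point supports.
  `tilt_solution()` exposes the closed form as an independent cross-check.
* **Extreme-category branch.** Mass on categories that were never observed
  costs nothing in likelihood. Whenever the dual feasibility condition
  `1 + θ(v_k − m) ≥ 0` fails for an unobserved category — which happens
  exactly when the RA score sits beyond, or far toward, the edge of the
  observed support — the optimum puts probability on the most extreme
  unobserved category, with the closed form
  `q_k = p_k (m − v_e)/(v_k − v_e)` on the support and the remainder on
  category `e`. This reproduces the characteristic "compensation at the
  extremes": a large retrospective–momentary discrepancy is explained by
  weight on the most intense (or mildest) possible experience rather than
  by inflating scores near the observed ones.
* **Degenerate targets.** An RA score exactly at a scale endpoint, with
  any observed mass elsewhere, admits only the endpoint point mass, whose
  divergence is infinite. These fits are flagged (`degenerate = TRUE`,
  non-converged) and treated downstream as automatic rejections — the
  observed data formally contradict the mean hypothesis — rather than
  raising an error.

The test suite checks the solver against an exhaustive grid search over
the mean-constrained slice of the simplex (step 1e−3 with a local
refinement pass) on randomized instances, against the closed-form tilt on
interior fits, and for monotonicity of the objective in the distance
between target and observed mean.

## The chi-squared test and its calibration

Degrees of freedom default to (number of categories with positive expected
count) − 1. The mean restriction comes from an externally reported RA
score, not from a parameter estimated out of the tested counts, so no
additional degree of freedom is subtracted by default;
`df_rule = "support_minus_2"` provides the alternative. With counts drawn
from a *fixed* fitted distribution (n = 42, K = 5) the default rule's
p-values are uniform to within Kolmogorov distance 0.05 — the calibration
property the test suite verifies.

Two caveats are worth stating plainly:

* **The per-participant test is conservative as a type-I-error rule.** In
  the strategy-recovery experiments, cohorts whose simulated participants
  truly report the mean of their answered beeps are rejected far below the
  nominal 5% rate. The reason is structural: the null distribution `q` is
  fitted to the very counts being tested, so when the RA score equals the
  observed mean, `q` equals the observed distribution (statistic 0) up to
  the 0.1 reporting granularity. The residual rejections are almost all
  endpoint-degenerate cases in which a near-floor mean quantises to
  exactly 1.0. Asymptotically the statistic under a true mean constraint
  concentrates like a 1-df chi-squared while being referred to a (K−1)-df
  distribution. A failure to reject is therefore strong evidence of
  closeness, while the rejection *rate* among true mean-reporters should
  not be read as α.
* **Small expected counts.** No pooling or continuity correction is
  applied by default (the substantive analyses test raw 5-category
  tables); `monte_carlo = TRUE` re-draws counts from `q` for an exact
  Monte-Carlo p-value when expected counts are small.

The Jensen–Shannon divergence uses base-2 logarithms (range [0, 1]); the
natural-log variant (range [0, log 2]) is available via `jsd_base`. With
n ≤ 42 and K = 5 the realistic maximum divergence on fitted pairs stays
well below 1.

## The synthetic cohort generator

No raw participant-level dataset of this design is publicly deposited, so
the generator (`generate_cohort()`) emulates the study conditions and is
the substrate for all end-to-end testing:

* **Profiles.** Each participant × valence gets a latent category
  distribution drawn from a Dirichlet family. Hyperparameters were
  moment-matched once to the published cohort descriptives: negative
  affect concentrated at the lowest categories (mean of per-person means
  ≈ 1.5, SD ≈ 0.35), positive affect spread around the midpoint (≈ 2.7,
  SD ≈ 0.66). With shape `g` and concentration `A`, the SD of profile
  means is `sd_g/√(A+1)`, giving `A = 2.3` (positive) and `A = 5.3`
  (negative) for the shapes in `emarecall:::profile_hyperparams`.
* **Series.** Scores are i.i.d. draws from the profile. The comparison
  machinery is entirely distribution-based and the substantive method
  never models serial dependence, so none is simulated by default.
* **Missingness.** Missing completely at random at rate 0.10 per beep;
  a ~21% subgroup receives an elevated rate drawn from U(0.45, 0.62),
  placing their completion in the ~0.38–0.55 band and below the 27-of-42
  (65%) threshold. The threshold flag uses the strictly-below rule:
  exactly 27 answered beeps is *not* flagged.
* **Reporting strategies.** Each participant applies one rule to produce
  their RA score: `mean` (noise-free), `noisy_mean` (Gaussian report noise,
  SD 0.15 on the summary scale), `peak_end` (average of the final
  scheduled day's mean and the single most intense score), or
  `salience_weighted` (weights `1 + w·(score−min)/(max−min)`). All
  summaries are quantised to 0.1 and clipped to [1, 5]. The default cohort
  mix (40/25/20/15%) encodes the premise that most people approximate an
  average while a substantial minority weight salient experiences; it is a
  modelling choice, not an estimate.

What the generator does **not** emulate: serial and diurnal structure,
systematic (non-random) missingness, item-level psychometrics of the
10-item retrospective questionnaire, and any coupling between a person's
affect level and their reporting strategy. Passing tests therefore show
that the analysis machinery behaves correctly under the stated data model,
not that real cohorts satisfy that model.

## Numerical and reporting conventions

* Interquartile ranges use linear-interpolation quantiles
  (`quantile_type = 7`), configurable; no quantile convention is canonical
  for 5-point data and published group summaries are sensitive to it.
* All tied modes are reported; scalar cohort summaries use the mean of the
  tied modes.
* Raw differences of exactly zero sit on the quadrant axes and are counted
  as `axis`, not assigned to a quadrant.
* Report tables round descriptives and differences to 2 decimals and RA
  summaries to 1 decimal.
* The `high_jsd` extreme flag defaults to the cohort 95th percentile
  (absolute threshold configurable); `high_raw_diff` defaults to 2 full
  scale points; flags are recomputed, never stored.
* Everything stochastic flows from a single integer seed
  (`study_config(seed = )`); cohort generation is byte-reproducible.

## Problem sizes

The shipped tests run the solver-versus-grid oracle on 100 randomized
K ≤ 4 instances, calibration on 2000 simulated count vectors, recovery
experiments on 10 replicate cohorts of 91 participants × 2 valences per
strategy, and generator checks on 1000 profiles per valence — sizes chosen
to make Monte-Carlo error small relative to every margin being asserted.

## Known limitations

* A single point-estimate RA score cannot separate the participant's
  summary *function* from the *subset* of experiences they recall; a
  non-rejection says the mean hypothesis is compatible with the data, not
  that the participant used the mean.
* The chi-squared test's conservativeness (above) means rejection counts
  across a cohort are a lower bound on mean-incompatible reporting.
* Low-completion participants pass through the pipeline flagged but
  untreated; representativeness of their answered beeps is the user's
  judgement.
* The generator's Dirichlet family cannot produce every empirical profile
  shape (e.g. hard zero-inflation beyond what low concentrations give).
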