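Package: emarecall
Title: Comparing Retrospective Affect Summaries with Momentary
    Assessment Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for deciding, one participant at a time, whether an
    unspecific retrospective summary score of affect could plausibly be
    the mean of the person's momentary experiences recorded with
    ecological momentary assessment (EMA).  Implements mean-constrained
    closest-distribution fitting over Likert categories (the constrained
    maximum-likelihood "optimized" distribution), per-person chi-squared
    goodness-of-fit tests and Jensen-Shannon divergences, peak-end
    retrospective summaries, a synthetic cohort generator with explicit
    participant reporting strategies, and an end-to-end analysis pipeline
    with strategy-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
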