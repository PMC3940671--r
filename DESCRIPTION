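Package: antscores
Title: Condition-Dissection Scoring and Reliability for the Attention
    Network Test
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for computing Attention Network Test (ANT) scores by
    dissecting the six cue-by-target conditions into additive components,
    alongside the traditional cell-mean contrasts. Provides directed
    inter-network influence scores (interaction contrasts between the
    alerting, orienting and executive-control networks), trial-level
    preprocessing (reaction-time window filtering, accuracy-based subject
    exclusion, per-condition median summaries), one-way random-effects
    intraclass correlation and permutation split-half reliability,
    repeated-measures ANOVA with Greenhouse-Geisser correction and partial
    eta-squared, and a counterbalanced ANT experiment simulator with an
    additive reaction-time model and explicit interaction parameters for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
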