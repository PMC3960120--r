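Package: fetchr
Title: Statistics for Forced-Choice Fetch-Task Word-Learning Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trial-level data from forced-choice object
    retrieval ("fetch task") experiments in comparative cognition, in which a
    subject is asked to retrieve a newly labelled object from an array. Provides
    a seeded Monte-Carlo chance null for the mean retrieval-attempt statistic of
    sequential search without replacement, together with its exact enumeration
    twin; exact binomial tests with explicit tail conventions (one-tailed
    smaller tail, tail-doubling two-tailed) and asymmetric chance levels;
    Pearson chi-square for 2x2 tables without continuity correction; end-to-end
    per-subject analysis reports for three canonical experiment designs;
    agent-based simulators (random, knower, associative, enhancement, learner
    agents) for generating synthetic trial data under those designs; and
    type-I error and power estimation for the tests under the agent models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
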