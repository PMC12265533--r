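Package: wmcda
Title: Dual-Process ROC Modeling and Contralateral Delay Activity
    Analysis for Visual Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for visual working-memory experiments that
    combine confidence-rating recognition with lateralized EEG.  Provides
    synthetic-data generators (dual-process recognition trials, a
    fixed-capacity change-detection observer, and lateralized ERP epochs
    with injectable ocular and EEG artifacts), behavioral summaries
    (hit/false-alarm rates, Cowan's K, confidence ROCs,
    repeated-measures ANOVA with partial eta-squared, Bonferroni-corrected
    pairwise tests), a hierarchical Bayesian dual-process signal-detection
    (DPSD) model of recognition ROCs estimated by MCMC through 'JAGS',
    and a contralateral delay activity (CDA) pipeline with rule-based
    artifact rejection, participant exclusion, windowed CDA amplitudes,
    and a set-size-by-stimulus-type additivity test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: JAGS (>= 4.0.0)
Imports:
    coda,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
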