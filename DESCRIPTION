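Package: glustress
Title: Stress-Induced Medial Prefrontal Glutamate Change and Daily-Life
    Expectation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for acute-stress magnetic resonance
    spectroscopy (MRS) studies of medial prefrontal glutamate. Computes
    percent change in creatine-normalized metabolites with scan-quality and
    outlier exclusions, calibrates the healthy-control linear law relating
    recent perceived stress (PSS) to glutamate change and scores each
    subject's maladaptive glutamate response (MGR) out of sample, filters
    and scores ecological momentary assessment (EMA) streams into
    expectation-inaccuracy summaries, and provides the supporting
    statistical battery (Spearman and partial correlations,
    repeated-measures ANOVA with Greenhouse-Geisser correction,
    hierarchical stepwise regression, Steiger's Z for dependent
    correlations, percentile bootstrap intervals, and test-retest ICC).
    A seeded synthetic-cohort generator emulates the study's group
    structure so the full pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
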