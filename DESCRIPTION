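Package: compadhere
Title: Adherence Scoring, Trial Statistics and Cost-Utility Analysis for
    Compression-Stocking Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested analysis pipeline for two-arm randomised trials of
    compression-stocking adherence interventions in chronic venous
    insufficiency. Implements the barrier-to-adherence questionnaire workflow
    (eligibility screen, severity-weighted top-three barrier selection,
    barrier-to-resource mapping), adherence-percentage scoring from
    possibly-ranged wear-time reports with mapping onto the modified VCSS Q10
    scale, barrier-resolution scoring, the trial's statistical comparisons
    (Mann-Whitney U with exact small-sample enumeration, Somers' D,
    baseline-adjusted regression, pooled effect size, noncentral-t and
    ARE-corrected sample-size planning), and a within-trial cost-utility
    analysis producing QALYs by area under the utility curve and an
    incremental cost-effectiveness ratio. Includes a synthetic-cohort
    generator emulating the pilot trial's data structure so every stage is
    testable without patient data.
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
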