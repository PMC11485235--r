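Package: mltcburden
Title: Illness-Death Markov Models for the Burden of Multiple Long-Term Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying the population burden of multiple long-term
    conditions (MLTCs) with discrete-time illness-death Markov models. Estimates
    age-specific monthly transition probabilities from person-month panel data,
    annualizes them by matrix power, propagates a birth cohort to obtain lifetime
    risk, median age at onset, years lived with and years of life lost to a
    condition combination, and community-scaled burden per 1,000 population.
    Includes cross-sectional prevalence analytics (point and joint prevalence,
    observed-minus-expected excess, condition-count distributions) and a
    synthetic cohort generator with analytic ground truth for validating the
    full estimation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
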