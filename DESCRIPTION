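Package: amlcure
Title: Net Survival and Statistical Cure Modelling for Acute Myeloid
    Leukaemia Registry Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for population-based net-survival analysis of acute
    myeloid leukaemia (AML) registry cohorts: expected mortality from
    period life tables, flexible parametric modelling of the cumulative
    excess mortality rate on the log-time spline scale with non-linear
    and time-dependent age effects, a flexible parametric cure model
    with a structurally enforced cure point, the cure-assumption
    decision rule, and derived indicators (cure proportion, conditional
    probability of cure, time to cure, median survival of the uncured).
    Includes a Pohar Perme net-survival estimator and interval-based
    excess-mortality-rate benchmarks, a registry-cohort simulator with
    closed-form mixture-cure truth, and a study pipeline with subtype
    recoding and death-count model tiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    survival,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
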