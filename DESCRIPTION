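Package: enrichest
Title: Point and Interval Estimation After Two-Stage Adaptive Enrichment
    with Time-to-Event Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation for two-stage adaptive enrichment trials with
    survival endpoints and biomarker-defined subpopulations. Computes
    log-rank score statistics and Fisher information at arbitrary calendar
    analysis times, stagewise estimates with the independent-increment
    decomposition, subpopulation selection rules with their truncation
    bounds, the uniformly minimum variance conditionally unbiased estimator
    (UMVCUE) of the log hazard ratio, naive multiplicity-split confidence
    intervals, and simultaneous confidence intervals by inverting closed
    tests built from Sidak-adjusted stagewise p-values combined with the
    weighted inverse-normal rule. A Weibull trial simulator reproduces
    design operating characteristics (selection probabilities, conditional
    bias and RMSE, simultaneous coverage, tail error).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
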