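Package: apcmort
Title: Age-Period-Cohort Modelling of Maternal Mortality with Restricted
    Cubic Splines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing maternal mortality from record-level death
    data and live-birth denominators. Tabulates deaths and exposure onto a
    one-year Lexis grid, fits an identifiable age-period-cohort Poisson rate
    model with restricted-cubic-spline effects (intercept and age slope in
    the age block, secular drift allocated to cohort, detrended period
    block, cohort curvature anchored at a reference cohort), and extracts
    age-specific rate curves and period/cohort rate-ratio curves with
    delta-method confidence bands. Also provides the equal-variance
    two-sample t machinery used to compare mean annual deaths between
    social-determinant and health-system groups, and a synthetic-data
    generator with known true effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
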