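Package: riskstrata
Title: Risk Stratification of Hospital Utilization from Claims-Based
    Condition Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating whether prospective actuarial risk scores
    can guide hospital-avoidance resource allocation. Calibrates expected
    performance-year inpatient admissions from base-year hierarchical
    condition category (HCC) flags by least squares, stratifies a held-out
    study population into expected-utilization quintiles and cumulative risk
    segments, and computes the segment-level statistics (predictive ratios,
    R-squared, capture fractions, zero-hospitalization fractions) that
    characterise how concentrated observed utilization is relative to
    predicted risk. Includes a synthetic Medicare-like claims generator
    (gamma-Poisson frailty counts over multiplicative condition-category
    rate effects) so the full pipeline is testable without restricted
    claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
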