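Package: hospprofile
Title: Equity-Aware Risk Adjustment and Hospital Outcome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hospital performance measurement with clinical risk
    adjustment: diagnosis-group-specific penalized logistic regression with
    restricted cubic splines and AICc-selected L2 penalties, internal-external
    (leave-one-hospital-out) cross-validation with calibration and
    discrimination metrics pooled by random-effects meta-analysis,
    risk-standardized outcome rates from a random-intercept logistic model
    with cluster-bootstrap intervals and below/average/above classification,
    and equity-gradient profiling of between-hospital differences in
    disability, homelessness, and neighborhood marginalization. Includes a
    synthetic admission-level cohort generator with known ground truth so the
    full pipeline is testable without access-restricted hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    metafor,
    yaml
Config/testthat/edition: 3
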