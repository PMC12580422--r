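Package: untwistr
Title: Scalar-on-Function Regression for Left-Ventricular Strain Curves in
    Hemodialysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Functional-data tools for speckle-tracking strain and rotation
    traces from hemodialysis cohorts: time-normalization of exported
    strain/rotation traces to a fixed 33-point cardiac-cycle grid,
    construction of left-ventricular torsion (apical minus basal rotation),
    penalized B-spline scalar-on-function regression with a patient-level
    random intercept for repeated intradialytic systolic blood pressure,
    a binomial-logit scalar-on-function model for mortality, pointwise and
    cluster-bootstrap confidence bands, global Wald tests for functional
    coefficients, curve-perturbation odds ratios, and a calibrated
    synthetic-cohort generator for validation and parameter-recovery
    experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    grDevices,
    tools,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
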