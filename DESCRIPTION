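Package: ferriscope
Title: Multi-Echo T2* Relaxometry and Iron-Overload Cohort Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies tissue iron from multi-echo gradient-echo magnitude
    MRI via mono-exponential T2* relaxometry (constant-offset and truncation
    decay models), maps the left-ventricular myocardium onto the 16-segment
    AHA model, computes Simpson's-rule biventricular volumes, ejection
    fraction and body-surface-area-indexed mass, applies clinical thresholds
    for vitamin-D status and organ iron overload, and provides the cohort
    statistics used in iron-overload epidemiology: normality-routed group
    comparisons with Bonferroni pairs, Woolf/logistic odds ratios, forward
    stepwise regression with collinearity diagnostics, and ROC analysis with
    Youden-index cut-offs. Includes seeded generators for multi-echo phantoms
    with Rician noise and for copula-based synthetic patient cohorts, so the
    whole chain is testable without protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    nortest,
    pracma,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
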