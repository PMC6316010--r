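Package: vocdx
Title: Diagnostic Classification of Urinary Volatile Organic Compounds from
    FAIMS and Electronic-Nose Sensor Arrays
Version: 0.1.0
Authors@R:
    person("VOC", "Analytics", email = "vocdx@example.org", role = c("aut", "cre"))
Description: A leakage-safe analysis pipeline for two-instrument urinary
    volatile organic compound (VOC) diagnostics. Ingests field-asymmetric ion
    mobility spectrometry (FAIMS) dispersion matrices and metal-oxide
    electronic-nose sensor traces, extracts 2D Daubechies-4 wavelet and
    sensor-response features, performs fold-wise Wilcoxon rank-sum ranking or
    Boruta shadow-feature selection inside cross-validation, trains four
    classifier families (sparse logistic regression, random forest, Gaussian
    process, support vector machine), and reports full ROC diagnostics with
    stratified bootstrap confidence intervals and sample-age stratification.
    Includes a synthetic cohort generator emulating class-dependent analyte
    signal, storage-age signal decay, and measurement noise for both
    instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    optparse,
    quadprog,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
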