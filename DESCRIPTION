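Package: uritox
Title: Urinary Toxic-Metal Panels and Autism Severity: Censored-Data
    Preprocessing, Kernel Discriminant Classification, and
    Cross-Validated Kernel Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for case-control biomonitoring studies that
    relate creatinine-normalized urinary toxic-metal panels to autism spectrum
    disorder (ASD) diagnosis and symptom severity. Provides left-censored
    detection-limit substitution, univariate group summaries and Hotelling's
    T-squared, linear and Gaussian-kernel Fisher discriminant classification
    with kernel-density score models and leave-one-out Type I/II error
    tradeoffs, linear and kernel partial least squares regression with
    exhaustive metal-subset search under leave-one-out cross-validated
    R-squared, principal component analysis of severity instruments, and a
    calibrated synthetic-cohort generator so that every stage is testable
    without access to the original study files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
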