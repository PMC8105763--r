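Package: vdra
Title: Distributed Regression Analysis for Vertically Partitioned Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Privacy-protecting regression analysis when the covariates of a
    single patient cohort are split column-wise across two or more
    data-contributing sites. Sites exchange only summary-level intermediate
    statistics (site-local Gram blocks and cross-site blocks obtained with a
    sequential projection-masking protocol) through a simulated, trust-governed
    file-transfer network; an analysis center assembles the global covariance
    matrix and fits linear models by normal equations and logistic models by
    distributed iteratively reweighted least squares. Includes a synthetic
    cohort generator with known ground truth, pooled patient-level oracle fits
    for verification, divide-and-conquer row blocking, and transfer metrics
    comparing hub-and-spoke with direct site-to-site routing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
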