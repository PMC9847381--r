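Package: polarlasso
Title: Group-Penalized Regression with Multi-Level Polar Coefficient Charts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits lasso, group lasso, and sparse group lasso regularization
    paths for Gaussian and binomial responses by cyclic block proximal
    descent, with k-fold cross-validation and the min / one-standard-error
    tuning rules. Summarizes a fitted coefficient vector as a multi-level
    polar chart: one sector per selected predictor group (radius
    proportional to the group's coefficient impact, color encoding group
    size) and one point per selected variable (radial position giving the
    relative coefficient magnitude, symbol giving its sign), rendered to
    deterministic SVG, PNG, or self-contained interactive HTML. Includes a
    seeded generator of grouped genomic-style synthetic data with known
    sparse truth, readers for tabular design matrices and coefficient
    tables, a JSON layout interchange format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
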