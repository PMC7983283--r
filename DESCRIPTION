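Package: cytoreg
Title: Conditional Differential Expression for Flow and Mass Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conditional (multiple-regression) differential expression
    analysis of single-cell flow and mass cytometry marker tables.
    Two complementary strategies are provided: a logistic generalized
    linear model with a two-level (donor, then cell) cluster bootstrap
    and percentile-interval inference, and a logistic generalized
    linear mixed model with donor-level random coefficients fitted by
    a method-of-moments procedure with asymptotic-normal inference.
    Includes a hierarchical Poisson log-normal simulator with known
    ground truth, Benjamini-Hochberg and Benjamini-Yekutieli false
    discovery rate control, a cross-analysis p-value combiner, and a
    simulation-study harness for observed FDR and power over scenario
    grids and donor sample-size scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
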