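Package: hba1cval
Title: Method Validation Statistics for HbA1c Assay Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for validating a candidate HbA1c assay
    against a comparative (reference) method, following the CLSI EP05/EP09/EP21
    family of protocols. Implements Passing-Bablok regression with rank-based
    confidence intervals and the Cusum linearity test, Bland-Altman difference
    analysis with nonparametric limits of agreement judged against allowable
    total error, Lin's concordance correlation coefficient, mountain-plot
    point generation, bootstrap estimation of bias at medical decision limits,
    nested-design precision analysis (repeatability, between-day and
    within-laboratory coefficients of variation), and a probability model for
    the risk of clinically misinterpreting HbA1c results given analytical
    bias, imprecision and biological variation. A synthetic-data module
    generates paired-method datasets and replicate precision designs with the
    statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
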