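Package: dietcross
Title: QTL Mapping and Trait-Network Analysis for Diet-Response F2 Intercrosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-marker genome scans, permutation-based genome-wide
    significance thresholds, 1.5-LOD support intervals, conditioned
    (pleiotropy) scans, residual-regression causal-network inference, and
    observed-variable path models for F2 intercross studies of diet
    response, together with a synthetic B6xFVB-style cross simulator that
    generates genotypes, phenotypes and parental/F1 cohorts with
    sex- and diet-modulated QTL effects, epistasis and pleiotropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
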