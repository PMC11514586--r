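Package: grindqsar
Title: Alignment-Independent 3D-QSAR with GRIND Descriptors and PLS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds alignment-independent 3D-QSAR models for small-molecule
    activity data. Reads V2000 SDF structures, assigns Gasteiger-style partial
    charges and pharmacophore atom types, evaluates molecular interaction
    fields for hydrophobic (DRY), hydrogen-bond acceptor (O), hydrogen-bond
    donor (N1) and shape (TIP) probes on a regular grid, extracts favourable
    field nodes and encodes them as distance-binned auto- and cross-correlogram
    (GRIND) descriptors. Models are fitted by NIPALS partial least squares with
    leave-one-out cross-validation, fractional-factorial-design variable
    selection, stratified train/test splitting, full internal and external
    validation (Q2, R2pred, rm2 metrics) and a leverage-based applicability
    domain with Williams-plot output. Includes a synthetic structure-activity
    data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
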