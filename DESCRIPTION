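Package: dcvfusion
Title: Detection and Quantification of Dense-Core Vesicle Fusion Events in
    pHluorin Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects single dense-core vesicle (DCV) fusion events in
    pHluorin time-lapse fluorescence movies using a temporal
    standard-deviation projection of the stimulation window, prominence-based
    spot calling and greedy non-redundant ROI placement. Estimates the total
    pHluorin-labeled vesicle pool from the NH4Cl dequenching response with
    raw, fused-corrected and puncta-corrected estimators, localizes events
    relative to a synapse mask built by morphological top-hat filtering and
    Triangle auto-thresholding, and emits per-event and per-cell
    quantification tables. A synthetic-movie generator provides exact ground
    truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
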