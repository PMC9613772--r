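Package: ktrfate
Title: Linking Single-Cell ERK/Akt Kinase Translocation Reporter Dynamics to Cell Division Fate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline that connects single-cell kinase
    translocation reporter (KTR) dynamics to cell-division outcomes in
    time-lapse fluorescence movies. Provides per-frame quantification of
    the cytoplasm-to-nucleus (C/N) fluorescence ratio via nuclear
    segmentation and a perinuclear "cytoring", frame-to-frame cell
    tracking by optimal centroid assignment, automatic division detection
    from the transient steep C/N drop at mitosis, windowed-median feature
    extraction, and the downstream statistics: right-tailed rank-sum
    comparison of dividing vs non-dividing cells, logistic regression of
    division fate on ERK/Akt medians, pooled ERK-Akt Pearson correlation
    with multivariate-normal resampling bands, and a perturbation-based
    two-node crosstalk assessment. A synthetic-data module simulates
    ground-truth activity dynamics and renders movies with division
    events so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
LinkingTo:
    Rcpp
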