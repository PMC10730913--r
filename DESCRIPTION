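Package: punctate
Title: Decoding, Segmentation and Integration for Targeted In Situ Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a targeted in situ spatial transcriptomics
    workflow. Builds combinatorial fluorescence codebooks with negative-control
    classes, simulates ground-truth tissues and cycle-by-channel optical signals,
    detects puncta by sub-pixel Gaussian fitting, decodes puncta to transcripts by
    maximum likelihood with Phred-style quality scores calibrated against
    negative-control codewords, assigns transcripts to cells by distance-capped
    nucleus expansion, and integrates the resulting cell-feature matrices with
    single-cell references (kNN label transfer), spot-array pseudobulk
    (hexagonal-grid interpolation) and landmark-based RANSAC registration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
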