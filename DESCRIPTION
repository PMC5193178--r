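Package: fretarray
Title: Analysis of FRET Biosensor Cell-Microarray Time-Lapse Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for ratiometric FRET biosensor imaging on cell
    microarrays: a synthetic-data generator for ground-truth-annotated
    spot layouts, single-cell activity trajectories and rendered
    multi-channel image stacks; image quantification (Triangle background
    subtraction, median filtering, Huang fuzzy masking, nucleus-seeded
    watershed segmentation, ROI ratiometry, expression gating, cell
    tracking); single-cell trajectory normalization and condition
    summaries; dynamic-signature clustering (hierarchical fingerprints
    and K-means trajectory patterns); condition-level PCA with coverage
    ellipses; and a stimulus-interaction (synergy/antagonism) score with
    error propagation, significance testing and multiple-testing
    correction.
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
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite,
    matrixStats,
    tiff,
    EBImage,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
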