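Package: octexture
Title: Retinal Layer Texture Analysis and Classification for OCT Macular Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct per-layer mean-value fundus (MVF) images from
    optical coherence tomography (OCT) macular cube volumes and layer boundary
    surfaces, extract 86 texture features per retinal layer (80 quadrant-aggregated
    grey-level co-occurrence matrix features plus 6 dual-tree complex wavelet
    directional-variance features), and discriminate healthy-control, Alzheimer's
    and Parkinson's eyes with a voted bank of binary radial-basis-function support
    vector machines under repeated k-fold cross-validation. Includes a synthetic
    OCT cohort generator with class-conditional layer texture, ETDRS-sector
    thickness analysis, and the associated performance, agreement and calibration
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
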