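Package: slideqc
Title: Two-Layer Quality Assessment for Whole-Slide Histopathology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quality control of whole-slide H&E images. A
    multi-label residual convolutional network scores 256x256 tissue
    patches at 5x magnification for diagnostic usability and common
    artefacts (focus, staining, tissue folding, ink/dirt/bubbles and other
    obscuring material), trained by Huber-loss regression. Patch scores
    are assembled into per-category quality overlays whose summary
    statistics feed linear models of slide-level usability, focus and
    staining scores (0-10 scale), with re-scan/re-stain intervention
    recommendations. Includes a synthetic H&E slide generator with
    ground-truth artefact labels, hand-crafted focus/contrast feature
    banks with random-forest baselines for comparison, tissue
    segmentation and tiling, heatmap rendering and cohort-level
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    pROC,
    png,
    randomForest,
    stats,
    tiff,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
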