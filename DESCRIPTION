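Package: wsitriage
Title: Patch-Based Triage of Cervical Biopsy Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A patch-based pipeline for slide-level triage of haematoxylin
    and eosin stained cervical biopsy whole-slide images. Provides pyramidal
    slide access, grid patch extraction with tissue detection, max-severity
    patch labelling from polygon annotations, a trainable patch classifier
    with focal loss for class imbalance, per-category probability heatmaps,
    two heatmap feature schemes (a 90-dimensional random-forest scheme and a
    refined gradient-boosting scheme), slide-level classifiers tuned for
    malignant sensitivity, inter-observer agreement statistics (Cohen's
    kappa), and a deterministic synthetic cohort generator so the whole
    pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    xgboost,
    ranger,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv
Config/testthat/edition: 3
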