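Package: trapaug
Title: Bounding-Box-Aware Data Augmentation and Detection Evaluation for
    Insect Trap Images
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A toolchain for enriching small annotated datasets of sticky-paper
    insect trap photographs for object-detector training. Provides six
    parameterized augmentation operators (gamma correction, brightness-contrast
    adjustment, multiplicative Gaussian noise, translation, rotation, and
    four-image mosaic composition), a modified mosaic operator that
    stochastically applies photometric transforms to the mosaic sub-images, a
    deterministic dataset-enrichment orchestrator with full provenance
    tracking, a mean-average-precision (mAP50, mAP50-95) detection evaluator,
    and a synthetic generator of trap-like annotated images for testing
    detection pipelines without field data. Annotations use the YOLO sidecar
    text format with normalized center-size boxes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, png, jsonlite
Suggests: jpeg, testthat (>= 3.0.0), withr, knitr, rmarkdown, optparse
Config/testthat/edition: 3
VignetteBuilder: knitr
biocViews: Software, Preprocessing, Classification
RoxygenNote: 7.3.3
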