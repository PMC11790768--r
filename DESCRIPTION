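Package: ribfrax
Title: Patch-Based Detection and Hierarchical Classification of Rib
    Fractures on Unfolded Rib-Cage Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and classifying rib-fracture types on 2-D
    "unfolded rib cage" images: seeded synthetic image generation with
    renderable fracture motifs, preprocessing (crop and pixel-area-relation
    upscaling), 99x99 patch mining with cardinal-shift augmentation and
    sliding-window negative sampling, leakage-safe grouped train/test and
    cross-validation splits, a convolutional patch classifier trained with a
    two-phase freeze/unfreeze schedule (early stopping and
    learning-rate-on-plateau), formula-defined aggregation of patch
    predictions to the fracture level, and evaluation on three levels of
    hierarchical taxonomy with absolute and row-normalised confusion
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
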