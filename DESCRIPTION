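Package: pestwatch
Title: Occlusion-Robust Pest Detection with Test-Time Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training and deployment tools for small-object pest detectors that
    must survive occlusion and shifting field conditions. Implements a
    dual-branch training framework in which a clean-input main detector and an
    occluded-input auxiliary detector exchange features through learned
    sigmoid gates while two convolutional autoencoders inpaint
    occlusion-damaged feature maps, and a streaming test-time adaptation
    strategy that scores detector parameters by diagonal Fisher information,
    partitions them into domain-sensitive and domain-invariant sets, and
    applies isolated student gradient steps and isolated teacher
    exponential-moving-average updates driven by augmented-view certainty
    matrices. Ships a synthetic pest-scene generator with nine environmental
    corruptions, YOLO-txt and COCO-JSON annotation I/O, VOC-style detection
    metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
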