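Package: attnguide
Title: Attention-Guided Lesion Classification for Panoramic Radiographs
Version: 0.1.0
Authors@R: person("Maintainer", "attnguide", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Training and evaluation toolkit for attention-guided diagnosis of
    jaw-bone lesions on panoramic radiographs. A convolutional classifier's
    Grad-CAM attention is supervised on a configurable fraction of
    location-labeled samples through a differentiable soft-mask IoU loss.
    Includes radiograph-specific augmentations (intensity jitter, joint
    horizontal flip, and a trapezoid projective transform applied jointly to
    image and mask), a stratified training pipeline with cosine-annealed SGD
    and early stopping, macro-averaged one-vs-rest metrics, and a synthetic
    phantom-radiograph generator with ground-truth lesion masks so the whole
    stack is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
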