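Package: scintnet
Title: Lightweight Multi-Scale Convolutional Networks for Bone Scintigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-class hotspot classification in planar whole-body
    bone scintigrams (normal, malignant, degenerative). Provides a seeded
    synthetic scintigram phantom generator with focal-metastasis, degenerative
    joint and artifact uptake models under Poisson counting noise; an image
    curation chain (grayscale conversion, aspect-preserving resize with zero
    padding, fixed-scale normalization, rotation/rescale augmentation); a
    declarative builder for the LB-FCN light architecture (depthwise separable
    convolutions, four multi-scale blocks, three look-behind residual
    connections, global-average-pooling softmax head) with exact trainable
    parameter accounting; a self-contained single-precision training engine
    (Adam, batch normalization, online augmentation); FLOP and parameter
    complexity audits against six reference architectures; and a 10-fold
    stratified cross-validation evaluation protocol with one-vs-rest
    per-class metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
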