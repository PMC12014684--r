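Package: orcharddet
Title: Lightweight Anchor-Free Fruit Detection with Depthwise-Separable
    Inverted Bottleneck Networks
Version: 0.1.0
Authors@R:
    person("Orchard", "Detection Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A single-stage, anchor-free object detector for round fruit in
    orchard imagery, built from depthwise-separable inverted bottleneck
    residual blocks, ghost convolutions, and a bidirectional feature pyramid
    neck with learnable fusion weights.  Includes analytic FLOP and parameter
    accounting for every convolution class, COCO-style detection metrics
    (precision, recall, AP, mAP50, mAP50-95), YOLO-format dataset input and
    output with deterministic splitting and label-preserving augmentation, a
    reproducible synthetic orchard-scene generator (lighting variation,
    branch or leaf occlusion, fruit stacking), and a CPU training loop with
    SGD, warm-up, and a task-aligned detection loss.  All tensor operations
    run on plain R arrays backed by a minimal reverse-mode autodiff tape
    with C++ convolution kernels, so the full pipeline is testable on one
    CPU without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
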