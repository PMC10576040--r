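Package: mountdetect
Title: Lightweight Detection of Cattle Mounting Behavior in Dense Barn Scenes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained, CPU-only implementation of a lightweight
    one-stage detector for recognizing cow mounting behavior (the visual sign
    of estrus) in crowded barn surveillance images. Provides the inverted
    residual building blocks (Fused-MBConv, MBConv, squeeze-and-excitation),
    Ghost convolution and Ghost bottlenecks with their analytic parameter and
    FLOP accounting, efficient channel attention (ECA), a 13-stage lightweight
    backbone with exact per-layer trainable-parameter auditing, an FPN+PAN
    neck with Ghost/ECA feature-enhancement modules, anchor-based multi-scale
    detection heads, mosaic/photometric/flip augmentation, YOLO-txt and
    COCO-JSON dataset IO, a synthetic barn-scene generator, an SGD training
    loop with cosine-annealed learning rate and label smoothing, and a
    precision/recall/AP/mAP evaluation stack with non-maximum suppression.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
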