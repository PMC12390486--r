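Package: prunekd
Title: Sensitivity-Guided Channel Pruning and Collaborative Distillation for Compact Pest Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for compressing small single-stage object detectors used in
    field-pest monitoring. Implements BatchNorm scaling-factor (gamma) channel
    importance scoring with L1 sparsity training, layer-wise pruning-sensitivity
    reports, global-threshold structured channel pruning with coupled-channel
    surgery, and a collaborative distillation loss that combines mask-free
    generative feature reconstruction with an L2 logit term computed through the
    frozen teacher detection head. Ships a synthetic multi-class pest-scene
    generator with YOLO-format input/output and stratified splitting, a small
    trainable anchor-free detector (MiniDet) with a minimal CPU training engine,
    a YOLOv8s accounting graph for parameter/FLOP bookkeeping, mean-average-
    precision evaluation, and an end-to-end compression pipeline with ablation
    grids and reports.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
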