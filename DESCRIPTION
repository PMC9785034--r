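Package: pestdetect
Title: Single-Stage Pest Detection with Extended Cross-Stage-Partial
    Backbone and Selective-Kernel Channel Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A single-stage convolutional object detector for small
    agricultural pests (ants, grasshoppers, palm weevils, shield bugs,
    wasps) in field imagery. The network extends the shallow stage of a
    cross-stage-partial (CSP) backbone, inserts a modified selective-kernel
    channel-attention block in each CSP module, and detects on four feature
    scales (strides 4 to 32) so that small, low-contrast objects reach a
    high-resolution head. Includes YOLO-format label input/output and
    dataset splitting, a deterministic synthetic pest-scene generator for
    end-to-end testing without image downloads, the composite CIoU / class /
    objectness training loss with hand-derived gradients, an SGD training
    loop with best-mAP checkpointing, precision/recall/AP/mAP and
    background-aware confusion-matrix evaluation, and analytic parameter,
    layer and FLOP accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
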