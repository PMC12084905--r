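Package: wsigt
Title: Weakly Supervised Graph-Transformer Classification of Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for weakly supervised classification of whole-slide
    histology images with slide-level labels only. Slides are tiled into
    patches at a target magnification with a tissue-content filter, patches
    are embedded with a contrastive (SimCLR-style) self-supervised encoder
    into 512-dimensional normalized features, per-slide spatial graphs with
    8-neighbour adjacency are built over the surviving patch grid, and a
    graph-transformer head (grid max-pooling, a graph-convolution block to
    128 dimensions, and a six-block transformer with a slide-level
    aggregation token) produces slide-class probabilities. Includes
    stratified k-fold fine-tuning with a frozen encoder, a from-scratch
    ablation arm, fold-ensemble inference, a full evaluation stack
    (confusion matrices, per-class sensitivity and specificity, balanced
    accuracy, one-vs-rest ROC and AUC, fold aggregation), and a synthetic
    toy-slide generator so the entire pipeline is testable on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    igraph,
    data.table,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
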