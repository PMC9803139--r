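Package: glandflow
Title: Gastric Gland Segmentation, Classification and Mucosa Quantification
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end digital-pathology workflow for gastric biopsies:
    two-branch convolutional segmentation of glands into background, lumen and
    edge classes with overlap-tile whole-slide inference and instance
    post-processing; gland classification into normal versus intestinal
    metaplasia with a feature-pyramid multi-scale deformable-attention
    encoder trained with focal loss and an optional mean-teacher scheme;
    weakly supervised tissue segmentation by k-means seeding, exact graph-cut
    energy minimization and a U-Net; object-level detection and segmentation
    metrics (object Dice, object Hausdorff, detection F1); and Sydney-system
    biopsy features with group statistics. Includes a synthetic gland-phantom
    generator with exact ground truth so the whole pipeline is trainable and
    testable on commodity CPUs, plus a small reverse-mode autodiff engine
    with C++ convolution kernels that powers the networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    igraph,
    png,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
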