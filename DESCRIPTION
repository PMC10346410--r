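Package: branchmorph
Title: Branch Phenotyping from Segmented Tree Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for measuring tree-branch phenotypes from RGB images.
    Provides an attention-augmented UNet semantic segmenter (VGG16-style
    encoder with squeeze-and-excitation channel attention and a parallel
    channel/spatial residual attention module) that labels pixels as
    background, trunk or branch; Zhang-Suen two-subiteration skeleton
    thinning; skeleton-based morphometry that reports per-branch length
    (skeleton pixel count) and inclination angle (total-least-squares line
    fit); segmentation and agreement metrics (MIoU, precision, recall, F1,
    R-squared, RMSE); and a synthetic tree-scene generator with exact
    ground truth for validation. The neural network is a self-contained
    CPU implementation (im2col convolutions via 'RcppArmadillo') with
    Adam, cosine learning-rate decay and two-phase freeze/unfreeze
    fine-tuning.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
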