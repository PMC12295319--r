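Package: patchfuse
Title: Attention-Weighted Decision Fusion for Histopathology Patch Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains two-branch convolutional classifiers for
    hematoxylin-and-eosin histopathology image patches. Each branch applies a
    learned single-channel spatial-attention mask to its convolutional feature
    map before global average pooling and a dense classification head; the two
    branch predictions are then combined by instance-specific fusion weights
    produced by a softmax layer over the concatenated predictions and pooled
    features. Includes exact parameter accounting for standard ImageNet
    backbones, the full training protocol (Adam, step learning-rate decay,
    early stopping with best-weight restoration, partial backbone freezing),
    multiclass evaluation metrics (per-class one-vs-rest rates, Matthews
    correlation, Cohen's kappa), Grad-CAM heatmaps with overlays, deterministic
    train/test and K-fold planning, a synthetic H&E-palette texture generator
    for fully offline testing, and an experiment harness with paired
    statistical comparison of models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
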