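Package: squeezevit
Title: Lightweight Hybrid CNN/Transformer Classifier for Chest Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements SqueezeViT, a lightweight hybrid convolutional /
    vision-transformer classifier for multi-label chest-radiograph images.
    Provides the squeeze-and-excite Fire module and Fire Block, the
    Translution Block (patch tokenization plus scaled dot-product attention
    with Fire-module channel squeezing), analytic parameter and
    multiply-accumulate (MAC) accounting with reduction percentages against
    published baseline budgets, the training recipe (binary cross-entropy,
    Adam, train-from-scratch) with class-wise AUROC, F1 and bootstrap
    confidence-interval evaluation, an NIH ChestX-ray14-style CSV label
    manifest reader, and a seed-deterministic synthetic multi-label image
    generator with planted class-specific patterns so the whole pipeline is
    exercisable without external data. A command-line interface exposes
    synth, train, eval, profile and ablate subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tibble,
    ggplot2,
    generics,
    rlang,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jpeg
Config/testthat/edition: 3
RoxygenNote: 7.3.3
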