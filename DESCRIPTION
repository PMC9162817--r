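Package: copnet
Title: Multi-Scale Residual 1D Convolutional Networks for Balance
    Control Classification from Center-of-Pressure Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating human balance-control level (high-level
    athlete, medium-level athlete, normal person) from two-channel
    center-of-pressure (COP) recordings sampled on a force platform.
    Provides a windowing and task-assembly layer for stabilometric time
    series, a seeded Ornstein-Uhlenbeck postural-sway simulator for fully
    reproducible experiments, a compact self-contained 1D convolutional
    network engine with residual (shortcut) connections and multi-scale
    feature extraction (parallel kernel sizes 3/10/20), four reference
    architectures for comparison, a mini-batch Adam training loop with
    repeat-averaged evaluation, ablation sweeps over filter counts and
    training-set sizes, and t-SNE visualization of learned features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    cluster,
    ggplot2,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
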