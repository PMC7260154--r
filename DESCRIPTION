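Package: vesseltrace
Title: Per-Frame Vessel Diameter Estimation from Ultrasound Video with a
    Convolutional GRU and a Periodicity-Regularized Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the pulsating diameter of a fetal abdominal aorta (or
    any horizontal vessel) frame by frame from gray-scale ultrasound video. A
    shallow convolutional encoder feeds a convolutional gated recurrent unit
    whose spatial state is regressed to one diameter per frame; training
    minimizes mean squared error plus a CyclicLoss penalty that ties
    predictions one cardiac period apart. Ships a fully specified synthetic
    pulsatile-vessel sequence simulator (sinusoidal lumen, anti-phase wall
    thickness, three-level gray rendering, additive and intensity-proportional
    noise) so the whole method is trainable and testable without external
    data, plus evaluation metrics (MSE, relative error, MAE, R squared,
    Kolmogorov-Smirnov model comparison) and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    tiff,
    EBImage,
    withr
Config/testthat/edition: 3
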