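Package: fishcut
Title: Fish Head-Cut Position Identification from Line-Laser Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the ideal head-cut position of spindle-shaped fish from
    line-laser triangulation scans of the upper body surface. Provides a
    parametric synthetic fish-scan simulator, threshold segmentation of belt
    and body points, Kalman and median profile denoising, ventral-dorsal
    demarcation-line extraction, correlation-matrix principal component
    reduction, and three head-length regressors built from first principles:
    an RBF-kernel least-squares support vector machine with particle-swarm
    hyperparameter search, a particle-swarm-initialized back-propagation
    network, and a single-layer LSTM. Includes train/test evaluation with
    R2, RMSE, MAE and residual predictive deviation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
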