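Package: esicnn
Title: EEG Source Imaging with a Shallow Convolutional Network on a Toy Spherical Head Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates event-related scalp potentials from distributed cortical
    dipole clusters on an analytic spherical head model, trains a shallow
    convolutional neural network to map single-time-point scalp topographies to
    distributed source vectors, and benchmarks it against minimum-norm and
    eLORETA-style inverse solvers. Includes region-growing source simulation,
    a weighted Hausdorff training loss, Brent amplitude rescaling, and an
    evaluation suite with two-sided ROC areas, localization error, and
    ghost/missed-source bookkeeping. Simulation and inversion use deliberately
    different forward models to avoid the inverse crime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    tibble,
    dplyr,
    generics,
    ggplot2,
    rlang,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
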