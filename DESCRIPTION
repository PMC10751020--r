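Package: smoothash
Title: Multiscale Signal Denoising by Empirical Bayes Adaptive Shrinkage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Smoothing of one-dimensional signals by empirical Bayes
    shrinkage in a multiscale domain. Provides an adaptive-shrinkage
    solver for the heteroskedastic normal-means problem with a
    zero-centered scale-mixture-of-normals prior, decimated and
    translation-invariant wavelet transforms (Haar and Symmlet8) with
    per-coefficient variance propagation, mean and variance estimation
    for heteroskedastic Gaussian data (including joint two-cycle
    estimation), and intensity estimation for Poisson count tracks via
    a recursive-sum multiscale decomposition with shrinkage of binomial
    log-odds. Includes a simulation module with standard wavelet test
    functions, benchmarking utilities, and a command-line interface
    reading TSV/CSV signals and bedGraph count tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    optparse,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
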