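Package: bimqp
Title: Quadratic-Programming Born Iterative Method for 2D Microwave
    Breast Imaging with Convolutional Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-dimensional quantitative microwave breast
    imaging. Implements a pulse-basis method-of-moments forward solver
    for the electric-field integral equation, the Born iterative method
    with each contrast update posed as a Tikhonov-regularized quadratic
    program over multiple sources and frequencies, and a convolutional
    encoder-decoder network that refines the iterative permittivity
    reconstructions. Includes generators for the concentric-circle
    validation phantom and for layered synthetic breast phantoms of four
    density classes with implanted tumors, plus Frobenius-norm error
    metrics and a permittivity-to-conductivity regression model.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
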