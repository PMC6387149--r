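Package: oculodyn
Title: Dynamical and Fractal Analysis of Eye-Movement Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the nonlinear dynamics and self-similarity
    of fixational eye-movement recordings. Provides a synthetic eye-movement
    generator (saccadic latency, raised-cosine saccades, fractional-Gaussian
    drift, tremor, microsaccades, optional chaotic component), a position filter
    bank (running median, Savitzky-Golay, undecimated Daubechies wavelet
    denoising), two-point velocity differentiation with fixation segmentation,
    phase-space reconstruction by delay embedding (mutual-information delay,
    false-nearest-neighbour dimension), largest-Lyapunov-exponent estimation by
    the nearest-neighbour divergence method, detrended fluctuation analysis with
    polynomial and bridge detrending, and group-level summary statistics and
    significance tests.
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
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
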