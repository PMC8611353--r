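Package: ebtgrowth
Title: Bayesian Calibration of a Non-Local Proliferation Model for Spheroid Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and calibrating a non-local logistic model of
    cell proliferation in multicellular spheroids. The radially reduced model is
    solved with an escalator boxcar train (EBT) particle scheme with fixed
    particle locations and mass ODEs integrated by an adaptive Dormand-Prince
    Runge-Kutta method implemented in C++. Colony radii are read off the
    particle measure as 95% mass quantiles, observations carry multiplicative
    lognormal error, and the four model parameters (proliferation rate, kernel
    radius, observation noise, initial colony radius) are inferred by
    random-walk Metropolis-Hastings on the log scale with lognormal priors.
    Includes a synthetic growth-curve generator with presets for the L-5178Y,
    V-79 and B-16 cell lines, an exact bounded-Lipschitz (flat) norm on
    discrete measures, a 3D FFT reference solver, and convergence and
    posterior-stability harnesses.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
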