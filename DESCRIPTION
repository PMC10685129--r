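Package: dhsicts
Title: Kernel Tests of Joint Independence for Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical tests of joint independence for d co-observed time
    series based on the d-variable Hilbert-Schmidt independence criterion
    (dHSIC). Two resampling schemes generate the null distribution: a
    circular-shifting bootstrap for stationary series observed as a single
    realization, and a cross-realization permutation test for (possibly
    non-stationary) series observed as multiple independent realizations.
    Recursive subset scanning flags emergent higher-order dependencies and
    maps them onto dependency hypergraphs. Includes generators for benchmark
    autoregressive, trend, parity-gate and frequency-mixing systems, wavelet
    instantaneous-phase extraction, and a simulation harness for power and
    type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
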