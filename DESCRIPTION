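Package: lipbeta
Title: Drift-Diffusion Choice Modelling and Matching-Pursuit Analysis of
    Transient Beta Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing routed perceptual decisions in primate
    parietal cortex. Implements a bounded drift-diffusion model of choice
    and response time with misrouting extensions (wrong-patch mixture and
    incomplete suppression of the uncued stimulus), fitted by maximum
    likelihood through a Crank-Nicolson solution of the Fokker-Planck
    equation; Matching-Pursuit decomposition of peristimulus firing rates
    and local field potentials into Gabor atoms with Wigner-Ville band
    power statistics for transient low-beta (12-20 Hz) oscillations; the
    accompanying resampling tests (subsample bootstrap, permutation and
    block tests, preferred/nonpreferred ratio analysis); spike-field phase
    alignment; and seeded synthetic-data generators (behaviour, Poisson
    spike trains, LFP) so the full pipeline runs without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
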