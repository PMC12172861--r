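Package: ftrsgt
Title: Behavioral, Bayesian and Psychophysiological Analysis of the
    Finger-Tapping Random-Sequence-Generation Task
Version: 0.1.0
Authors@R:
    person("FT-RSGT", "Maintainers", email = "maintainers@ftrsgt.dev",
           role = c("aut", "cre"))
Description: Tools for experience-sampling studies of mind wandering with
    the finger-tapping random-sequence-generation task (FT-RSGT).
    Implements approximate entropy and tap-timing variability over
    pre-probe windows, a hierarchical Bayesian ordered-probit regression
    of thought-probe responses with nested random intercepts (Gibbs
    sampler with collapsed cutpoint updates, highest-density intervals,
    evidence ratios, Bayes R2), a simulation-based power analysis with a
    parametric power-surface approximation, a deconvolution-based
    tonic/phasic decomposition of pupillometry traces (trough-anchored
    spline envelope plus non-negative least squares over
    pupil-response-function regressors), EEG spectral and event-related
    features (oddball mismatch negativity, occipital alpha, midfrontal
    theta), and a synthetic-data generator with known ground truth so
    the whole pipeline is testable end to end without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
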