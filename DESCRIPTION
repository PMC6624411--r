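Package: netstates
Title: Trial-Resolved Neural Network States via Autoregressive Hidden
    Markov Models
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers trial-by-trial latent network states and directed
    inter-regional information flow from multivariate neural time series
    (e.g., electrocorticographic broadband gamma power). Each latent state
    is a multivariate autoregressive process with its own coefficient
    tensor, innovation covariance and bias; states switch according to a
    hidden Markov chain with a sticky self-transition prior. The package
    provides Baum-Welch expectation-maximization with exact forward-backward
    smoothing, Viterbi decoding, BIC/held-out model selection, windowed
    adaptive MVAR estimation with k-means initialization, partial directed
    coherence connectivity summaries with a cross-state dissimilarity score,
    state-sequence behavioral analyses (cumulative state durations,
    language-state termination, Fisher-transform correlation tests),
    residual whiteness diagnostics, and a calibrated switching-AR simulator
    with known ground truth for robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'TrialTensor.R'
    'ARHMMParams.R'
    'utils.R'
    'RcppExports.R'
    'arhmm.R'
    'amvar.R'
    'simdata.R'
    'preproc.R'
    'connectivity.R'
    'stateseq.R'
    'diagnostics.R'
    'io.R'
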