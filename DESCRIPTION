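Package: tdehmm
Title: Time-Delay Embedded Hidden Markov Models for Dynamic Spectral Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and characterisation of recurrent spectral-connectivity
    states in multichannel electrophysiological recordings. Implements the
    full analysis chain: leakage-corrected preprocessing of region time
    series, time-delay embedding with PCA reduction, a variational-Bayes
    Gaussian hidden Markov model with zero mean and full state covariances,
    state-resolved multitaper power and coherence spectra, data-driven
    frequency modes by non-negative matrix factorisation, mixture-model
    thresholding of coherence networks, Riemannian matching of states across
    independently fitted models, and dwell-time statistics with factorial
    comparisons. Includes a Markov-switching oscillatory cohort simulator
    with closed-form coherence ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
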