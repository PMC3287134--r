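Package: teflow
Title: Transfer Entropy Analysis of Directed Interactions in Trial-Based Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nearest-neighbour (Kraskov-Stoegbauer-Grassberger) estimation of
    transfer entropy and mutual information for trial-based multichannel
    analog recordings such as LFP, EEG and MEG. Includes data-driven
    optimisation of the delay-embedding parameters (Cao and Ragwitz
    criteria), autocorrelation-decay-time estimation with Theiler
    correction, six trial-based surrogate-data schemes, nonparametric
    permutation testing with FDR/Bonferroni correction, a shift test
    against instantaneous linear mixing (volume conduction, shared
    noise), condition and group comparison pipelines, and seeded
    simulators of coupled autoregressive and mixed white-noise
    benchmark systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
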