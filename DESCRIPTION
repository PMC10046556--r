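Package: thetanet
Title: Theta-Band EEG Functional Network Analysis of Mental Workload
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pipeline for studying mental workload and skill acquisition through
    theta-band functional brain networks. Generates synthetic multichannel EEG
    with known phase-coupling structure (stochastic phase oscillators with
    volume-conduction mixing), preprocesses recordings (zero-phase bandpass,
    decimation, event segmentation), estimates the individual alpha peak
    frequency by the spectral center-of-gravity method to anchor an
    individualized theta band, computes weighted Phase Lag Index connectivity,
    binarizes matrices at the per-test median, derives graph metrics
    (characteristic path length, global and local efficiency, clustering,
    small-worldness against degree-preserving surrogate networks), and runs the
    two-way within-subject ANOVA layer with Greenhouse-Geisser correction,
    generalized eta squared, and Bonferroni-corrected mass-univariate tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
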