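Package: flightload
Title: Single-Trial Mental Workload Estimation from Oddball EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of six-channel auditory-oddball EEG for
    passive brain-computer-interface workload estimation. Provides a synthetic
    flight-EEG generator with load-dependent P300 and band-power effects,
    EDF and event-table I/O, windowed-sinc FIR preprocessing, Artifact
    Subspace Reconstruction (classic and Riemannian-mean variants) with
    clean-raw channel/window criteria, ERP and CSP log band-power features,
    mRMR + shrinkage-LDA single-trial classification with stratified
    cross-validation, forward-model (activation pattern) interpretation, and
    sign-flip bootstrap condition contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
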