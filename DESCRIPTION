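Package: pulsegate
Title: ECG-Only Pulse Detection for Out-of-Hospital Cardiac Arrest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the presence of pulse from short single-lead ECG
    segments recorded during out-of-hospital cardiac arrest, classifying
    organized rhythms into pulse-generating rhythm (PR) versus pulseless
    electrical activity (PEA). Implements two compact neural networks (a
    fully convolutional network and a convolutional-recurrent network with a
    bidirectional GRU), their training recipe (ADAM, per-mini-batch
    augmentation, patient-equalized cross-entropy, max-norm constraints),
    Monte-Carlo-dropout uncertainty gating for selective feedback,
    hand-crafted-feature machine-learning baselines, Bayesian
    hyper-parameter optimization (TPE and Gaussian-process surrogates), and
    patient-weighted evaluation. A synthetic ECG generator with
    patient-structured PR/PEA contrasts makes the whole pipeline exercisable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    e1071,
    randomForest,
    lhs,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
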