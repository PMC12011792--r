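Package: ecgid
Title: Biometric Identification from 12-Lead ECG via Mutual-Information
    Graph Convolutional Networks
Version: 0.1.0
Authors@R:
    person("ecgid", "maintainers", email = "maintainers@ecgid.invalid",
           role = c("aut", "cre"))
Description: Tools for person identification from 12-lead electrocardiograms.
    Implements a full pipeline: denoising (Butterworth band-pass, LOESS
    baseline removal, non-local-means), per-lead feature extraction, a
    histogram estimator of inter-lead mutual information, construction of a
    thresholded and symmetrically normalized 12x12 lead graph, a graph
    convolutional classifier trained with Adam, biometric evaluation metrics
    (accuracy, precision, recall, F1, ROC-AUC, equal error rate) under
    hold-out, k-fold and leave-one-out protocols, and paired t-test /
    confidence-interval comparison of model variants. Includes a synthetic
    12-lead ECG cohort simulator with the four classical noise sources
    (powerline, baseline wander, electrode motion, muscle noise) and WFDB
    record I/O so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    digest,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
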