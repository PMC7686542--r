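Package: gcflow
Title: Granger-Causal Effective Connectivity Analysis of Brain Network
    Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Directed (effective) connectivity analysis of multi-region
    neuroimaging time series. Computes bivariate Granger-causality
    matrices over a 52-region, six-subsystem resting-state parcellation,
    selects consensus connections by F-score ranking inside a
    leave-one-out support-vector-machine loop, derives regional and
    inter-system information-flow-strength statistics with group tests,
    tracks the temporal co-evolution of inter-system causal interactions
    in sliding windows, quantifies the regulatory effect of the
    frontoparietal control network by partial-correlation strength, and
    classifies groups with a permutation-tested linear SVM. Includes a
    block-structured vector-autoregressive cohort simulator with planted
    ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    kernlab,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
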