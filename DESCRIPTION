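Package: icnsync
Title: Task-Linked Intrinsic Network Synchrony Analysis for EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for task-based EEG studies of
    intrinsic connectivity network (ICN) dynamics under the tri-network model
    (default mode, central executive, and salience networks). Provides a
    synthetic-cohort generator with controllable network-coupling effects,
    EEG preprocessing (zero-phase Butterworth band filtering via second-order
    sections, spectral bad-channel detection, ICA-based artifact removal,
    average referencing, spherical-spline interpolation, block-aligned
    epoching), connectivity feature extraction (coherence, phase lag index,
    directed phase lag index, phase-amplitude coupling, cross-frequency
    synchronization index), window-level network-state classification, the
    pairwise cross-entropy (PCE) synchrony statistic over task trials and
    trial halves, responder labeling for neurofeedback and aerobic-exercise
    interventions, and the group-level statistical battery (ANOVA families
    with FDR and Bonferroni control, bootstrapped repeated-measures ANOVA,
    rank correlations, and cross-validated response prediction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    glmnet,
    e1071,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
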