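Package: pulsespace
Title: Phase-Space Electro-Mechanical Pulse-Wave Analysis for Elevated LVEDP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for non-invasive prediction of
    elevated left ventricular end-diastolic pressure (LVEDP) from orthogonal
    voltage gradient (OVG) and photoplethysmography (PPG) signals. Provides a
    synthetic cohort and signal generator with known ground truth, signal
    quality gates (powerline and high-frequency SNR, PPG saturation),
    cardiac-cycle segmentation and feature extraction across time-domain,
    phase-space, PPG-indicator, spectral, synchronization and respiration
    families, isolation-forest outlier exclusion, a 13-model ensemble
    classifier (random forests, gradient boosting, elastic nets) with
    normalized-output averaging and repeated stratified cross-validation,
    diagnostic-accuracy evaluation (DeLong AUC confidence intervals and tests,
    Clopper-Pearson intervals, LVEDP threshold sweeps, propensity matching,
    subgroup reports), and a boxplot-constrained Monte-Carlo simulation of BNP
    performance with Bayesian post-test probability curves and net
    reclassification index comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    pROC,
    ranger,
    xgboost,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
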