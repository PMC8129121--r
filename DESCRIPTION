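Package: restingalpha
Title: Resting-State EEG Alpha Biomarkers of Schizotypy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for discriminating high- from low-schizotypy
    individuals using resting-state EEG alpha-band features: individual
    alpha frequency (IAF) located on a Savitzky-Golay smoothed power
    spectrum, maximum alpha amplitude in dB, weighted phase lag index
    (wPLI) and the directional time lag index (TLI) between frontal and
    parieto-occipital electrode clusters. Includes a synthetic
    multichannel EEG cohort generator with per-subject alpha sources,
    1/f background and lagged intra-hemispheric coupling; mixed-design
    2x2x2 ANOVA with partial eta squared and noncentral-pivot confidence
    intervals; Dunn-Sidak multiple-comparison thresholds; and a nested
    stratified cross-validated pattern classifier (linear SVM and L2
    logistic regression) with feature-combination selection, balanced
    accuracy, AUC and averaged ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
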