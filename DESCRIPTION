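Package: ctphase
Title: Contrast-Phase Identification for Multi-Phase Abdominal CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automatic identification of contrast-enhancement phases
    (early arterial, late arterial, portal venous, delayed) in multi-phase
    abdominal CT examinations. Implements a shared-parameter 3D convolutional
    feature extractor with cross-phase attention fusion, one-step and two-step
    (cascaded) classification strategies with phase-order calibration, focal-loss
    training with a step learning-rate schedule, and diagnostic accuracy
    statistics (sensitivity, specificity, PPV, NPV, balanced-accuracy AUC,
    binomial confidence intervals, chi-square subgroup comparisons). Ships a
    synthetic multi-phase abdominal phantom generator with a rule-based
    labelling oracle so the full pipeline is trainable and testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
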