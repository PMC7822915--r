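Package: trajex
Title: Trajectory Features and Ensemble Classification for Longitudinal
    Cognitive Decline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts conversion from normal cognition to mild cognitive
    impairment (MCI), and from MCI to Alzheimer's disease, from irregular
    longitudinal cognitive-test and structural-MRI measurements. Per-measure
    linear (or quadratic) mixed-effects models yield subject-level trajectory
    features (random-effect slope, baseline deviation from the cohort curve,
    and endpoint rate of change) which feed a soft-voting ensemble of five
    classifiers tuned by subject-level leave-one-out cross-validation.
    Includes a seeded synthetic-cohort generator emulating the statistical
    structure of ADNI-style longitudinal data, permutation feature
    importance, and stratified k-fold robustness evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    glmnet,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
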