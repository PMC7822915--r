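---
title: "Trajectory features and ensemble classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory features and ensemble classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajex)
```

## The problem

Conversion from normal cognition to mild cognitive impairment (MCI), and
from MCI to Alzheimer's disease (AD), is preceded by years of gradual change
in memory performance, global cognition, and regional brain structure.
Longitudinal study cohorts observe these changes on irregular schedules:
subjects differ in the number of visits, the spacing between visits, and the
total time under observation, and cognitive testing and MRI scanning follow
different calendars. `trajex` implements a pipeline for predicting
conversion from such data: per-measure mixed-effects trajectory models turn
each subject's irregular series into a small set of subject-level features,
and a soft-voting ensemble of five standard classifiers separates stable
subjects from converters in two experiments — stable healthy controls (HC)
vs controls who later convert to MCI (cMCI), and stable MCI (sMCI) vs MCI
subjects who later convert to AD (cAD).

## Trajectory model

For each measure $c$ (three cognitive scores: RAVLT immediate recall, RAVLT
percent forgetting, ADAS13; six MRI measures: hippocampal volume,
entorhinal-cortex thickness, and lateral-ventricle volume, each per
hemisphere) we fit a linear mixed-effects model with age as the only
predictor:

$$
M^{c}_{ij} = \beta_0^{c} + \beta_1^{c}\,\mathrm{Age}_{ij}
           + b_{0i}^{c} + b_{1i}^{c}\,\mathrm{Age}_{ij}
           + \epsilon^{c}_{ij},
$$

with subject random effects $(b_{0i}, b_{1i}) \sim N(0, D)$ and residuals
$\epsilon_{ij} \sim N(0, \sigma^2_\epsilon)$. Lateral-ventricle volume grows
non-linearly at the cohort level (accumulating cerebrospinal fluid as
atrophy progresses), so for the ventricles the model adds quadratic fixed
and random terms $\beta_2\,\mathrm{Age}^2 + b_{2i}\,\mathrm{Age}^2$.
Volumes (hippocampus, ventricles) are divided by estimated total
intracranial volume (eTIV) before fitting, removing head-size and most sex
differences; thickness and test scores are used raw.

Estimation is REML via `lme4::lmer`. Ages are centred at the
training-sample mean before entering the model: around age 75 the raw
$(\mathrm{Age}, \mathrm{Age}^2)$ design is severely ill-conditioned, and
centring fixes this without changing the model. The centring constant is
stored inside the fitted `trajectory_model` so that features for new
subjects are computed on exactly the training scale.

### Features

Per subject and measure the pipeline derives:

* **r-slope** — the subject's random slope $b_{1i}$ (and for the ventricles
  additionally the quadratic coefficient $b_{2i}$, the `_quad` columns):
  the subject's rate of change relative to the cohort curve, borrowing
  strength across subjects.
* **dev** — the first observation minus the fixed-effect prediction at that
  age, $M_{i1} - (\beta_0 + \beta_1 \mathrm{Age}_{i1})$ (the $\beta_2$ term
  is included for the ventricles, a deliberate extension of the linear-case
  formula so that "distance from the cohort curve" means the same thing for
  both model orders): where the subject entered the study relative to the
  cohort average.
* **d-slope** — the endpoint rate of change
  $(M_{in_i} - M_{i0}) / (\mathrm{Age}_{in_i} - \mathrm{Age}_{i0})$,
  which deliberately depends on the subject's own observation span.

Sex (0 = male, 1 = female) and age at the last retained visit
(`current_age`) complete the feature vector. With three cognitive measures
that is $3 \times 3 + 2 = 11$ features; adding the six MRI measures (two of
them quadratic) gives $9 \times 3 + 2 + 2 = 31$.

`current_age` uses the last retained visit of *either* modality — the later
of the last cognitive and last MRI visit — since both streams carry
information about how long the subject was observed pre-conversion.

### Censoring and leakage

Two rules protect the prediction task:

1. **Censoring at conversion.** All visits at or after the first visit
   carrying the converted diagnosis are removed, in both modalities, before
   any feature is computed. The models only ever see strictly
   pre-conversion data. A converter censored down to a single visit in a
   modality has no d-slope there; the value is recorded as missing and
   imputed with the median over training-subject rows (no subject is
   dropped for this).
2. **Hold-out before fitting.** In a mixed model every subject influences
   the fixed effects and variance components, hence every other subject's
   features. The 20% test set is therefore put aside before any mixed model
   is fitted. Held-out subjects get their random effects from the
   closed-form empirical-Bayes (BLUP) predictor under the train-fitted
   parameters,
   $\hat b_i = D Z_i^\top V_i^{-1} (y_i - X_i \beta)$ with
   $V_i = Z_i D Z_i^\top + \sigma^2_\epsilon I$,
   so their data never touch the model. Applied to a training subject this
   formula reproduces the fitter's stored conditional modes, which the test
   suite verifies, along with bit-level invariance of training features
   when test subjects are deleted.

Mixed models are refitted per experiment and feature set on that
experiment's training subjects, because the hold-out is defined per
experiment.

## Classification

Five base learners — ridge/unpenalized logistic regression (`glmnet`),
a kernel SVM (`e1071`, with its built-in Platt calibration supplying
probabilities), k-nearest neighbours (implemented in-package so that both
Euclidean and Manhattan metrics are available and leave-one-out evaluation
is cheap), a random forest (`ranger`), and gradient boosting (`xgboost`) —
are each tuned by subject-level leave-one-out cross-validation over a small
grid, then combined by soft voting: the ensemble probability is the
uniformly weighted mean of member probabilities, and the label is 1 when it
reaches 0.5 (an exact tie goes to the converter class). Uniform weights are
the standard reading of probability-weighted voting when no weights are
specified; they are stored in the model and can be edited. Features are
standardized by training mean/SD for the scale-sensitive members (logistic,
SVM, kNN); the tree ensembles consume raw features.

The train/test split is stratified by label and sex, balances the classes
exactly, and matches train/test age distributions by drawing one test
subject per consecutive age band within each label-by-sex stratum.

Hyperparameter grids are small and documented (`default_grids()`): LOOCV
refits every grid point once per training subject, so grid size multiplies
directly into runtime. `default_grids(compact = TRUE)` provides a one-point
grid per family (the midpoint of each default grid) for end-to-end runs
where the search itself is not under study; the packaged acceptance script
and the replication checks in the test suite use it so that full-cohort
LOOCV ensembles complete in minutes on one CPU. During LOOCV the SVM is
fitted without probability calibration (class predictions suffice for
accuracy); the final refit enables it for soft voting.

## Evaluation

`evaluate()` reports the confusion matrix (rows = truth), accuracy,
precision, recall and F1. The converter group is the positive class — it is
the clinical target — and class-1 metrics are primary; macro-averages are
also emitted. `kfold_robustness()` refits the whole pipeline (grid search
included) inside stratified folds whose label counts are within one of
proportional and whose sex ratios and age means are matched by a sorted
cyclic deal. `permutation_importance()` implements mean decrease accuracy:
each feature column is shuffled five times on the held-out test rows (the
model untouched) and the mean accuracy drop is recorded; the test set is
used because importance should reflect generalization, not memorization.
Features whose trial SD exceeds the mean drop are flagged unstable, mirroring
the convention of excluding such features from importance plots.

## The synthetic cohort generator

The analysis was designed for an access-restricted longitudinal cohort, so
the package ships a seeded generator (`generate_cohort()`) that emulates the
statistical structure the pipeline assumes, making every stage testable:

* **Group structure** — four subgroups with the published sizes (134 HC,
  134 cMCI, 333 sMCI, 333 cAD) and per-group visit schedules: visit counts
  $2 + \mathrm{Poisson}(\bar n - 2)$ and inter-visit gaps
  $\mathrm{Gamma}(4, \bar\Delta/4)$ (coefficient of variation 0.5, chosen
  once as a realistic irregularity level), calibrated to the published
  per-group means — e.g. sMCI: 5.1 MRI scans 0.48 years apart, 6.0
  cognitive tests 0.63 years apart. Cognitive and MRI schedules are sampled
  independently because their published average intervals differ.
* **Trajectories** — per (subgroup, measure), subject intercept, slope (and
  ventricular quadratic term) drawn from between-subject normal
  distributions plus Gaussian visit noise. Trajectories are parameterized
  at the mean baseline age (76 y), so the configured intercept mean is also
  the expected baseline value; the test suite checks 3-standard-error
  agreement at n = 500 per group. Cognitive intercepts and SDs use the
  published training-set female calibration (e.g. cAD ADAS13
  21.8 ± 7); slopes are chosen so converter groups decline faster than
  their stable counterparts. MRI scales are typical FreeSurfer values
  (hippocampus ≈ 3.0–3.7 × 10³ mm³ per side, lateral ventricle
  ≈ 2–3 × 10⁴ mm³ with a positive quadratic term, entorhinal thickness
  ≈ 3 mm, eTIV ≈ 1.5 × 10⁶ mm³) with plausible annual decline rates, since
  the emulated summaries do not print raw MRI means.
* **Conversion** — converters switch diagnosis at a visit drawn uniformly
  between the second and penultimate cognitive visit (no conversion-timing
  distribution is published; this guarantees at least one strictly
  pre-conversion visit). RAVLT percent forgetting is generated directly as
  a measure, clipped to [−50, 150]; trial-level simulation is out of scope.
* **Knobs** — `cross_measure_rho` couples a subject's random effects across
  measures through a latent severity factor (default 0: independence; the
  within-subject cross-measure correlation of decline is not published).
  `mri_dominant_hc_cmci = TRUE` gives HC and cMCI identical cognitive
  trajectories but clearly separated MRI decline rates, emulating the
  regime where structural change precedes measurable cognitive change.
* Education and sex are generated (education is *not* a classifier
  feature; the feature list is fixed to the trajectory features plus sex
  and current age).

### What the generator does and does not emulate

It reproduces group means/SDs, irregular scheduling, near-linear decline
with a convex ventricular trajectory, and conversion-censoring semantics.
It does not model floor/ceiling psychometrics beyond clipping, practice
effects, missing-not-at-random dropout, scanner/site effects, or realistic
cross-measure correlation structure (unless the knob is turned). Passing
replication checks on these cohorts therefore demonstrates that the
pipeline recovers structure it was designed for — not that real-cohort
performance figures would be reproduced.

## Numerical choices and degenerate inputs

* REML throughout; `lmerControl(calc.derivs = FALSE)`, singular-fit checks
  relaxed: a singular $D$ (common when a variance component is tiny) yields
  a warning upstream, not an error, and the BLUP formula only requires
  $V_i$, not $D^{-1}$.
* Zero-variance data (all subjects on one line) is a supported limiting
  case: fixed effects recover the line, random effects and $\sigma^2$ go to
  zero within optimizer tolerance.
* d-slope errors on a single visit or identical first/last ages; dev and
  d-slope sort visits by age internally, so file row order is irrelevant.
* Grid-search ties go to the earliest grid row; soft-vote ties at exactly
  0.5 go to class 1; both rules are documented and tested.
* Constant feature columns get scaling SD 1 (not 0) so standardization
  never divides by zero; their permutation importance is exactly 0.
* Seeds: one global seed fans out to per-stage seeds through a fixed affine
  map (`cohort`, `split`, `ensemble`, `importance` offsets), so stages can
  be rerun in isolation; all stage seeds stay below $2^{31}$.

## Problem sizes

The packaged checks run on one CPU: parameter recovery uses 200 simulated
subjects with 6 visits; the BLUP oracle uses 50 random subjects; the
replication-direction checks run the full pipeline on default-size cohorts
(666 resp. 268 subjects per experiment) across 5 seeds with the compact
grids; the acceptance script repeats the four experiment/feature-set runs at
the same size. The k-fold robustness helper refits the entire grid search
inside every fold, so its cost is k times the ensemble cost; the packaged
tests exercise it at toy sizes and leave full 15-fold runs to the user.

## Known limitations

* The quadratic random-effect model for ventricles can be near-singular on
  small cohorts; the fit is still returned (with $D$ projected to the
  nearest symmetric matrix) and BLUPs remain well-defined.
* Vote weights are uniform; no weight optimization is attempted.
* The SVM's probabilities come from Platt scaling on held-in folds, which
  can be poorly calibrated at small n — a known property of the method, not
  of this implementation.
* Normalizing ventricle volumes before choosing the quadratic form (rather
  than after) is a modelling decision; the package normalizes first so that
  one rule covers all volumes.
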