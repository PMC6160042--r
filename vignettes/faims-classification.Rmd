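---
title: "Classifying disease from FAIMS urinary volatiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying disease from FAIMS urinary volatiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Field Asymmetric Ion Mobility Spectrometry (FAIMS) measures the volatile
organic compounds (VOCs) emanating from a biological sample — here, urine
headspace — by ionising them and sweeping a DC compensation voltage (CV)
against a stepped asymmetric dispersion field. One run of one sample
produces a pair of dispersion matrices (one per ion polarity): detected
current over 512 CV steps (+6 V to −6 V) × 51 dispersion-field steps.
Each sample is measured three consecutive times ("runs"), and disease
state is a binary label (case/control) accompanied by demographic
covariates (sex, age, alcohol use, BMI).

The statistical task is high-dimensional, small-sample classification:
roughly 10^2 samples against 5 × 10^4 raw measurements per sample, with
spatially structured signal (curved analyte traces in the CV × field
plane), strong run-to-run degradation of volatile analytes, and — a key
caveat in this kind of case-control design — demographic imbalance that
can confound the chemical signal. `faimspipe` implements the full
pipeline: data model and I/O, wavelet feature extraction, in-fold feature
selection, five reference classifiers under stratified cross-validation,
ROC evaluation with bootstrap uncertainty, ensembling across runs, and a
synthetic cohort generator that makes every stage testable end to end.

# Pipeline stages and their parameters

## Linearisation

A run is flattened positive-matrix-first, row-major over CV rows, giving
`2 × 512 × 51 = 52,224` features with identifiers encoding polarity and
grid position. The concatenation order is a package convention (fixed so
that feature identifiers are stable); any consistent order works because
every downstream stage is permutation-equivariant up to its documented
tie-breaks.

## Discrete wavelet transform

Wavelet coefficients concentrate smooth, localised spectral structure
into few large coefficients, which suits dispersion plots: an analyte
appears as a compact curved ridge. Two modes are supported.

* **1D** (`wavelet_spec(mode = "dwt1")`): the linearised vector is
  zero-padded to the next power of two (65,536) and decomposed to full
  depth; the output is all detail coefficients plus the final smooth
  coefficient, ordered scale-major from coarsest to finest.
* **2D** (`mode = "dwt2"`, the recommended setting): the vector is
  reshaped back to its 512 × 102 grid (positive columns then negative
  columns), optionally cropped to the `crop_rows` CV rows that contain
  structure (512, 256 or 128), zero-padded to a dyadic square, and
  decomposed to full depth by a separable 2D transform. The feature
  vector keeps all four sub-grids per scale — smooth, horizontal,
  vertical, diagonal — plus the final smooth constant, i.e.
  `4(4^L − 1)/3 + 1` features for a `2^L` square: 349,525 (512),
  87,381 (256), 21,845 (128). Keeping the smooth track at every scale is
  deliberately redundant with respect to the orthonormal basis (the
  smooth sub-grid is what gets decomposed further); it is part of the
  package's canonical feature layout, and `idwt2()` reconstructs from the
  non-redundant subset (details plus final smooth).

The filters are least-asymmetric Daubechies ("symlet") wavelets with 10
vanishing moments by default (`vanishing_moments`, 1–10): long enough to
be nearly symmetric — so coefficient energy stays aligned with ridge
position — while still compactly supported. Boundary handling is
periodic on the already-zero-padded dyadic array, the standard choice for
decimated transforms: it keeps the transform exactly orthonormal (energy
conservation and perfect reconstruction hold to ~10⁻¹³ relative error in
the test suite), and the zero padding means wrap-around touches only
zeros. The analysis phase convention matches the widespread
"periodization" convention, verified coefficient-for-coefficient against
an independent implementation on frozen inputs.

The crop window defaults to rows `[0, crop_rows)`; real dispersion plots
carry their structure in a low-|CV| band, and `crop_offset` moves the
window if an instrument configuration puts structure elsewhere.

## Feature exclusion (`sigma`)

Features whose sample standard deviation is not strictly greater than
`sigma` are dropped inside each training fold. The default `sigma = 0`
removes exactly the zero-variance features — mostly wavelet coefficients
that are functions of the zero padding alone. "Strictly greater" is
chosen so that the documented `sigma = 0` behaviour (remove only
zero-variance features) follows from the rule itself. Raising `sigma`
mainly buys speed, not accuracy, so 0 is the recommended value.
Constant-column detection compares values exactly rather than relying on
a variance computation, so cancellation error cannot leak a constant
feature through.

## Filter selection (`nkeep`)

Every retained feature is scored by a two-sided Wilcoxon rank-sum test of
case versus control values, and the `nkeep` smallest-p features are kept
(ties broken by ascending feature index, so selection is deterministic).
The default `nkeep = 2` gives the smallest usable input dimension; the
AUC is typically flat over a wide `nkeep` range. The p-value is exact
(computed from the enumerated rank-sum null) when both groups have at
most 25 observations and no ties occur, and otherwise uses the normal
approximation with tie and continuity corrections — the same convention
as `stats::wilcox.test`, against which the vectorised per-feature screen
is verified exactly. No multiplicity correction is applied: only the
ranking matters.

Selection runs strictly inside each cross-validation fold, on training
rows only — the single most important design property of the pipeline,
since selecting on all samples first would make held-out performance
meaningless at this dimensionality.

## PCA (optional), wrapper and embedded comparison modes

With `use_pca = TRUE`, the filter cap is first raised to the
training-set size, then a covariance PCA (centred on training means, no
scaling, fitted by SVD) keeps the fewest components reaching
`pca_var_threshold` (default 95%) of the variance, never fewer than two;
test scores use training loadings and centring. PCA typically *hurts*
here — linear recombination dilutes the few informative coefficients —
and is off by default.

The wrapper mode is greedy stepwise AIC over binomial GLMs: starting
from `wrapper_n_start = 5` random features, each step tries every
single-feature addition or removal, accepts the move that most decreases
`AIC = deviance + 2k` (k = fitted coefficients including the intercept),
and stops at a local minimum. Non-convergent candidate fits (e.g.
quasi-separation) are skipped with a warning, and a non-convergent start
is redrawn with progressively fewer features. The embedded mode passes
all retained features straight to the classifiers, relying on their own
sparsity (lasso, forest splits). Both exist as comparison arms; the
filter method is the recommended default on both accuracy and cost.

## Classifiers

Five reference classifiers run under one harness (`fit_predict()`), all
emitting case probabilities:

| kind | implementation | non-default settings |
|---|---|---|
| `random_forest` | randomForest | 500 trees, importance recorded |
| `sparse_logistic` | glmnet | binomial, lasso (`alpha = 1`), penalty by inner CV deviance |
| `svm_rbf` | kernlab::ksvm | `k(x,y)=exp(−σ‖x−y‖²)`, σ = 0.05, C = 5, Platt probabilities, 3-fold internal CV |
| `neural_net` | in-package | 1 hidden unit, logistic activations, RPROP+ with weight backtracking |
| `gaussian_process` | kernlab::gausspr | unscaled inputs, termination tolerance 0.01 |

The neural network is trained on cross-entropy by resilient
backpropagation with weight backtracking (step sizes 0.1 initial,
×1.2/×0.5 adaptation, bounds 10⁻⁶–50), stopping when the largest
absolute gradient falls below 0.01; if the iteration cap (10,000) is hit
first, the fold degrades to predicting the training prevalence with a
logged warning rather than aborting the whole cross-validation — small
networks on selected features occasionally stall, and a prevalence
prediction is the honest "no information" output. The lasso penalty
weight is chosen by inner cross-validated deviance on the training fold
(the penalty rule is a package decision; only the penalty family is
canonical).

## Cross-validation

`cv_spec(k = 10)` stratified folds: shuffled cases are dealt round-robin
across folds and shuffled controls continue the deal, which makes both
the total fold sizes and the per-fold class counts balanced to within
one sample (115 samples give training sets of exactly 103 or 104). Folds
and all stochastic fitting are seeded; a draw that would leave a
single-class training set is retried with a logged message. Each sample
is predicted exactly once, out of fold, and per-model predictions are
pooled into one ROC analysis.

## Evaluation

AUC is the normalised Mann–Whitney statistic (ties count one half),
identical to the trapezoidal ROC area. Its 95% CI comes from 2,000
stratified bootstrap replicates (cases and controls resampled
independently; percentile interval — the simplest defensible choice, and
documented as such). The operating threshold maximises
`(SE − 1 + SP)² + (SP − 1 + SE)²`, which equals `2(SE + SP − 1)²` and
therefore picks the squared-Youden-index maximiser; candidate thresholds
are midpoints of adjacent distinct probabilities plus sentinels, the
rule is `probability ≥ threshold ⇒ case`, and ties resolve toward higher
specificity, then lower threshold. Sensitivity and specificity at that
threshold carry exact Clopper–Pearson intervals, always reported on the
same scale as the point estimate. Demographic covariates can be scored
as single biomarkers (`demographic_auc()`, orientation-corrected to
`max(a, 1 − a)` with the flip logged), and two probability sets are
compared with an unpaired two-sided rank-sum test
(`compare_predictions()`).

## Ensembles

Three ways to combine the three runs of each sample: subtract two runs'
raw tables (`combine_subtract`; probes degradation chemistry), average
the three raw tables (`combine_mean`), or classify each run separately
and average the per-sample probabilities (`probability_ensemble`). All
are exposed through the `run` selector of `pipeline_config()`.

## Demographics

`demographics = "only"` feeds sex (0/1), age, alcohol and BMI as the
entire feature set (no selection — four features need none);
`"combined"` appends them to the in-fold selected wavelet features. A
strong demographics-only result signals confounding: the classifier may
be reading the cohort's demographic imbalance rather than chemistry.

# The synthetic cohort generator

No clinical FAIMS cohort is bundled; `generate_cohort()` produces one
with the structural features the pipeline must cope with:

* **Geometry.** Per polarity, a grid of `rows × cols` (default 512 × 51)
  holding a small baseline, a high-amplitude reactant-ion ridge, and
  `n_peaks = 6` Gaussian analyte peaks whose CV centre drifts linearly
  across dispersion columns (`drift_slope = 1.5` rows/column) — the
  simplest shape reproducing the curved traces of real dispersion plots.
  Peak centres are placed in the low-CV band (4–22% of the rows) where
  real plots carry structure, so the 128-row cropped transform window
  covers them.
* **Class signal.** The first two peaks are markers: cases get their
  amplitudes scaled by `1 + effect_size` (default 1.5×). Biological
  variability enters as per-sample, per-peak lognormal amplitude noise
  (sd 0.3 on the log scale) and a per-sample global intensity factor
  (sd 0.2), so classification is non-trivial; additive Gaussian noise
  (sd 0.02) models detector noise, and values clip at zero like a real
  current measurement.
* **Degradation.** All analyte peaks are volatile-designated and decay
  by `run_decay = 0.85` per run, so run 3 is measurably weaker than
  run 1 — the reason run choice and run ensembles matter.
* **Demographics.** Case/control moments (BMI 38.3 (10.5) vs
  28.1 (5.96); mean age 57 vs 45; alcohol 2 vs 5 units/week; male
  fraction 43/72 vs 17/43) interpolate with the pooled cohort through
  the `confounding` knob: 1 reproduces a demographically imbalanced
  case-control study, 0 gives identical distributions. This makes the
  confounding analysis rehearsable in both directions.
* **Determinism.** The whole cohort is a pure function of `seed`;
  `planted_truth()` recomputes the marker-peak windows so selection
  recovery can be scored, and `features_overlap_truth()` maps selected
  2D wavelet features back to grid regions through their
  inverse-transform support.

What the generator does *not* emulate: real chemical identity and
co-elution, instrument drift between samples, heteroscedastic detector
noise, or missing runs. A pipeline that passes on synthetic cohorts has
demonstrated its statistical machinery, not clinical validity.

# Numerical and testing choices

* Transform exactness is asserted at 10⁻⁶ (energy) and 10⁻⁸
  (reconstruction) relative error over random matrices; observed errors
  are ~10⁻¹³.
* The statistical primitives are tested against independent brute force:
  rank-sum p-values against full enumeration of rank assignments for all
  group sizes up to 6, AUC against direct pair counting, the threshold
  rule against an exhaustive Youden scan, and the stepwise wrapper
  against both exhaustive best-subset AIC and an established stepwise
  implementation.
* End-to-end property checks run at reduced problem sizes chosen to keep
  the suite quick while preserving the regime of interest: permutation
  nulls on a 30 + 30 cohort and planted-signal recovery on a 60 + 60
  cohort, both with the 128-row cropped 2D transform: the crop window
  covers the structured compensation-voltage band, so the cropped variant
  carries the same signal as the full 512-row transform at a sixteenth of
  the feature count (21,845).
* Under label permutation the pipeline's out-of-fold AUC is unbiased
  (mean ≈ 0.51 over 20 permutations, every model) — the direct evidence
  that no information leaks across folds. One caveat is worth knowing:
  the per-realisation bootstrap CI undercovers the *across-permutation*
  spread of pooled cross-validation AUC (~80% rather than 95%), because
  all samples of a test fold share that fold's randomly selected
  features and fitted model, a variance component invisible to a
  case/control bootstrap that conditions on the realised scores. A
  control simulation isolates this: the identical bootstrap covers 95%
  for exchangeable scores and ~74% once a fold-level random shift is
  injected, with no cross-validation code involved. Permutation testing,
  not the bootstrap CI, is therefore the right tool for null calibration
  of pooled-CV AUCs.

# Known limitations

* The 1D mode's coefficient count is a convention (padded length 65,536
  for instrument-standard input); other historical conventions counted
  differently, so 1D feature identifiers are not comparable across
  software.
* Probabilities pooled across folds are not recalibrated; AUC is
  rank-based and unaffected by monotone miscalibration within a fold,
  but fold-to-fold calibration differences add variance (see above).
* The wrapper mode is practical only after pre-filtering (hundreds to a
  few thousand features); its cost grows with the square of the feature
  count and it underperforms the filter method anyway.
* `ksvm`'s Platt calibration and `cv.glmnet`'s inner folds are stochastic;
  all of it is seeded per fold, so pipelines reproduce bit-identically
  from their manifest, but per-fold probabilities depend on the seed as
  in any such pipeline.

# A minimal session

```{r, eval = FALSE}
library(faimspipe)

spec <- synth_spec(n_case = 30, n_control = 30, seed = 1)
cohort <- generate_cohort(spec)

config <- pipeline_config(
  wavelet = wavelet_spec(crop_rows = 128),
  models = default_models()["sparse_logistic"],
  cv = cv_spec(k = 10, seed = 1),
  n_boot = 2000)

result <- run_pipeline(config, cohort)
result$metrics$sparse_logistic
```
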