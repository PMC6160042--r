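# faimspipe

Machine-learning classification pipelines for FAIMS (Field Asymmetric Ion
Mobility Spectrometry) measurements of volatile organic compounds in
biological samples.

FAIMS instruments read the headspace of a sample (e.g. urine) as a pair of
dispersion matrices — detected ion current over 512 compensation-voltage
steps × 51 dispersion-field steps, one matrix per ion polarity — three
consecutive runs per sample. The scientific question is whether disease
state can be classified from these 52,224 raw measurements per sample at
cohort sizes of order 100, which makes the statistics (feature extraction,
leakage-free selection, honest uncertainty) the hard part. `faimspipe` is
for researchers analysing such data, and for methodologists who want a
fully testable reference pipeline.

## What it implements

- **Data model & I/O** — `faims_run` objects, a plain-text run dialect
  (`read_faims_run`/`write_faims_run`), sample metadata, linearisation into
  feature vectors (`linearise`, `build_table`), run subtraction and run
  averaging.
- **Wavelet features** — full-depth decimated 1D/2D discrete wavelet
  transforms with least-asymmetric Daubechies filters and periodic
  boundaries (`wavelet_table`, `dwt1_features`, `dwt2_features`, inverses,
  and per-coefficient spatial support). The 2D layout keeps all four
  sub-grids per scale plus the final smooth constant: 349,525 features
  from a 512×512 padded grid, 87,381 from 256×256, 21,845 from 128×128.
- **Feature selection** — SD exclusion (`sd_exclude`), Wilcoxon rank-sum
  filter selection (`ranksum_p`, `filter_select`), covariance PCA
  (`pca_reduce`), and a stepwise-AIC wrapper (`stepwise_select`), all run
  strictly inside cross-validation folds.
- **Classification** — five reference classifiers (random forest, lasso
  logistic regression, RBF SVM, a 1-hidden-unit RPROP neural network,
  Gaussian process) under a stratified, seeded 10-fold CV harness
  (`cross_validate`) producing out-of-fold case probabilities, plus
  probability-level ensembling across runs (`probability_ensemble`).
- **Evaluation** — Mann–Whitney AUC, stratified bootstrap CIs (2,000
  replicates), the balanced threshold rule maximising
  (SE − 1 + SP)² + (SP − 1 + SE)² = 2(SE + SP − 1)² (the squared Youden
  index), exact binomial CIs for SE/SP, demographics-as-biomarker AUCs,
  and rank-sum comparison of probability sets.
- **Synthetic cohorts** — `generate_cohort()` builds seeded cohorts with
  drifting Gaussian analyte peaks, planted marker peaks
  (`planted_truth`), run-to-run degradation and controllable demographic
  confounding, so the entire pipeline is testable without clinical data.
- **Orchestration** — `pipeline_config()` + `run_pipeline()` run any
  configuration (run selector, wavelet mode, selection, models,
  demographics mode) and write predictions, metrics, ROC points, selected
  features and a reproducibility manifest. A thin CLI lives at
  `inst/cli/faimspipe.R` (`simulate` / `run` subcommands over a YAML
  config).

## Worked example

Simulate a 30 + 30 cohort and run the recommended pipeline (run 2, 2D
wavelet transform cropped to the structured 128 compensation-voltage rows,
zero-variance exclusion, Wilcoxon filter keeping 2 features per fold,
lasso logistic regression):

```r
library(faimspipe)

spec   <- synth_spec(n_case = 30, n_control = 30, seed = 1)
cohort <- generate_cohort(spec)

config <- pipeline_config(
  wavelet = wavelet_spec(crop_rows = 128),
  models  = default_models()["sparse_logistic"],
  cv      = cv_spec(k = 10, seed = 1),
  n_boot  = 2000)

result <- run_pipeline(config, cohort)
result$metrics$sparse_logistic
#> <roc_summary> sparse_logistic  n = 30 case / 30 control
#>   AUC         0.797  (0.671-0.909, 95% CI, 2000 stratified bootstrap reps)
#>   threshold   0.4664
#>   sensitivity 0.833  (0.653-0.944, exact binomial)
#>   specificity 0.767  (0.577-0.901, exact binomial)
```

The AUC of 0.797 says that a randomly chosen case outranks a randomly
chosen control about 80% of the time, out of fold; the threshold 0.466 is
the probability cut-point balancing sensitivity (0.833: fraction of cases
called case) against specificity (0.767: fraction of controls called
control). Per-fold selected features show which wavelet coefficients carry
the signal:

```r
head(result$selection, 4)
#>   fold     feature_id      p_value
#> 1    1 W2_j3_LH_r6_c8 4.188679e-06
#> 2    1 W2_j2_HL_r4_c3 5.826378e-06
#> 3    2 W2_j3_LH_r6_c8 8.744571e-06
#> 4    2 W2_j1_HL_r2_c1 1.111845e-05
```

`features_overlap_truth()` maps such identifiers back to dispersion-grid
regions and confirms they sit on the planted marker peaks. See the
vignette (`vignettes/faims-classification.Rmd`) for the model details,
parameter meanings and design rationale.

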