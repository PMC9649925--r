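# strokerad

An R implementation of a DWI/ADC radiomics pipeline for predicting
1-year ischemic stroke recurrence, built to be testable end to end on
synthetic phantom cohorts with known ground truth.

About one in twelve ischemic stroke patients has a recurrent stroke
within a year. Acute infarcts are hyperintense on diffusion-weighted MRI
(DWI) and hypointense on the apparent diffusion coefficient (ADC) map,
and quantitative texture features of the lesion may carry prognostic
signal beyond clinical covariates. The pipeline implemented here:

1. **Phantom cohorts** (`phantom_config()`, `generate_cohort()`) —
   paired DWI/ADC volumes with ellipsoid-union lesions, Gaussian
   random-field intra-lesion texture, clinical covariates matching a
   published cohort's margins (1,003 subjects, 8.5% recurrence), and
   labels from a planted logistic model
   p(recurrence) = logistic(α + Σ w_f·z(feature_f) + Σ w_c·z(covariate_c)),
   with the intercept α calibrated by root finding so the mean equals the
   target prevalence.
2. **Segmentation** (`train_unet()`, `segment_volume()`,
   `postprocess_mask()`, `dice_coefficient()`) — a native 2D U-Net over
   window-normalized axial slices, per-slice removal of 8-connected
   components < 20 pixels, exclusion of lesions < 50 voxels, DICE
   verification.
3. **Radiomics** (`extract_features()`) — 513 features: 18 first-order +
   39 gray-level texture features (23 co-occurrence, 16 run-length; 13
   distance-1 directions, 32 gray levels) in the image domain and in the
   8 sub-bands of an undecimated one-level 3D Haar transform.
4. **Sparse selection** (`solve_sparse()`, `select_top_k()`) — the L0
   sparse-representation objective argmin_w ‖l − Fw‖² + η‖w‖₀ with
   labels coded −1/+1; exact subset enumeration for small problems,
   orthogonal matching pursuit with least-squares refit beyond; top 100
   coefficients by magnitude are kept.
5. **Classification** (`build_split()`, `train_rnn()`,
   `train_clinical_logistic()`) — under-sampled 57/100 training cohort,
   weighted cross-entropy, a GRU over 9 timesteps of 57 features, a
   clinical logistic baseline, and a combined model (late-fusion
   stacking by default).
6. **Evaluation** (`roc_auc()`, `delong_test()`, `confusion_metrics()`,
   `decision_curve()`, `table_one()`) — Mann–Whitney AUC with DeLong 95%
   CIs, DeLong tests between correlated AUCs, Youden-threshold metrics,
   decision-curve analysis, and cohort summary tables (pooled t,
   Mann–Whitney, χ²/Fisher).

## Worked example

A full experiment at the study scale — 1,003 phantoms, 85 recurrences,
57/100 under-sampled training cohort, 100 selected features, three model
arms:

```r
library(strokerad)

cfg <- experiment_config(
  phantom = phantom_config(n_subjects = 1003),
  rnn = rnn_config(epochs = 80, learning_rate = 1e-3, validation_fraction = 0),
  seed = 1
)
report <- run_experiment(cfg)
report
#> experiment report
#>   test cohort: 846 subjects (28 recurrences)
#>   clinical   AUC 0.562 (0.453-0.665)  acc 0.816 sens 0.286 spec 0.834
#>   radiomics  AUC 0.795 (0.707-0.862)  acc 0.745 sens 0.714 spec 0.746
#>   combined   AUC 0.808 (0.722-0.872)  acc 0.762 sens 0.714 spec 0.764
#>   DeLong clinical_vs_radiomics: p = 0.001
#>   DeLong clinical_vs_combined: p = <0.001
#>   DeLong radiomics_vs_combined: p = 0.257
```

Read it as: on the held-out 846-subject cohort (28 recurrences) the
clinical logistic model alone discriminates weakly on this seed's test
draw (AUC 0.56), the radiomic GRU does substantially better (0.80), and
fusing both is best (0.81) — the qualitative ordering the planted
generator encodes. Selection kept 94 radiomic features and all 6
clinical covariates of the 519-column pool. The sensitivity/specificity
rows are read off at the Youden threshold fixed on the training cohort.
Exact numbers vary with the seed; AUC differences of ±0.05 are within
sampling noise at 28 test recurrences.

The ground truth behind these numbers is available for checking:
`report$selection` lists which of the 519 candidate columns (513
radiomic + 6 clinical) survived selection, and the generated cohort's
`true_probability` column gives the Bayes-optimal score.

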