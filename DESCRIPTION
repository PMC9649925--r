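Package: strokerad
Title: DWI/ADC Radiomics Pipeline for Predicting One-Year Ischemic Stroke
    Recurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of a diffusion-weighted MRI (DWI/ADC)
    radiomics pipeline for predicting 1-year ischemic stroke recurrence in a
    heavily class-imbalanced cohort. Provides a synthetic phantom-cohort
    generator with known ground truth (lesion geometry, planted radiomic and
    clinical effects on recurrence), a compact native 2D U-Net lesion
    segmenter with windowed intensity normalisation and small-component
    cleanup, a 513-feature radiomic extractor (18 first-order and 39
    gray-level texture features in the image domain and in 8 undecimated
    wavelet sub-bands), L0 sparse-representation feature selection (exact
    enumeration for small problems, orthogonal matching pursuit beyond),
    an under-sampled training split with a GRU recurrent classifier trained
    under weighted cross-entropy, and the full statistical evaluation layer:
    ROC/AUC with DeLong confidence intervals and tests, threshold metrics,
    decision-curve analysis, and cohort ("table one") summaries with
    t, Mann-Whitney, chi-square and Fisher tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
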