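# habitatr

Habitat radiomics for preoperative prediction of axillary lymph node
metastasis (ALNM) from multiparametric breast MRI.

`habitatr` is aimed at quantitative-imaging researchers who want a fully
reproducible, tested implementation of an intratumoral-habitat radiomics
pipeline: it partitions each tumor into spatially coherent subregions
("habitats" — e.g. a necrotic core, a transition zone and a vascularised
rim), extracts a standardized radiomics feature bank from the whole tumor
and from each habitat on T2-weighted, diffusion-weighted and
dynamic-contrast-enhanced volumes, and builds interpretable
gradient-boosted models that predict nodal status. Because cohorts of this
kind are private, the package ships a first-class synthetic mpMRI
generator with planted habitat structure and published-scale clinical
effects, so every stage is exercised end to end without any download.

## The method

**Habitat generation (extract-then-pool).** Local first-order statistics of
each sequence are computed per voxel in a sliding 3³ window, spatially
aggregated by mean pooling inside SLIC supervoxels, and clustered by one
population K-means over all training patients' supervoxels. K ∈ [2, 10] is
selected by the mean silhouette coefficient, and clusters are ordered by
ascending mean DCE enhancement so habitat 1 is the least-enhancing core
and habitat K the vascularised rim, identically across patients.

**Feature bank.** 14 shape + 93 intensity features (first-order, GLCM,
GLDM, GLRLM, GLSZM, NGTDM) on the original image, 8 undecimated coif1
wavelet subbands and 2 Laplacian-of-Gaussian scales (σ = 3, 4 mm):
14 + 93 × 11 = **1,037** features per (region, sequence), hence 3,111
conventional, 9,333 habitat (K = 3) and 12,444 fused features per patient.

**Selection cascade.** ICC(2,1) ≥ 0.90 against a second rater's masks →
train-fitted z-scoring → Welch-t/Mann–Whitney filter at p < 0.05 (gated by
Shapiro–Wilk) → Spearman pruning at |ρ| > 0.90 → mRMR (FCQ) → LASSO
logistic with 10-fold cross-validated λ.

**Models and evaluation.** Univariable→multivariable logistic screening
defines the clinical feature set (for a binary predictor the univariable
odds ratio equals the 2×2 cross-product ratio `ad/bc`); four XGBoost
classifiers (clinical / conventional / habitat / combined) are tuned by
grid search under 5-fold stratified CV on mean AUC. Evaluation implements
ROC/AUC with DeLong variance `Var = Var(V10)/m + Var(V01)/n`, paired
DeLong tests, calibration with the Hosmer–Lemeshow C statistic, decision
curves `NB(p_t) = TP/n − FP/n · p_t/(1−p_t)`, threshold-0.5 confusion
metrics, and exact tree-Shapley attributions (log-odds space, local
accuracy `base + Σφ = margin`).

## Worked example

```r
library(habitatr)

cfg <- pipeline_config(
  synthetic = synthetic_config(n_patients = 48,
                               grid_shape = c(22L, 22L, 22L), seed = 7),
  features  = feature_bank_config(families = c("shape", "firstorder"),
                                  filters = "original"),
  selection = selection_config(mrmr_k = 10, lasso_folds = 5),
  boost     = boost_config(max_depth = 2L, eta = c(0.1, 0.3),
                           nrounds = c(30L, 60L), subsample = 1,
                           cv_folds = 3L),
  use_icc = FALSE, seed = 7)

pp <- run_pipeline(cfg)
print(pp$habitats$model)
#> Habitat model: K = 3 clusters over 3 pooled channels
#>   silhouette by k:
#>     2     3     4     5     6     7     8     9    10
#> 0.475 0.598 0.539 0.505 0.462 0.438 0.386 0.353 0.356
#>   ordering: ascending mean DCE intensity
summary(pp$bundle)
#>          model auc_train  auc_test
#> 1     clinical 0.9871324 0.8125000
#> 2 conventional 1.0000000 0.9464286
#> 3      habitat 1.0000000 0.8660714
#> 4     combined 1.0000000 0.8750000
head(global_importance(pp$explanation), 4)
#>         DCE_habitat3_original_firstorder_Uniformity
#>                                               1.116
#>             DCE_habitat3_original_firstorder_Energy
#>                                               0.748
#> DCE_original_firstorder_RobustMeanAbsoluteDeviation
#>                                               0.520
#>                        DCE_original_firstorder_Mean
#>                                               0.077
```

The silhouette trace selects K = 3, matching the three planted habitats;
the selected features and Shapley ranking recover the planted signal
(rim-habitat DCE enhancement and composition). Single-seed test AUCs at this size are
noisy — the stable statement, asserted by the acceptance checks over ten
generator seeds, is the expected ordering
`AUC(combined) ≥ AUC(habitat) ≥ AUC(clinical)`.

`write_cohort()` exports any generated cohort as per-patient NIfTI volumes
plus a clinical CSV and JSON manifest; `inst/scripts/habitat-alnm.R` is a
thin command-line front-end over the same functions.

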