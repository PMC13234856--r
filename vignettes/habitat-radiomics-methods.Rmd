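---
title: "Habitat radiomics for ALNM prediction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat radiomics for ALNM prediction: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Axillary lymph node metastasis (ALNM) drives surgical and systemic treatment
decisions in breast cancer, but its preoperative assessment is invasive
(sentinel node biopsy or dissection). `habitatr` implements a habitat-radiomics
pipeline that predicts ALNM from three co-registered MRI sequences — T2-weighted
(T2WI), diffusion-weighted (DWI) and dynamic contrast-enhanced (DCE) — plus
routine clinicopathological covariates. The central scientific idea is that
tumors are not homogeneous: spatially coherent subregions ("habitats", e.g. a
hypoxic–necrotic core, a cellular transition zone and a vascularised rim) carry
information that whole-tumor averaging destroys.

The pipeline has eight stages, each exposed as ordinary R functions and
orchestrated by `run_pipeline()`:

1. `generate_cohort()` — synthetic mpMRI cohort with planted habitat structure
   (patient data of this kind are private, so the package ships a generator
   that emulates the study conditions);
2. `preprocess_cohort()` — isotropic resampling, VOI percentile clipping,
   per-patient per-sequence z-scoring;
3. `build_habitats()` — "extract-then-pool": voxel-level sliding-window
   features, SLIC supervoxels, mean pooling, one population K-means with
   silhouette-selected K;
4. `extract_cohort_tables()` — a 1,037-feature radiomics bank per
   (region, sequence);
5. `select_features()` — ICC, univariate testing, Spearman pruning, mRMR,
   LASSO;
6. `build_bundle()` — four gradient-boosted classifiers (clinical,
   conventional, habitat, combined);
7. `evaluate_bundle()` — ROC/AUC with DeLong comparisons, calibration +
   Hosmer–Lemeshow, decision curves, threshold-0.5 confusion metrics;
8. `explain_model()` — exact tree-Shapley attributions of the combined model.

# The synthetic cohort generator

The generator is first-class, tested code, not a fixture. It emulates:

* **Cohort structure.** 125 patients by default, 66 ALNM vs 59 non-ALNM,
  split 87/38 by a stratified 70/30 rule (`floor(0.7 n)` to training,
  per-class floors topped up by largest remainder).
* **Clinical effects.** Covariates are drawn *class-conditionally* from
  published-scale group summaries (e.g. ALN length 18.4 ± 11.9 mm in ALNM vs
  5.0 ± 5.9 mm in non-ALNM; washout-type time–intensity curves in 76% of
  cases vs 42% of controls; grade G3 in 79% vs 41%). This retrospective
  (case–control) formulation was chosen over a prospective logistic link
  because it reproduces the class counts exactly and makes the group means
  converge to their configured targets — both properties the test suite
  asserts. ALN length uses a gamma distribution moment-matched to its
  (mean, SD) so that support is nonnegative without biasing the mean.
* **Tumor geometry.** An ellipsoid with a smoothed random boundary, placed in
  a tumor-centred crop whose background has parenchyma-like signal (mean 0.4,
  spatially correlated SD ≈ 0.36). Tumor extent is capped at 30% of the grid
  edge: in a real field of view the tumor occupies a small fraction of the
  volume, and without that property per-patient whole-volume z-scoring
  would hinge on tumor fraction and misalign intensities across patients.
* **Habitats.** Three contiguous sub-lobes formed by banding a smooth
  radial + lateral field (a core-to-rim gradient with a random lateral tilt).
  Thick lobes rather than thin concentric shells are used deliberately:
  2–3-voxel-thick outer shells would be straddled by any supervoxel of
  realistic size, turning pooled vectors into mixtures and destroying
  cluster structure. Each habitat has a distinct per-sequence intensity
  pattern with a biological reading — fluid-rich core (high T2WI),
  cellular transition (high DWI), vascularised rim (high DCE) — plus
  spatially correlated noise with habitat-specific correlation lengths, so
  texture (not only means) differs between habitats.
* **Planted label signal.** Two imaging effects couple the ALNM label to the
  tumor: the rim-habitat volume fraction (0.42 vs 0.25, SD 0.07) and an
  extra rim DCE enhancement (+0.15 vs −0.15, SD 0.15; half of it echoed in
  DWI). Angiogenic, strongly enhancing rims in metastatic disease are the
  biological motivation. Both effects are per-patient draws, so the signal
  is noisy at realistic levels.
* **A second rater.** `perturb_mask()` applies a random over- or
  under-segmentation bias (each voxel of the 1-mm morphological shell
  toggled with probability ½ — full-shell erosion would push Dice below 0.7
  on small lesions, which no plausible second reader does) plus 15%
  boundary-voxel noise, keeping the largest connected component.

**What the generator does not emulate:** pharmacokinetic DCE dynamics, coil
or bias-field artifacts, scanner differences, partial-volume effects at
acquisition resolution, or deformable misregistration between sequences
(volumes are born co-registered). Passing tests therefore demonstrate the
pipeline's correctness and its behaviour under controlled, recoverable
signal — not clinical performance on real data.

# Preprocessing

Fixed order: resample → clip → z-score.

* Resampling to 1 × 1 × 1 mm (linear for images, nearest-neighbour for
  masks; output shape `ceiling(shape · spacing_in / spacing_out)`, voxel
  `i` centred at `(i−1)·spacing`).
* Percentile clipping inside the tumor VOI at (0.5, 99.5) by default — the
  exact percentiles are a configurable convention, chosen as a standard
  outlier trim.
* Z-scoring per patient and sequence with the population (1/N) SD
  convention, fixed package-wide. The default scope is the whole volume;
  a `"voi"` switch exists because the scope changes feature values (not
  counts) and is not universally standardised.

# Habitat generation: extract-then-pool

Voxel feature maps are local first-order statistics (mean, SD, skewness,
kurtosis, entropy, energy) of each sequence over a 3³ window intersected
with the tumor mask — 18 channels. Entropy uses an 8-bin histogram with
edges fixed per sequence over the tumor; windows with near-zero SD get
skewness/kurtosis 0.

SLIC supervoxels are seeded on a physical grid with spacing
`S = (V/n)^{1/3}` (default ≈ 1 supervoxel per 100 mm³, floored at 12 per
tumor) and assigned by `d = mean squared channel difference +
compactness · (d_spatial/S)²` with compactness 0.1. Two numerical choices
matter and are deliberate:

* channels enter the distance on their native (z-scored-intensity) scales —
  re-standardising each channel to unit variance would amplify flat-region
  noise and drown the spatial term;
* only the local-mean channels enter the SLIC distance and the habitat
  K-means by default (configurable). Higher-moment statistics of a 27-voxel
  window are noise-dominated; including them flattens the silhouette
  profile and destabilises the selection of K. All 18 channels are still
  pooled and available.

Connectivity is enforced SLIC-style afterwards: disconnected fragments are
split and any component smaller than `S³/8` voxels is merged into its
largest-contact neighbour.

Pooling is the arithmetic mean of member-voxel vectors (an exact identity in
the tests). One K-means is fitted on the pooled vectors of *all training
patients* (k = 2..10, 10 restarts, fixed seed, ties toward smaller k), with
mean silhouette selecting K. Population-level clustering guarantees that
"habitat 2" means the same thing in every patient; test patients are
assigned by nearest centroid. Clusters are ordered by ascending mean DCE
intensity, so habitat 1 reads as the low-enhancement core and habitat K as
the vascularised rim.

# The feature bank

14 shape + 93 intensity features (18 first-order, 24 GLCM, 14 GLDM, 16
GLRLM, 16 GLSZM, 5 NGTDM) on the original image, 8 single-level undecimated
wavelet subbands (coif1, symmetric boundaries) and 2 Laplacian-of-Gaussian
responses (σ = 3 and 4 mm, scale-normalised, zero-DC second-derivative
kernels): 14 + 93 × 11 = 1,037 per (region, sequence). "Eight decomposition
levels" of a wavelet transform is read as the 8 L/H subbands of a
single-level 3-D transform — the standard radiomics convention and the only
reading consistent with the 1,037 count.

Numerical conventions, stated once and tested:

* discretization by **fixed bin count** (32) inside each region — a fixed
  bin *width* is ill-posed on z-scored inputs;
* GLCM and GLRLM are direction-averaged over the 13 unique 3-D offsets
  (feature values averaged, not matrices);
* undefined features on degenerate regions get documented fallbacks (GLCM
  correlation = 1 on constant regions, MCC = 1, nonfinite run/zone features
  → 0) — never silent NaN;
* surface area counts exposed voxel faces. This makes the sphericity of a
  cubic region exactly `(36π)^{1/3}/6 ≈ 0.806` but overestimates curved
  surfaces (a digital ball scores ≈ 2/3); mesh-based implementations will
  differ on curved shapes, a documented divergence. Mesh volume equals voxel
  volume under this convention, and maximum diameters use voxel centres;
* regions below `min_region_voxels` (10) yield missing-flagged vectors with
  an unchanged schema; selection later drops features with missing values
  at the ICC stage, and any residual missing habitat features are
  median-imputed with training-split medians at modelling time.

Pool widths follow identically: 1,037 × 3 sequences = 3,111 conventional,
× K habitats = 9,333 for K = 3, and 12,444 fused.

# Feature selection

The cascade (each stage fitted on the training split only; survivors nested):

1. **ICC(2,1)** — two-way random effects, absolute agreement, single rater —
   between the two raters' feature tables, threshold 0.90. Computed from the
   two-way ANOVA mean squares; zero between-subject variance returns 0 with
   a flag.
2. **z-scoring** of surviving features with training means / population SDs.
3. **Univariate filter** at p < 0.05: Welch t-test when Shapiro–Wilk keeps
   normality in both classes (α = 0.05), Mann–Whitney U otherwise. No
   multiplicity correction is applied, reproducing the published procedure;
   the pretest-gated choice makes the realised type-I rate ≈ 0.055 rather
   than exactly 0.05, a property of the procedure itself that the
   acceptance checks measure.
4. **Spearman pruning** at |ρ| > 0.90, greedy by ascending univariate p —
   the tie-break keeps the most outcome-relevant member of each correlated
   block; deterministic with name-order tie-breaks.
5. **mRMR**, FCQ variant (ANOVA-F relevance over mean |Pearson ρ| redundancy),
   k = 30. FCQ is deterministic and well-defined on continuous features,
   unlike mutual-information estimators at these sample sizes.
6. **LASSO-penalised logistic regression** over glmnet's λ path;
   λ* = argmin mean 10-fold cross-validated binomial deviance (the "optimal
   features" reading, not the 1-SE rule), stratified folds fixed by seed;
   survivors are the nonzero coefficients at λ*.

# Models

Univariable logistic regression screens the clinical covariates (categorical
covariates expanded against stated reference levels: inflow/platform TIC,
BI-RADS 4a4b, grade G1–2, Ki-67 < 20%); variables with p < 0.05 enter a
multivariable fit whose significant terms define the clinical model's
features. On very small cohorts where nothing clears the screen the single
smallest-p variable is used, with a warning.

Four XGBoost binary classifiers are tuned by exhaustive grid search
(default grid: depth {2,3,4} × η {0.05,0.1,0.3} × trees {50,100,200} ×
subsample {0.8,1}) under 5-fold stratified CV on mean validation AUC, ties
toward fewer trees, then shallower depth, then smaller η; the winner is
refit on the full training split. Within each (depth, η, subsample) cell a
single model is trained to the largest tree count and evaluated at the
smaller counts by prediction truncation — mathematically identical to
training each count separately, at a third of the cost. The combined
model's radiomics features come from the fusion-pool cascade, plus the
clinical features; an assertion refuses test-tagged rows inside the tuner.

# Evaluation and interpretation

All statistics are implemented from their definitions and cross-checked in
the tests against independent oracles (brute-force pair counting for AUC,
pROC for DeLong, hand arithmetic for Hosmer–Lemeshow and confusion
metrics):

* AUC as the tie-corrected Mann–Whitney statistic; DeLong placement-value
  variance and normal-approximation CIs clipped to [0, 1];
* paired DeLong z-test, two-sided, no multiplicity correction across model
  pairs (matching the published analysis); zero variance of the difference
  returns p = 1 with a flag;
* Hosmer–Lemeshow C statistic on deciles of predicted risk (ties share a
  bin, empty bins merge with a warning), df = g − 2;
* decision curves `NB(p_t) = TP/n − FP/n · p_t/(1−p_t)` on the grid
  0.01–0.99 (step 0.01) with treat-all/treat-none references;
* confusion metrics at threshold 0.5 with NA (never NaN) on zero
  denominators.

Shapley attributions are exact path-dependent tree-Shapley values in
log-odds (margin) space, the standard for tree ensembles. Local accuracy —
base value plus the attribution sum equals the margin — holds for every
sample up to the engine's single-precision arithmetic. Test samples are
explained against the training background implicit in the trees. The test
suite additionally enumerates all 2^M feature subsets of small models and
checks exact agreement with the cover-weighted value function; this
equivalence requires (and the tests assert) that no feature repeats along a
root-to-leaf path, which is where the path-dependent algorithm and the
subset game provably coincide.

# Problem sizes used by the tests and the acceptance script

Repeated end-to-end experiments use a reduced configuration
(`experiment_config()`): 48 patients on 22³ grids with a shape + first-order
original-image bank and a compact tuning grid. These sizes were chosen so a
single replicate is a faithful miniature of the full pipeline — every stage
runs, the planted signal is at full strength — while ten replicates remain
cheap. Reported multi-seed quantities are the mean test AUC of the four
models (whose expected ordering combined ≥ habitat ≥ clinical is the
package's model-information property) and the modal silhouette-selected K
(which recovers the three planted habitats). The full 1,037-feature bank is
exercised on small cohorts where pool widths (3,111 / 9,333 / 12,444) are
verified by actual extraction.

# Known limitations

* The feature bank's numeric conventions (bin count, voxel-face surface
  area, undecimated coif1 wavelets, zero-DC LoG kernels) are internally
  consistent and tested, but reference implementations with mesh surface
  areas or decimated wavelets will produce different values for the same
  names.
* Silhouette-based K selection is only as good as the pooled-feature
  geometry; on real data with weak habitat contrast it may prefer small K.
* The synthetic cohort cannot validate clinical performance; headline AUCs
  on it reflect the planted effect sizes, not patient populations.
* SLIC is a local optimiser seeded on a regular grid; supervoxel boundaries
  on flat regions are arbitrary up to the spatial term.
* In the synthetic cohort the conventional whole-tumor model also performs
  well: the planted rim effects shift whole-tumor averages too, and the
  generator has none of the nuisance heterogeneity that penalises
  whole-tumor averaging on real data. The ordering property asserted by
  the acceptance checks is therefore combined ≥ habitat ≥ clinical, which
  is the part the planted signal controls.
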