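---
title: "Habitat imaging and radiomic signatures for multi-phase CT tumor grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat imaging and radiomic signatures for multi-phase CT tumor grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitatct)
```

## The problem

Clear cell renal cell carcinoma (ccRCC) is graded on the WHO/ISUP four-tier
nuclear scale; the binary distinction between low (I–II) and high (III–IV)
grade drives surgical planning, but the reference standard is post-operative
histology. Habitat imaging tries to predict the grade preoperatively from
multi-phase contrast CT by exploiting *intratumoral heterogeneity* (ITH):
rather than summarising the whole tumor with one set of descriptors, the
tumor volume is partitioned into internally homogeneous subregions
("habitats" — e.g. enhancing viable rim, intermediate zone, hypoenhancing
necrotic core), and quantitative features are computed per subregion. The
package implements that analysis end to end, together with a synthetic
multi-phase CT cohort generator so every stage can be exercised and tested
without patient data.

## Pipeline overview

1. **Preprocessing** (`resample_fixed()`, `window_hu()`). All volumes are
   resampled to a fixed isotropic grid and clipped to the display window
   `level ± width/2` (default 300/25 HU, i.e. `[-125, 175]`).
2. **Habitat mapping** (`local_feature_map()`, `select_k_by_ch()`,
   `cluster_habitats()`, `knn_fill()`). Every tumor voxel receives a
   19-dimensional vector of first-order statistics of its 5×5×5
   neighbourhood; per patient and phase, K-means partitions the z-scored
   vectors into `k` habitats, with `k` selected cohort-wide by the
   Calinski–Harabasz index over `k = 3..10`.
3. **Peritumoral geometry** (`dilate_ring()`). Ring masks at 1/3/5 mm
   physical radii via Euclidean-distance-transform thresholding.
4. **Feature extraction** (`derive_images()`, `extract_region_features()`,
   `build_feature_tables()`). An IBSI-style engine computes 1,106 features
   per region and phase: 14 shape descriptors plus 91 intensity/texture
   features (18 first-order, 22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM,
   5 NGTDM) on each of 12 image types (original, 8 stationary coiflet-1
   wavelet sub-bands, Laplacian-of-Gaussian at σ = 1, 2, 3 mm). Four phases
   give 4,424 columns for the whole-tumor table and each ring table, and
   4,424 × 3 = 13,272 for the pre-fusion habitat (ITH) table.
5. **Selection cascade** (`run_selection_cascade()`). Two-reader ICC(2,1)
   filter at 0.8 (skipped for the ITH branch, whose subregions come from
   unsupervised clustering rather than manual delineation), greedy Pearson
   redundancy pruning at |r| > 0.9, mRMR to a 64-feature budget, then an
   L1-penalised logistic path with the penalty chosen by 10-fold
   cross-validated deviance. The linear predictor of the retained features
   is the *rad-score*.
6. **Signature modelling** (`train_signature()`, `clinical_screen()`,
   `combined_model()`). Per branch (whole-tumor, Peri1/3/5 mm, ITH,
   clinical), classifiers are grid-searched by 5-fold cross-validated AUC
   with SMOTE class balancing applied inside training folds only. Clinical
   covariates pass a univariate-then-multivariate logistic screen at
   p < 0.05. The final integrated model is a logistic fit on the ITH score,
   the best peritumoral score, and the screened covariates; its
   coefficients export to a nomogram.
7. **Evaluation** (`auc_delong()`, `delong_test()`, `threshold_metrics()`,
   `hosmer_lemeshow()`, `calibration_curve()`, `decision_curve()`,
   `nomogram_export()`, `cohort_balance_check()`).

`run_pipeline()` executes all stages from two config objects and is a pure
function of its seeds: a rerun with the same configuration is bit-identical
for the deterministic stages.

## Key tunable parameters

| parameter | default | meaning |
|---|---|---|
| `target_spacing_mm` | 1 mm isotropic | working grid; isotropy makes mm-defined ring radii and 3D texture kernels well-posed |
| `window_width` / `window_level` | 300 / 25 HU | display window applied before filtering and intensity features |
| `window` (voxels) | 5 | moving-window edge for the per-voxel feature map |
| `k_range` | 3..10 | candidate habitat counts for CH selection |
| `ring_radii_mm` | 1, 3, 5 | peritumoral expansion radii |
| `bin_width` | 25 HU | fixed-width discretization for histogram/texture features |
| `icc_threshold` | 0.8 | two-reader reproducibility cut |
| `pearson_threshold` | 0.9 | redundancy cut |
| `mrmr_k` | 64 | mRMR budget |
| `lasso_cv_folds` | 10 | folds for the penalty path |
| `cv_folds` (models) | 5 | folds for the hyperparameter grid search |

## Design choices where the design was open

**The 19 local features.** The moving-window vector is fixed as: mean,
median, min, max, range, variance, coefficient of variation, skewness,
kurtosis, energy, entropy, uniformity, RMS, mean absolute deviation, IQR,
and the 10/25/75/90 percentiles. Entropy and uniformity use 16 fixed bins
spanning the display window so they are comparable across voxels and
patients. All 19 are first-order, so a 125-voxel sample supports them; the
set includes the canonical texture pair (entropy, energy) by construction.

**Feature-inventory reconciliation.** The printed totals (1,106 per region;
216 first-order; 14 shape) force 12 intensity image types × 91 non-shape
features. We adopt first-order 18, GLCM 22 (the canonical 24 without
SumAverage — redundant with JointAverage for symmetric matrices — and the
expensive MCC), GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5, and 12 image types =
1 original + 8 one-level stationary coiflet-1 sub-bands + 3 LoG scales.
Texture matrices merge the 13 unique 3D directions before feature
computation; discretization is fixed-bin-width (25 HU) on the windowed
image, relative to the region minimum.

**Surface area.** Shape features need a surface-area estimate that is
asymptotically unbiased (voxel-face counting overestimates a sphere's area
by ~50%, which would wreck sphericity). We integrate the gradient magnitude
of the Gaussian-smoothed occupancy function (the coarea formula); on a
10 mm digital ball at 1 mm spacing this is within a few percent of
`4*pi*r^2`, and sphericity of a ball converges to 1.

**K-means initialisation.** `stats::kmeans` with 10 random restarts
(falling back to Lloyd iterations if a restart degenerates) replaces a
k-means++ single start: with ≥10 restarts on z-scored voxel vectors the
best-of-restarts inertia is at least as reliable as one seeded start, and
it keeps the clustering inside base R. Labels are renumbered by ascending
windowed-intensity mean so that label 1 is always the least-enhancing
habitat and labels are comparable across patients.

**Per-phase clustering.** Each phase's VOI is clustered independently and
`k` is selected per phase (with disagreements resolved by the overall mean
CH curve); the phases of multi-phase CT are analysed as separate sequences
rather than stacked per voxel.

**Pearson keep-order and the mRMR criterion.** Both are fixed for
determinism: pruning visits features by descending absolute point-biserial
correlation with the label and drops a feature when |r| with any kept
feature exceeds the threshold; mRMR uses the difference criterion
`|r(f, label)| − mean_s |r(f, s)|` with the max-relevance feature first.

**ICC flavour.** Two-way random effects, absolute agreement, single
measurement — ICC(2,1) — computed from the two-way ANOVA mean squares.

**Threshold rule.** The operating point for accuracy/sensitivity/
specificity/PPV/NPV is Youden's J maximised on the training split and
frozen for validation/test. Degenerate ratios (0/0) are reported as 0 and
flagged rather than dropped.

**Hosmer–Lemeshow df and reporting.** The test uses deciles of risk and
`groups − 2` degrees of freedom, the convention calibrated for fitted
probabilities; both the statistic and the p-value are always reported,
since "HL value" is ambiguous between the two in parts of the literature.
Under a correctly specified fitted logistic null the p-values are uniform
(checked by simulation in the test suite).

**Peritumoral rings.** The ring is *not* masked against body or perirenal
structures by default (a config choice); rings are clipped to image bounds
and are disjoint from the tumor by construction.

**Gradient-boosting variants.** Two boosted-tree model kinds are provided:
depth-wise trees, and a leaf-wise histogram-based variant
(`grow_policy = "lossguide"`), covering the two dominant growth strategies
in modern gradient boosting. Grids are deliberately small (depth {2, 3},
learning rate {0.05, 0.1}, 100/300 rounds) to keep a desk-scale run fast.

## The synthetic cohort generator

`generate_phantom()` builds a body ellipsoid containing a lobulated,
roughly spherical tumor partitioned into three concentric-but-blobby
habitats (necrotic core, intermediate zone, enhancing rim), with per-phase
mean intensities emulating a hypervascular renal tumor (strong rim
enhancement in the corticomedullary phase, washout later, near-water core),
a peritumoral enhancement gradient decaying over 5 mm, and air at
−1000 HU outside the body. A second reader's mask is simulated by
re-thresholding the signed distance function at a smooth random field
(`perturb_mask()`), which produces spatially correlated boundary
disagreement whose Dice overlap decreases with the displacement scale.

Grade acts on *habitat composition* (core volume fraction +0.15) and
*texture* (per-habitat noise SD ×1.5), not on tumor size, so subregion
features rather than volume carry the signal. Clinical covariates carry
grade effects in the directions seen in renal cohorts (male excess
+0.5 log-odds, age +6 y, platelets +30 g/L), plus nuisance covariates
(hematuria, tumor side) with no effect so covariate screening has true
negatives. All effect magnitudes are calibration constants of the
generator, not estimates of any real cohort.

**Between-patient variability.** Each patient additionally draws a global
intensity offset (sd 10 HU — calibration/enhancement-timing differences),
independent per-habitat mean jitter (sd 8 HU), log-normal jitter of the
habitat fractions (scale 0.25) and of the texture SDs (scale 0.2), plus a
±15% tumor-radius factor at the cohort level. Without these random
effects every phantom of a grade is statistically identical and any fixed
grade effect is perfectly separable (every branch reaches AUC 1.0), which
makes model comparison meaningless; with them, discrimination is
imperfect in a controlled way.

**What the generator does not emulate — and what that implies.** Habitats
are concentric and radially ordered; real ccRCC habitats are spatially
scattered and irregular. A consequence worth stating plainly: in a
concentric phantom, habitat-level effects remain visible to *whole-tumor*
statistics (a composition shift moves the whole-tumor mixture variance; a
texture change moves whole-tumor local-difference features, diluted only
by the volume fraction), so the empirical finding on real tumors that
subregion signatures beat whole-tumor signatures need not reproduce here —
and in our replicate studies it does not reliably do so. Passing tests on
this generator therefore validate the *machinery* (counts, contracts,
estimators, leakage-freedom, calibration), not claims about real ccRCC
biology; scanner physics, dose, motion, and contrast kinetics beyond
per-phase mean shifts are likewise out of scope.

## Numerical choices and degenerate inputs

- K-means: 10 restarts, 300 iterations; ties and empty clusters handled by
  `knn_fill()`, which dissolves clusters under 5 voxels and reassigns their
  voxels by majority vote of the 5 nearest labelled voxels (physical
  distance, ties to the smaller label).
- CH scores are undefined for `k ≥ n_voxels`; such maps are excluded from
  the cohort mean with a warning.
- Regions with fewer than 2 voxels have no defined shape/texture; in the
  habitat table they contribute cohort-median-imputed columns (logged)
  rather than dropping the patient.
- Constant features: dropped before Pearson pruning; zero-variance ICC is
  undefined and the feature is dropped; z-scoring maps zero-variance
  columns to 0.
- The LASSO at very large penalties keeps nothing: the signature then
  scores every patient at the intercept, and downstream modelling falls
  back to the rad-score as the single feature.
- SMOTE requires at least 2 minority samples; model-selection folds that
  lose a class are skipped (their AUC is undefined).
- `perturb_mask()` redraws at half magnitude (up to 3 times) if a draw
  empties or nearly-disjoints the mask, then errors.

## Problem sizes used by the test suite

The suite exercises the full stack at deliberately small sizes: phantoms of
20–30 voxels per axis at 1.5–2 mm spacing (tumors of a few hundred to a few
thousand voxels), cohorts of 10–40 patients for imaging stages and 200–513
patients for clinical-only stages, 10 phantoms for the cluster-number
recovery study, 20 replicates for branch-comparison studies, and 500
replicates for calibration-uniformity checks. The feature-count contracts
are verified at the full 12-filter inventory on a 4-phase phantom.

## Known limitations

- The feature definitions are IBSI-style but are not certified
  IBSI-compliant implementations; absolute values can differ from other
  engines (aggregation, discretization and interpolation conventions), so
  comparisons across engines should be made at the level of pipelines, not
  individual feature values.
- The wavelet and LoG responses use mirror padding; features of regions
  close to the volume boundary inherit that convention.
- The maximum-3D-diameter uses deterministically subsampled boundary
  voxels above 2,500 points (a lower bound, negligible at package scales).
- DICOM ingestion and cross-phase registration are out of scope; phases
  are assumed co-registered on a shared grid.
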