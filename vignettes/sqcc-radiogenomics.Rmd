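---
title: "Methods: CT radiomics and pathway radiogenomics for lung SQCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT radiomics and pathway radiogenomics for lung SQCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqccradiomics)
```

This vignette documents the model implemented by **sqccradiomics**, every
parameter with a default, the numerical choices, and what the synthetic-data
validation does and does not establish.

## 1. Problem

Given (a) contrast CT volumes of lung squamous cell carcinoma with tumor
segmentations, (b) non-contrast chest CT for lung densitometry, and (c) a
somatic mutation table, the analysis asks whether quantitative imaging
features are associated with the alteration status of five functional
signaling pathways — redox stress, apoptosis, proliferation,
differentiation, chromatin remodelers — and with disease-free (DFS) and
overall survival (OS).

## 2. Imaging feature model

### 2.1 Geometry and intensity conventions

Volumes are 3D arrays of Hounsfield units (HU) with positive voxel spacing
in mm (`image_volume`). ROI masks are binarized arrays of the same shape
(`roi_mask`); masks read from disk must match the volume's spacing to a
relative tolerance of 1e-4. ROI voxels are traversed in lexicographic
(i, j, k) order, so all reductions are deterministic. An empty ROI is an
error, never a silent NA.

### 2.2 Discretization

Texture features operate on discretized levels. `discretize(x, n_bins)`
maps ROI intensities to `1..n_bins` by equal-width binning over the ROI's
own [min, max]: `floor(n_bins * (x - min) / (max - min)) + 1`, with the
maximum clamped to `n_bins` and a constant ROI mapping to level 1.
**Default `n_bins = 32`**: coarse enough that GLCM/GLSZM matrices are well
populated for tumors of a few thousand voxels, fine enough to retain
contrast; it is the most common choice in the radiomics literature and is
configurable via `extraction_config()`.

### 2.3 The 52 tumor features

The exact feature inventory behind the published count of 52 is not fully
enumerable from available sources, so the package freezes a reference list
(`tumor_feature_list()`) that contains every feature named in the source
material and fills the remainder with standard members of each family:

- **global (2)** — `volume_ml` (voxel count × voxel volume);
  `mass_g` = Σ density × voxel volume with density (HU + 1000)/1000 g/cm³
  clipped below at 0 (air ≈ 0, water = 1).
- **histogram (15)** — mean, sd, min, max, range, energy, entropy,
  kurtosis, skewness, IQR, percentiles 2.5/25/50/75/97.5. Percentiles use
  R's default quantile type 7. `energy` is by default the **uniformity
  form** Σ pᵢ² over the discretized-level histogram (a probability, in
  (0, 1]); `extraction_config(energy_variant = "intensity")` switches to
  Σ x² over raw HU. Entropy is −Σ pᵢ log₂ pᵢ. Kurtosis is Fisher (excess)
  kurtosis from population moments; skewness/kurtosis are NA for constant
  ROIs.
- **lung cancer specific (4)** — mean of positive pixels (MPP) and the
  fraction, SD and (discretized) entropy of positive-HU voxels; all NA when
  the ROI contains no positive voxels.
- **shape (7)** — `surface_area_mm2`, sphericity, spherical
  disproportion, surface-to-volume ratio, maximum 3D diameter,
  compactness1, compactness2. Surface area is the **exposed-face area**:
  the summed area of mask-voxel faces not shared with another mask voxel.
  This is exact for axis-aligned boxes (a 10 mm cube gives exactly
  600 mm²) but overestimates smooth shapes by the staircase effect
  (≈ 1.5× for a sphere in the fine-voxel limit); features built on it are
  used comparatively across tumors, where the bias is shared. Spherical
  disproportion is A / (4πr²) with r = (3V/4π)^{1/3}; for a cube this has
  the closed form 6/(4π(3/4π)^{2/3}) ≈ 1.2407. Maximum 3D diameter is the
  largest pairwise distance between **surface** voxel centers (interior
  voxels cannot realize the maximum), which keeps the pairwise computation
  tractable.
- **local / GLCM (13)** — autocorrelation, cluster prominence/shade/
  tendency, contrast, correlation, dissimilarity, energy, entropy,
  homogeneity, inverse difference moment, maximum probability, sum
  average. The GLCM uses the 13 unique distance-1 3D offsets (each
  direction counted once with its first nonzero component positive); each
  offset's count matrix is symmetrized (C + Cᵀ), normalized, and the 13
  normalized matrices are averaged. Offsets with no in-mask pairs are
  dropped from the average; an ROI with no co-occurring pair at all is an
  error. `correlation` is NA when a marginal SD is 0 (single-level ROI).
- **regional / GLSZM (11)** — small/large zone emphasis, intensity and
  size-zone variability, zone percentage, low/high intensity emphasis and
  the four low/high × small/large combinations. Zones are 26-connected
  components of equal level; `size_zone_variability` = Σₛ(Σ_g c)²/N and
  `intensity_variability` = Σ_g(Σₛ c)²/N, i.e. the package equates
  "intensity variability" with the gray-level non-uniformity of the
  standard GLSZM formulation. Connected components are resolved with
  `igraph::components` over an edge list built by vectorized array shifts.

`extract_all()` evaluates the six groups independently; a failing group
raises "feature group 'X' failed" naming the group.

### 2.4 Emphysema features (11)

`segment_lungs()` thresholds at HU < −300 (default) to find air-like
voxels, removes components touching the volume border (exterior air),
keeps the two largest 26-connected components, and assigns **right** to
the component with the smaller centroid x-index (radiological convention:
patient right on image left). `emphysema_features()` then reports, for
total/right/left lung: volume (ml), emphysema volume (ml), and the
emphysema index — the percentage of lung voxels **at or below −950 HU
(inclusive)** — plus the normal (non-emphysematous) lung volume and
percentage, 11 features in all. The −950 threshold is
the standard densitometric definition; inclusivity matters for synthetic
volumes with voxels exactly at the threshold and is pinned by tests.

### 2.5 Clinicoradiological feature set (73)

`clinicoradiological_feature_list()` = 10 clinical features (age, sex,
smoking status, pack-years, T/N/M stage, overall stage, adjuvant and
palliative treatment indicators) + 52 tumor + 11 emphysema features, in
8 categories. Smoking status is coded as a single ordinal column
(never/former/current = 0/1/2) so that each feature contributes exactly
one univariate p-value to the selection rule; binary clinical variables
are 0/1 indicators.

## 3. Genomics

`read_mutations()` accepts a TSV with `patient_id`/`gene`/`variant_class`
columns or their MAF aliases (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
`Variant_Classification`) and drops `Silent` variants. The default
pathway map assigns NFE2L2, KEAP1 → redox stress; TP53 → apoptosis;
PIK3CA, PTEN, RB1 → proliferation; SOX2, TP63, NOTCH1 → differentiation;
MLL2 → chromatin remodelers. The differentiation genes are a documented
placeholder so every pathway has at least one gene; supply a full map via
`read_pathway_map()` (YAML/JSON) for real analyses. A pathway is altered
when **at least one** of its genes is mutated (`min_genes` raises this).
Duplicate patient–gene rows and silent variants do not change counts.

## 4. Statistics

- **Univariate logistic** (`univariate_logistic`): `glm(binomial)` of the
  label on one predictor. Continuous predictors are z-standardized, so the
  odds ratio is **per SD**; binary predictors enter raw. Wald CIs. Flags:
  `constant` (no fit), `insufficient` (fewer than 10 observations or a
  single-class label), `separation` (glm convergence warning or SE > 50) —
  flagged fits are reported but never selected.
- **Selection rule** (`select_per_category`): within each feature
  category, keep the single feature with the smallest p-value, and only if
  p < 0.2 (strict; p = 0.2 is not selected). Ties break lexicographically
  by feature name, making selection deterministic.
- **Multivariate logistic** (`multivariate_logistic`): all selected
  features jointly; reports per-term ORs/CIs/p, the linear predictor, and
  the apparent AUC.
- **AUC** (`roc_auc`): the Mann–Whitney estimator with midranks,
  orientation fixed (higher score ⇒ positive class), so values below 0.5
  are possible and meaningful. Cross-checked against `pROC` with
  `direction = "<"` in the test suite.
- **Cox** (`univariate_cox`, `multivariate_cox`): `survival::coxph` with
  Efron ties; monotone-likelihood (infinite-coefficient) fits are flagged
  analogously to separation. `survival_auc` is the AUC of the linear
  predictor against the event indicator — a crude concordance-style
  summary that ignores censoring times; it is reported as such.
- **Smoking association** (`smoking_association`): Fisher's exact test on
  the dichotomized table and a Wilcoxon rank-sum test on pack-years.

A selection threshold of 0.2 is deliberately liberal — the univariate
stage is a screen, not a test; inference happens in the multivariate
model at `alpha = 0.05`. Both are configurable in the run config.

## 5. Synthetic data generator

All generators take a `seed` and save/restore `.Random.seed`, so they are
reproducible and side-effect free.

- **Tumor phantom**: ellipsoid (default semi-axes 12/10/8 mm in a 64³
  volume at 1 mm spacing) of Gaussian soft-tissue HU (mean 40, SD 20) in a
  −800 HU background, with an optional lower-density core.
- **Lung phantom**: a body ellipsoid (40 HU) in −1000 HU air containing
  two disjoint −850 HU lung ellipsoids; `make_lung_phantom(fraction)`
  sets **exactly** `round(fraction × n)` randomly chosen voxels per lung to
  −1000 HU, so the planted emphysema index is known by construction up to
  rounding (± half a voxel in each lung), not up to binomial noise.
- **Cohort** (`simulate_cohort`): imaging features are Gaussian with a
  configurable covariance (validated positive semi-definite); pathway
  labels follow logistic models whose intercepts reproduce realistic
  prevalences (≈ 37/81/56/25/49%) and whose slopes plant one known driver
  per pathway (e.g. `range` drives apoptosis with log-OR −1.0); survival
  times are Weibull proportional-hazards with feature-dependent linear
  predictors and exponential censoring; the mutation table is emitted from
  pathway-unique genes so `map_pathways` recovers the planted labels
  exactly. The truth (coefficients, drivers, labels) is returned alongside
  the data.

## 6. Validation: what the tests show

Oracle-first tests pin the numerics against independent implementations:
GLCM against an exhaustive nested-loop pair counter and GLSZM against a
stack-based flood fill (50 + 50 random instances on grids up to 8³),
histogram statistics against direct moment formulas, Fisher's exact
p against hypergeometric tail enumeration, AUC against `pROC`, shape
closed forms on cubes/boxes to 1e-9, and digitized-ball convergence for
volume. Calibration tests check that the logistic p-value is uniform
under the null (Kolmogorov–Smirnov over 200 replicates of n = 500), that
Cox CI coverage is nominal, that logistic/Cox coefficient recovery at
n = 2000 is within ±0.15 of truth, and that the bi-normal AUC matches
Φ(1/√2) within ±0.01 at n = 20000. A driver-recovery property test
verifies that planted per-category drivers are selected in ≥ 90% of 20
replicates at n = 1000. The pipeline tests check byte-identical rerun of
extraction and exact reproduction of the worked-example alteration
percentages end to end.

These sizes (≤ 8³ oracle grids, n up to 2000 for recovery, 20 replicates)
were chosen to keep the suite under a few minutes; they establish
correctness of the implementations and calibration of the estimators on
well-behaved synthetic data — **not** clinical validity, external
reproducibility of any published effect sizes, or performance under
distribution shift.

## 7. Limitations and open choices

- The 52-feature identity is a frozen reconstruction; formulas follow the
  standard radiomics definitions and any alternative inventory
  with the same category structure can be swapped in.
- `intensity_variability` is interpreted as GLSZM gray-level
  non-uniformity; other groups use the same name for the normalized
  variant.
- No resampling/interpolation: anisotropic voxels are handled by using
  physical spacing in geometric features, but texture offsets are
  lattice-step offsets, so strongly anisotropic volumes mix physical
  scales across directions. Resample upstream if this matters.
- The multivariate AUCs are apparent (training-data) AUCs with no
  cross-validation, matching the source analysis; treat them as
  optimistic.
- `survival_auc` ignores censoring times; a time-dependent AUC or
  Harrell's C would be preferable for real cohorts.
- Lung left/right assignment assumes standard radiological orientation;
  volumes in other orientations must be reoriented first.
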