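---
title: "fetrad: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fetrad: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetrad)
```

`fetrad` implements a complete FET-PET radiomics analysis for recurrent
glioblastoma: SUV-threshold tumor segmentation, a 135-feature radiomics
vector, phantom-based feature screening, and prognostic modelling of
time-to-progression (TTP), overall survival (OS) and recurrence location
(RL). This vignette records the models behind each stage, the parameters
that matter, and the choices made where the design was genuinely open.

## Segmentation model

The contouring chain is deliberately semi-automatic so that the only manual
inputs are the two background sphere positions and an optional exclusion
mask:

* SUV(Bg.) is the **mean of the two per-sphere mean SUVs**, not the pooled
  voxel mean: with unequal sphere sizes the pooled mean would be dominated
  by the larger sphere. The sphere diameter is a protocol constant exposed
  as `bg_diameter_mm` (default 30 mm, a typical cerebrum/cerebellum
  reference sphere; the value is a configuration parameter, not a claim
  about any specific protocol).
* `v_threshold` contains every voxel with SUV ≥ 1.8 × SUV(Bg.). The
  comparison is **inclusive**: a voxel exactly at the threshold is tumor.
  This is a boundary convention; either choice changes results only on sets
  of measure zero for continuous-valued images.
* Expert removal of non-tumor uptake (vessels, extracerebral enhancement)
  is represented by an explicit exclusion mask. The package never
  auto-classifies such regions — doing so would smuggle an unvalidated
  classifier into a pipeline whose point is transparent quantification.
* `v_pet3mm` is the exact Euclidean dilation of `v_pet` by 3 mm: a voxel is
  included iff its center lies within 3 mm of some `v_pet` voxel center.
  Anisotropic spacings are respected exactly (the dilation is the union of
  shifts by all integer offsets of physical length ≤ 3 mm, equivalent to
  thresholding the Euclidean distance transform), rather than approximated
  with a cubic structuring element.
* `v_petmax` is the connected component of `v_pet` containing the global
  SUV maximum. Connectivity is 26-neighbor (the common radiomics
  convention for 3D morphology), configurable to 6. Ties on the maximum are
  broken by the lexicographically first voxel index, making the operation
  deterministic.
* Sphere membership everywhere uses the voxel-center-inside test with no
  partial-volume weighting; volumes are therefore quantized at the voxel
  volume (8 μl at 2 mm spacing), and all geometric accuracy claims in the
  tests are stated up to a one-voxel surface shell.

## Intensity preprocessing

Texture matrices require discretized gray levels. Three intensity
representations feed the texture code:

* **Fixed bin width (FBW)**: `level = floor((SUV − min_ROI)/W) + 1` with
  W = 0.01 SUV, anchored at the ROI minimum. Anchoring at the minimum makes
  the level map invariant to adding a constant to the ROI and makes the bin
  count proportional to the ROI's SUV range (a range of 2.36 gives 237
  bins). A 10⁻⁶ guard inside the floor keeps values lying exactly on a bin
  edge in the upper bin despite floating-point rounding.
* **Equal-probability quantization (`Q` features)**: empirical quantile
  edges assign levels so each of 64 levels holds as equal a voxel count as
  ties permit (64 is the conventional default of histogram-equalization
  implementations). Unoccupied levels are renumbered away so downstream
  matrices never carry empty rows.
* **Wavelet band-pass (`WF_` features)**: a one-level separable 3D discrete
  wavelet transform (coiflet-1 by default; Daubechies-2 and Haar are
  available) splits the volume into eight sub-bands LLL…HHH. The six mixed
  sub-bands (those containing both a low-pass and a high-pass factor) are
  the "band-pass" set; they are reweighted 1:2 against LLL and HHH and the
  volume is reconstructed. Two open choices are resolved as follows and are
  configurable:
  * *Orientation of the ratio.* "1:2 between band-pass and other sub-bands"
    can mean attenuate or boost. The default (`attenuate`) fixes the
    non-band-pass weight at 1 — so the image mean, carried by LLL, is
    preserved — and halves the band-pass sub-bands; `boost` fixes the
    band-pass weight at 1 instead.
  * *Boundary and phase.* The transform uses symmetric boundary extension
    and is exactly invertible (unit ratio reproduces the input to < 10⁻¹⁰;
    the analysis half is verified against reference coefficients from an
    established wavelet library). Because a decimated transform is
    decimation-phase dependent, a single-orientation filter would give
    (slightly) different features when an axis is reversed. The filter
    response is therefore averaged over the eight axis-reversal
    orientations of the grid. The averaged operator is still linear, still
    the identity at unit ratio, and is exactly equivariant under all 48
    axis permutations/reflections — which is what makes the full feature
    vector invariant under grid symmetries, not just the texture-matrix
    aggregation.

  For feature extraction the filter is applied to the mask's bounding box
  padded by 8 voxels (the filter's spatial support), so WF features depend
  on a fixed local neighborhood and are translation invariant.

## The 135-feature catalogue

The catalogue is frozen in a versioned manifest
(`inst/extdata/feature_manifest.json`): 10 histogram statistics and 8 shape
descriptors on the raw volume, and 39 texture features (8 GLCM, 13 GLRLM,
13 GLSZM, 5 NGTDM) computed on each of the three intensity representations
(base, `Q`, `WF_`), giving 18 + 3 × 39 = 135 named entries. The manifest is
best-effort with respect to published 135-feature panels (full published
lists are not always available) and is guaranteed to contain every feature
the modelling stage references, including SZLGE, Busyness, the `Q`/`WF_`
variants of the co-occurrence and run/zone emphases, Eccentricity, GLV and
GLV2.

Conventions, following the standard 3D definitions:

* GLCM and GLRLM pool counts over the 13 unique direction offsets at
  Chebyshev distance 1 into one matrix before normalization ("merged"
  aggregation). Merging was chosen over per-direction averaging for
  rotational stability; with merged aggregation every matrix-derived
  feature is invariant under the 48 grid symmetries.
* GLSZM zones and NGTDM neighborhoods use 26-connectivity restricted to
  the mask.
* The "2"-suffixed names pair with the zone matrix: GLN2 and GLV2 are the
  GLSZM gray-level non-uniformity (normalized, in (0, 1]) and gray-level
  variance, while GLN and GLV are their GLRLM counterparts. `TS` is the
  NGTDM texture strength; `WF_TS` is that feature on the wavelet-filtered
  volume.
* Histogram variance, skewness and kurtosis use population (1/n) moments;
  `Kurtosis` is excess kurtosis. Histogram entropy and uniformity are
  computed on the FBW-discretized histogram.
* Shape eccentricity is `sqrt(1 − λ_min/λ_max)` of the voxel-center
  covariance eigenvalues; surface area is exposed-face counting. Both
  methods are recorded because competing definitions (mesh-based surface,
  ellipsoid-fit eccentricity) give systematically different values.
* Features undefined on degenerate regions (constant ROI, single voxel,
  zero denominators) propagate as `NA` flags and are excluded pairwise by
  the statistics downstream; they are never silently dropped.

## Feature screening

* **Scanner robustness**: paired Wilcoxon signed-rank per feature across
  contours rendered under two scanner profiles; robust ⇔ failure to reject
  at uncorrected α = 0.05. No multiplicity correction is applied here
  because the screen is *protective*: correcting would make it easier for
  features to pass. All 18 contours (6 spheres segmented at 40% of their
  maximum uptake + 12 background spheres) enter one test per feature. All
  pairwise differences zero gives p = 1 by convention.
* **Size dependence**: Spearman correlation with contour voxel count over
  background contours spanning 0.8–234 cc; size-dependent ⇔ p < 0.05 and
  |r| > 0.8. The absolute value is used — a strong negative correlation is
  equally disqualifying, even where conventions are sometimes printed as
  "r > 0.8".
* **Tumor vs background** uses the Bonferroni-corrected paired signed-rank
  test with K = the number of features actually tested (recorded in the
  report, not hard-coded).
* The exact signed-rank null distribution is used for n ≤ 25 pairs; above
  that, the normal approximation with tie correction.

## Prognostic models

* Univariate screening dichotomizes each feature at the cohort **median**
  (ties to the low group). The median is a deterministic, assumption-free
  cut; optimizing the cut-point would inflate type-I error.
* The log-rank test is the standard two-group 1-df chi-square
  (`survival::survdiff`); tests verify it against a hand risk-table
  enumeration to 10⁻¹².
* Bonferroni K is the number of features entering univariate testing after
  the robustness restriction; with K = 38 the threshold prints as 0.0013.
* Redundancy removal builds a graph with an edge wherever two candidate
  features are strongly Spearman-correlated (p < 0.05, |r| > 0.8);
  connected components are redundancy groups and each is represented by the
  member with the smallest log-rank p (ties by name). Transitive grouping
  is intentional: chains of pairwise-correlated features collapse to one
  representative.
* Signatures are **refit jointly**: the representatives enter one
  multivariate Cox model (Efron tie handling) per endpoint, rather than
  carrying over univariate coefficients — the standard practice when
  coefficients are to be interpreted together. The risk score is βᵀx; its
  median-split Kaplan–Meier log-rank p is attached to the fitted object
  because a signature is conventionally displayed as two survival curves.
  With 32 subjects and several covariates the events-per-covariate ratio is
  below comfort margins; the fit warns but does not fail, matching the
  pilot-study setting it models.
* The RL model is logistic regression with **imbalance-adjusted bootstrap**
  resampling: each bootstrap sample draws both classes at equal expected
  proportion, coefficients are bootstrap means, and AUC/sensitivity (at the
  probability-0.5 operating point) are 0.632+ combinations of apparent and
  out-of-bag performance. One estimator detail matters for calibration: the
  no-information cap on the out-of-bag error enters only the relative
  overfitting ratio R, not the final weighted average. Capping inside the
  average would pull a null predictor's AUC visibly above 0.5; with the cap
  confined to R, the null AUC is centered near 0.5 (verified to ±0.03 in
  the acceptance suite).

## The synthetic-data module

The generators define the study conditions under which the pipeline is
verified; they emulate, with known ground truth:

* **Brain PET**: uniform background (default SUV 1.0) plus spherical
  lesions with ≥ 1.8× contrast, convolved with a Gaussian PSF (default
  FWHM 4.8 mm, a typical clinical PET resolution) and additive Gaussian SUV
  noise clipped at zero, on 2 mm isotropic grids. Noise is additive
  Gaussian in SUV rather than Poisson in counts: the pipeline consumes
  reconstructed SUV images, and for robustness testing the noise level
  matters, not its deeper generative mechanism. Intra-lesion heterogeneity
  is a multiplicative `1 + g` field (`g` Gaussian, smoothed to a
  controllable correlation length, clipped at 0.1) — a minimal texture
  model chosen because no published lesion-texture model accompanies the
  study design; background SUV and contrast defaults (1.0, 2.5–4.5) are
  asserted as plausible clinical magnitudes, not derived quantities.
* **NEMA-like phantom**: six fillable spheres of 0.5–25 cc on a ring in a
  warm background, rendered under two scanner profiles. Geometry is
  simplified to spheres in a box (no lung insert or torso shell): only
  sphere and background statistics reach the downstream screens.
* **Cohorts**: features are Gaussian per name; TTP/OS times are exponential
  proportional-hazards draws (hazard `h₀·exp(βᵀ(x − μ))`; covariates are
  centered so `h₀` is the hazard of an average subject, a pure
  reparameterization of the baseline). Censoring is an independent
  exponential time whose rate is calibrated by root finding to the
  requested expected censoring fraction. The RL label is
  Bernoulli(logistic(γᵀ(x − μ))) and is defined only for subjects with an
  observed TTP event. A constant baseline hazard suffices because the Cox
  stage is hazard-shape agnostic: coefficient recovery, not hazard-shape
  recovery, is what the tests must certify.

What passing tests on these data do **not** show: robustness to
reconstruction artifacts, patient motion, partial-volume effects beyond
Gaussian blur, non-Gaussian noise, or real biological texture. The
generators are a correctness harness, not a scanner simulator.

## Problem sizes and numerical choices

The verification suite uses scaled problem sizes chosen to exercise every
code path with tight statistical bounds: 200 random ROIs (≤ 6³ voxels,
≤ 5 levels) for oracle equivalence at 10⁻¹⁰ relative error; 1000 null
cohorts of n = 32 for log-rank type-I calibration (95% binomial CI around
0.05); 500 cohorts of n = 500 for Cox bias (< 10%) and CI coverage
(92–98%); 100 cohorts of n = 200 for end-to-end driver recovery (≥ 90%
selection past Bonferroni at β = 1 per SD). The bundled demonstration run
(`fetrad_demo`) uses a 32-subject cohort on 44³ grids, 18 paired phantom
contours and 40 size-screen contours of 0.8–60 cc; these sizes are the
package's demonstration defaults, while the generators' own defaults keep
the full phantom ranges (102 contours, 0.8–234 cc).

Tie-breaks and degeneracies are all deterministic: lexicographic voxel
order for the SUV-maximum component, name order for equal log-rank p in
redundancy groups, ties-to-low-group at the median split, `NA` flags (not
errors) for degenerate features, and errors (not silent results) for empty
masks, empty PET volumes and non-convergent or separated Cox fits.

## Known limitations

* The feature catalogue's exact composition beyond the names the modelling
  stage uses is a reconstruction; alternative 135-feature panels exist.
* `V_PET3mm` features are computed on all voxels inside the dilated
  contour, including background admitted by the margin; no special
  background masking is applied there (the alternative was rejected as
  under-specified).
* The screening and modelling stages operate on any feature table, but the
  imbalance-adjusted bootstrap assumes both RL classes are reasonably
  represented; with fewer than ~5 subjects in a class the out-of-bag
  estimates become unstable.
* No clinical-covariate adjustment, external-cohort validation, or
  proportional-hazards diagnostics beyond convergence checks are included.
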