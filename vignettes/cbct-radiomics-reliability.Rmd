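---
title: "Reliability screening for preclinical CBCT radiomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability screening for preclinical CBCT radiomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctradiomics)
```

## The problem

Radiomic features — hundreds of quantitative descriptors of intensity,
texture and shape computed from a segmented region of a medical image — are
only useful as biomarkers if they are stable: a feature that changes when a
scan is simply repeated, or when an analyst picks a different bin width,
carries no biological signal. On small-animal irradiator cone-beam CT
(CBCT), where tube voltages are low (40–60 kV) and fields of view small,
this stability is far from guaranteed. `cbctradiomics` implements the full
screening workflow for this setting: it generates controlled synthetic
phantoms and scan–rescan pairs, extracts an 842-feature radiomic vector,
and classifies every feature's test–retest repeatability and
cross-parameter reproducibility with two-way mixed-effects intraclass
correlation coefficients (ICCs).

Everything runs from code; no scan archive is required. That makes the
package equally usable as a teaching tool for radiomics reliability
analysis and as a harness for stress-testing feature implementations.

## Synthetic phantoms and the imaging model

Three generators produce the study objects:

* **Mouse phantom** (`generate_mouse_phantom()`): an ellipsoidal
  soft-tissue body with two ellipsoidal lungs and a cylindrical spine.
  Compartment densities follow the tissue-equivalent phantom materials —
  bone 1.39, lung 0.68, soft tissue 1.01 g/cm³ — and map to scanner
  intensity through a fixed affine calibration
  (`intensity = 12000 · density + 4680`), chosen so soft tissue sits at
  16 800 scanner units, the scale observed for this class of scanner. The
  geometry is deliberately schematic: it exists to host ROI placements,
  not to be anatomically realistic.
* **Texture phantom** (`generate_texture_phantom()`): a homogeneous block
  with four parallel cylindrical inserts (air, solid water 1.05, PVC 1.47,
  acetal 1.52 g/cm³) whose mean intensities are set to the measured values
  for these materials (1861, 2940, 4138, 2917 scanner units). Note that
  measured intensity is not monotone in density here — acetal reads lower
  than PVC — which is exactly why the insert means are configured directly
  rather than through the density calibration.
* **Tumour cohorts** (`generate_tumour_cohort()`): two arms of subjects,
  each a soft-tissue background with a spherical tumour of 94.25 mm³.
  Tumour texture parameters are per-cohort; each subject additionally draws
  its own tumour mean intensity (`between_subject_sd`, default 600 scanner
  units) to emulate biological heterogeneity — without it, subjects within
  an arm would be statistically identical and the ICC's between-subject
  variance would vanish. Arm B's mean is shifted by
  `effect_size × texture_sd`; `effect_size = 0` is the null.

Each material carries an *intrinsic texture*: a Gaussian random field with
a configured standard deviation (scanner units) and spatial correlation
length (mm), generated by smoothing white noise and rescaling to the exact
target standard deviation over the material's voxels. This field is a
property of the *object* — scan and rescan see the same realisation.

Imaging is emulated, not simulated: `simulate_scan_pair()` applies a
protocol-dependent contrast scale, then adds an independent white-noise
realisation and a smooth bias field per scan. The 40/50/60 kV presets
encode the empirical ordering that lower tube voltage yields noisier,
more artefact-prone scans (noise SD 300/200/140, bias 120/80/50 scanner
units). There is no projection, reconstruction or beam-hardening physics;
consequently the workflow can show *that* feature robustness degrades with
noise and parameter changes, and *how* the screening machinery behaves,
but its robust-feature inventories are not predictions for any physical
scanner.

## Preprocessing

* **Discretisation** (`discretize_fixed_bin_width()`): fixed bin width
  anchored at the ROI minimum, `level(x) = floor((x − min)/w) + 1`. The
  maximum falls in its own top bin, so `Ng = level(max)`. All texture
  matrices are built from these levels, making every texture feature
  invariant to adding a constant to the raw intensities. The study grid
  for `w` is 10, 25, 50, 100 scanner units, default 25.
* **Slice-thickness resampling** (`resample_slice_thickness()`): only the
  slice-direction (axis 3) spacing changes; in-plane spacing is untouched.
  This reading — resampling the slice direction while leaving the
  "axial"/in-plane grid alone — matches the way the swept quantity is
  named throughout the workflow ("slice thickness"). The image is
  interpolated linearly, masks by nearest neighbour so they stay binary,
  and the new slice count is `round(extent / new_thickness)`. Both image
  and mask are resampled together. The study grid is 0.2, 0.26, 0.3, 0.5,
  1 mm; 0.26 mm is the native default. The in-plane spacing is also set to
  0.26 mm isotropic — the scanner's in-plane value is not documented, so
  the slice value is adopted for all axes.
* **Spherical segmentation** (`make_spherical_mask()`): radius from
  `r = (3V/4π)^{1/3}`, a voxel included iff its centre lies within `r`.
  At 0.26 mm spacing the achieved volume of the ~92 mm³ sphere is within
  about 0.5% of the request; the documented tolerance is 5%.

## The feature engine

A default extraction returns exactly 842 features:
14 shape + 18 first-order + 23 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM +
5 NGTDM = 106 on the original image, plus the six intensity classes
(92 features) on each of eight wavelet sub-bands. Names follow
`<filter>_<class>_<feature>`, e.g. `original_firstorder_Mean` or
`wavelet-HHL_glszm_ZoneEntropy`.

Key conventions, each of which materially affects values:

* **Directions**: GLCM and GLRLM accumulate per lattice direction (13
  unique 3-D directions at distance 1) and *average the feature values*
  across directions — not the matrices. GLSZM zones, GLDM dependences and
  NGTDM neighbourhoods use the full 26-neighbourhood.
* **GLCM algebra**: most co-occurrence features are computed from the
  marginal, difference (`p_{x−y}`) and sum (`p_{x+y}`) distributions,
  using the identities `Σ ij·P = (Σ s²p_s − Σ k²p_d)/4` and, for the
  symmetric matrices built here, `HXY1 = HXY2 = 2·HX`. MCC uses the fact
  that the Markov-like matrix `Q` equals `A²` with `A` row-stochastic, so
  its eigenvalues are the squared eigenvalues of the symmetric
  `D^{-1/2} P D^{-1/2}`. Unit tests verify all of this against literal
  brute-force pair enumeration.
* **Degenerate values**: on a single-level ROI, features whose definitions
  divide by zero (Correlation, Imc1, Imc2, MCC, Busyness, InverseVariance,
  Strength, first-order Skewness/Kurtosis) return 0, and NGTDM Coarseness
  is capped at 10⁶. These sentinels keep vectors complete so that
  downstream screening sees the feature as degenerate rather than missing.
* **Shape**: the mask boundary is polygonised at the 0.5 iso-surface by
  marching tetrahedra (six tetrahedra per cell sharing the main diagonal),
  with linear interpolation of edge crossings on a lightly smoothed
  indicator field (separable Gaussian, σ = 0.8 voxel). The smoothing
  exists because a *binary* iso-surface has facet normals locked to the
  voxel staircase, which overestimates the area of oblique surfaces by a
  resolution-independent factor (a digitised ball then reads sphericity
  ≈ 0.79 at any spacing). With the smoothed field a digitised ball at
  0.1 mm spacing recovers its analytic volume to better than 1% and
  sphericity ≈ 0.99, approaching 1 with refinement. For masks so small
  that smoothing would erase them the raw binary indicator is used, and a
  single-voxel mask returns `NA` for all mesh-based features (with a
  warning) since a mesh needs extent. Maximum 2-D diameters are computed
  per slice/column/row plane over boundary voxel centres.
* **Wavelets**: single-level, undecimated Coiflet-1 analysis filters with
  symmetric padding, applied along each axis (low/high), giving sub-bands
  LLL…HHH on the input grid so the original mask applies unchanged. Each
  band is discretised independently with the same bin width.

## The reliability model

For a feature measured on `n` subjects by `k` raters, the two-way model
yields mean squares MSR (subjects), MSC (raters) and MSE (residual), and

* single measures, absolute agreement:
  `ICC(A,1) = (MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE))`;
* average measures: `ICC(A,k) = (MSR − MSE) / (MSR + (MSC − MSE)/n)`.

Confidence bounds use the F-distribution method with Satterthwaite degrees
of freedom for the single form; average-form bounds apply the
Spearman–Brown step-up to the single-form bounds, the convention of the
standard ICC software this analysis follows. Numerically, the
Satterthwaite df is clamped to [1, 10⁶]: outside that range the interval
is already extreme and the F quantile solver destabilises. A matrix whose
cells are all identical is reported as ICC 1 with degenerate interval
[1, 1] and flagged, and degenerate features are excluded from robust
counts — silently including them would inflate the robust sets.

Simulation checks in the test suite hold the estimator to a mean within
±0.03 of a true ICC of 0.8 (200 replicates, n = 50, k = 2) and to 93–97%
coverage of the nominal 95% interval (500 replicates, n = 30, k = 2).

Classification follows the study's reliability index with strict
inequalities: **robust** iff ICC > 0.8 *and* lower 95% bound > 0.7;
**reliable** iff ICC > 0.8; otherwise not reliable. An ICC of exactly 0.8
is not reliable.

**Subjects.** The phantom studies measure one physical object, but an ICC
needs n ≥ 2 subjects. Here subjects are repeated seeded spherical ROI
placements (default 10) within the soft-tissue compartment; raters are
scan/rescan (repeatability, single measures) or the swept conditions on
scan–rescan means (reproducibility, average measures). The placement count
and rule are configurable in `study_config()`.

**Volume correlation.** Features are correlated against the measured
`original_shape_MeshVolume` across the five segmentation volumes (27.68,
34.38, 41.71, 92.24, 237.5 mm³) and flagged when Pearson r > 0.8. The rule
is applied *signed and strict*, exactly as stated for this workflow; a
feature with r = −1 is not flagged. Because a perfectly anti-correlated
feature is as volume-confounded as a correlated one, `volume_correlation()`
offers `absolute = TRUE` as an explicit deviation. Constant features have
undefined r and are recorded as degenerate.

**Cohort comparison.** Paired two-tailed t-tests across index-paired
subjects (n = 9 per arm) at p < 0.05, restricted to the robust-set
intersection. Multiplicity correction is off by default to match the
screening convention; `p_adjust = "BH"` is available. Identical pairs are
reported as t = 0, p = 1.

## Problem sizes and runtime choices

The default study runs on a 64³ grid at 0.26 mm (mouse phantom), a 120³
grid at 0.5 mm for the 60 mm texture block (0.26 mm over 60 mm would be a
231³ volume whose eight wavelet bands bring no additional insight for
spheres of 42 mm³), and 40³ subject volumes for the cohorts. Ten ROI
placements per condition balance ICC stability against extraction cost; a
full three-energy repeatability sweep (60 extractions of 842 features)
runs in about two minutes on one core. The test suite uses smaller
configurations (3–8 placements, wavelet off where the check does not
concern wavelet features) — these are scaled-down instances of the same
generators, not different conditions.

## What passing tests do and do not show

The synthetic generators emulate: density-calibrated compartments,
shared-object texture with scan-specific noise, the energy ordering of
noise and artefact, spherical segmentations of specified volume, and
cohorts with controlled effect sizes. They do not emulate: reconstruction
artefacts with spatial structure (streaks, rings, beam hardening), partial
volume at compartment boundaries, scanner-specific intensity
non-linearity, or anatomical variability. Passing the pipeline checks
therefore validates the *statistical machinery* — matrices, ICCs,
classification, set logic — and the *qualitative* behaviour of robustness
under noise; it does not certify any specific robust-feature inventory for
real scans, which depend on data no desk simulation can stand in for.

## Known limitations

* The shape class reports a faceted-mesh surface area; for masks a few
  voxels across the smoothing/fallback switch makes mesh values
  discontinuous in mask size.
* GLCM Imc1/Imc2 rely on the symmetrised matrix; software that skips
  symmetrisation will differ on asymmetric-neighbourhood ROIs.
* The NRRD reader supports raw little/big-endian encoding with
  axis-aligned space directions only (gzip-encoded NRRD is not parsed);
  NIfTI I/O covers the common scalar 3-D case.
* `Maximum2DDiameter*` uses boundary voxel centres, a lower bound on the
  mesh-vertex convention, tight at the resolutions used here.
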