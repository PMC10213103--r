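# cbctradiomics

Reliability screening for preclinical cone-beam CT (CBCT) radiomics, end
to end and fully synthetic: digital phantoms, scan–rescan simulation, a
3-D radiomic feature engine, and ICC-based repeatability /
reproducibility analysis.

## Who this is for

Small-animal irradiators image at low tube voltages (40–60 kV), and the
radiomic features extracted from those scans are sensitive to every knob
in the workflow: imaging energy, intensity bin width, slice thickness and
segmentation volume. Before a feature can be trusted as a biomarker it has
to survive a test–retest screen. This package implements that screen as a
reusable, deterministic pipeline for researchers building or auditing
preclinical radiomics workflows — with synthetic data generators standing
in for the phantom and tumour scans, so every analysis runs from code
alone.

## What it computes

* **Feature engine** — 842 features per image/mask pair under the default
  configuration: shape (14), first order (18), GLCM (23), GLRLM (16),
  GLSZM (16), GLDM (14), NGTDM (5) on the original image, and the six
  intensity classes on eight undecimated Coiflet-1 wavelet sub-bands
  (106 + 8 × 92 = 842). Fixed-bin-width discretisation
  (`level(x) = floor((x − min)/w) + 1`), 26-connectivity, feature values
  averaged over the 13 unique 3-D directions for GLCM/GLRLM. Every
  texture-matrix feature is verified against brute-force enumeration
  oracles in the test suite.
* **Reliability core** — two-way mixed-effects ICC, absolute agreement:

  `ICC(A,1) = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)·(MSC − MSE))`

  `ICC(A,k) = (MSR − MSE) / (MSR + (MSC − MSE)/n)`

  with F-based 95% confidence intervals (Satterthwaite df for the single
  form). Classification: **robust** iff ICC > 0.8 and lower CI > 0.7,
  **reliable** iff ICC > 0.8, strict inequalities.
* **Workflows** — repeatability sweeps over energy (40/50/60 kV), bin
  width (10/25/50/100) and slice thickness (0.2/0.26/0.3/0.5/1 mm);
  volume effect over 27.68–237.5 mm³ spheres with Pearson r > 0.8
  volume-correlation flagging; reproducibility (average-measures ICC
  across conditions); a texture-phantom study; and a two-arm tumour
  cohort pilot with paired t-tests (p < 0.05) on the robust set.

## Worked example

```r
library(cbctradiomics)

g <- grid_spec(c(64, 64, 64), 0.26)              # 16.6 mm cube, 0.26 mm voxels
phantom <- generate_mouse_phantom(g, seed = 7)   # soft tissue / lung / bone
pair <- simulate_scan_pair(phantom$image, scan_protocol(60), seeds = c(1, 2))
mask <- place_roi_spheres(phantom$labels, g, volume = 92.24, count = 1,
                          seed = 3)[[1]]
fv <- extract_all(pair$scan, mask, extraction_config())
length(fv)
#> [1] 842
round(fv[c("original_firstorder_Mean", "original_shape_MeshVolume",
           "original_glcm_Contrast")], 4)
#>  original_firstorder_Mean original_shape_MeshVolume
#>                16787.9172                   90.5587
#>    original_glcm_Contrast
#>                  121.5807
```

The ROI mean (~16 788) sits at the soft-tissue calibration point
(1.01 g/cm³ → 16 800 scanner units, here under 60 kV scan noise), and the
92.24 mm³ spherical segmentation meshes to 90.6 mm³.

```r
icc_absolute(matrix(c(1, 3, 5, 7, 2, 4, 6, 8), ncol = 2), form = "single")
#> ICC(A,1) = 0.9302, 95% CI [0.0152, 0.9957] (n = 4 subjects, k = 2 raters)

cfg <- study_config(seed = 1234, roi_count = 6, wavelet = FALSE)
res <- run_repeatability(cfg, "energy")
res$report
#> reliability_report (single-measures ICC): 106 features x 3 condition(s)
#>   40kV: 0 robust, 0 reliable, 14 degenerate
#>   50kV: 0 robust, 10 reliable, 14 degenerate
#>   60kV: 2 robust, 25 reliable, 14 degenerate
```

Per-condition ICCs, robust/reliable sets and their intersections are in
`res$report`; the long-format feature table in `res$table`. The pattern —
fewest stable features at 40 kV, most at 60 kV — is the noise ordering of
the energy presets showing through the screen. The 14 shape features are
degenerate here by design: scan and rescan share the segmentation, so
shape carries no test–retest information and is screened out rather than
counted as robust.

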