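Package: cbctradiomics
Title: Repeatability and Reproducibility Screening for Preclinical CBCT Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying the stability of radiomic features extracted
    from small-animal cone-beam CT (CBCT). Provides density-calibrated digital
    phantoms and scan-rescan simulators, a 3-D radiomics engine (shape, first
    order, GLCM, GLRLM, GLSZM, GLDM and NGTDM texture families, with
    single-level wavelet-filtered variants; 842 features under the default
    configuration), fixed-bin-width intensity discretisation, slice-thickness
    resampling, and two-way mixed-effects intraclass correlation analysis with
    F-based confidence intervals for repeatability, reproducibility,
    volume-correlation filtering and two-arm cohort differentiation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
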