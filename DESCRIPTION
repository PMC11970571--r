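Package: radcorr
Title: Cross-Modality Correlation of 3D Radiomic Texture Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how three-dimensional radiomic texture
    features of an organ agree across co-registered imaging modalities
    (T2-weighted MRI-like, CT-like and cone-beam-CT-like volumes).
    Provides a synthetic phantom-cohort generator with a tunable fraction
    of texture shared across modalities, isotropic resampling, 3-sigma
    intensity re-segmentation, Lloyd-Max gray-level quantization,
    metal-fiducial streak-artifact masking, gray-level co-occurrence,
    run-length, size-zone and neighborhood gray-tone difference features
    with volume normalization, an absolute Spearman correlation analysis
    with Benjamini-Hochberg adjustment and volume-confound filtering, and
    correlation power calculations based on the noncentral t
    distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    Rcpp,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
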