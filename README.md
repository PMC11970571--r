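# radcorr

Cross-modality correlation analysis of 3D radiomic texture features.

## The problem

Radiomic features — scalar texture descriptors computed from image
intensities inside a region of interest — are candidate biomarkers for
prostate cancer radiotherapy. But a cohort is typically imaged on
several modalities (T2-weighted MRI for diagnosis, planning CT, daily
cone-beam CT on the treatment machine), and each modality sees
different physics. Whether a feature measured on one modality carries
over to another is an empirical question: across patients, how strongly
does feature *i* on modality *a* correlate with feature *j* on modality
*b* — and how much of any apparent agreement is both features merely
tracking organ volume?

`radcorr` implements that study end to end for people who work with 3D
ROI imaging data: radiation-oncology physicists and quantitative-imaging
researchers. It provides

* a **synthetic phantom-cohort generator** — three co-registered
  modality volumes per patient sharing a tunable fraction *w* of latent
  texture variance, ellipsoidal prostate-like ROIs with patient-varying
  volume, and metal-fiducial streak artifacts on the X-ray-like
  channels — so the whole analysis is testable without clinical data;
* **preprocessing**: cubic resampling to a 1 mm isotropic grid,
  3-sigma intensity re-segmentation, Lloyd-Max quantization to 64 gray
  levels;
* **fiducial streak-artifact masking**: per-slice threshold from
  artifact-free layers (mean ± 3 SD), a 5 mm disk around the seed,
  supra-threshold pixels, and discrete lines from each back to the
  seed;
* **42 texture features** (8 GLCM, 13 GLRLM, 3 intensity statistics,
  5 NGTDM, 13 GLSZM, with IBSI codes in `feature_registry()`) plus ROI
  volume, seven of them volume-normalized (RF/V, RF×V, or
  probability-renormalized busyness/coarseness);
* the **correlation study**: absolute average-rank Spearman correlation
  `R_M` for every (modality, feature) column pair across patients,
  upper triangle only, one pooled Benjamini–Hochberg adjustment,
  a volume-confound filter that removes columns with `R_V > 0.75`, and
  summaries by comparison class (intramodality, intermodality
  same-feature, intermodality cross-feature);
* **correlation power analysis** via the noncentral-t (point-biserial)
  model: power, required sample size, minimum detectable effect.

Everything is tidyverse-shaped: feature tables and reports are tibbles,
results have `tidy()`/`glance()` methods and `autoplot()` displays.

## Worked example

```r
library(radcorr)

spec <- cohort_spec(n_patients = 10, grid_shape = c(32, 32, 32),
                    roi_radii_mm = list(meanlog = log(c(9, 7, 8)),
                                        sdlog = 0.15),
                    shared_weight = 0.5, seed = 77)
coh <- generate_cohort(spec)
ext <- extract_cohort_features(coh, bins = 16)
rep <- correlation_report(ext$features, alpha = 0.05,
                          volume_threshold = 0.75)
rep
#> <radcorr_report> 10 patients, 117 columns, 6786 pairs (226 significant at adjusted p < 0.05)
glance(rep)
#> # A tibble: 1 × 7
#>   n_patients n_columns n_pairs n_undefined n_dropped_for_volume n_significant
#>        <int>     <int>   <int>       <int>                <int>         <int>
#> 1         10       117    6786           0                    9           226
#> # i 1 more variable: alpha <dbl>

tidy(summarize_correlations(rep))[1:3, 1:5]
#> # A tibble: 3 × 5
#>   class                  group  n_pairs n_significant pct_significant
#>   <chr>                  <chr>    <int>         <int>           <dbl>
#> 1 intramodality          T2w        780            61           7.82
#> 2 intermodality_same_rf  CT-T2w      38             0           0
#> 3 intermodality_cross_rf CT-T2w    1562             2           0.128

power_correlation(n = 47, rho = 0.75, alpha = 4.0e-4, tails = 2)
#> [1] 0.9998795
```

Reading the output: with 10 phantoms and half of the latent texture
shared, 117 (modality, feature) columns survive the volume filter (9
columns dropped as volume confounds), and 226 of the 6786 upper-triangle
pairs stay significant after BH adjustment at alpha 0.05. At only ten
patients, intramodality correlations (features of one modality
correlating with each other) dominate the significant set, while
same-feature cross-modality pairs rarely clear the adjusted threshold —
cross-modality agreement needs the full 47-patient cohort to show up,
which is exactly what the power analysis quantifies: at n = 47 a
correlation of 0.75 is detected essentially always (power rounds to
1.00) even at the Bonferroni-corrected alpha of 4.0e-4.

The full pipeline, with file outputs (NIfTI volumes, manifest,
features CSV, pairs CSV, summary JSON, provenance):

```r
run_pipeline(pipeline_config(cohort = spec), "out_dir")
```

or from a shell: `Rscript inst/scripts/radcorr.R --config cfg.yaml
--out out_dir`.

## Package layout

| Module | Where |
|---|---|
| Phantom cohorts, streak injection | `R/synthetic.R` |
| Resampling, re-segmentation, Lloyd-Max | `R/preprocess.R` |
| Fiducial artifact masking | `R/fiducial.R` |
| Texture matrices and features | `R/texture.R`, `R/registry.R`, `src/texture.cpp` |
| Correlation study | `R/correlation.R` |
| Power analysis | `R/power.R` |
| Pipeline, IO, CLI | `R/pipeline.R`, `R/io.R`, `inst/scripts/radcorr.R` |

The methods vignette
(`vignettes/radiomic-correlation-methods.Rmd`) documents the model,
parameter defaults, numerical conventions and limitations.
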