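---
title: "Cross-modality radiomic correlation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality radiomic correlation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radcorr)
library(dplyr)
```

## The scientific question

Radiomic texture features promise quantitative descriptors of tumour
tissue, but each imaging modality — T2-weighted MRI, planning CT,
on-treatment cone-beam CT — sees different physics. Before features
measured on one modality can stand in for features measured on another,
one has to ask: across a patient cohort, how strongly does a feature
computed on one modality correlate with the same (or any) feature on
another? And how much of any apparent agreement is merely both features
tracking organ volume?

`radcorr` implements that analysis end to end for 3D prostate-like
regions of interest: feature extraction (five texture families plus
volume), the preprocessing the extraction depends on (isotropic
resampling, outlier re-segmentation, Lloyd-Max gray-level quantization,
metal-fiducial streak masking), an absolute-Spearman /
Benjamini-Hochberg correlation study with a volume-confound filter, and
the companion correlation power analysis. Because no public image
cohort accompanies this kind of clinical analysis, the package also
ships a synthetic phantom-cohort generator whose ground truth makes
every stage testable.

## The phantom cohort model

Each patient `p` owns a latent smooth field `S_p` (white Gaussian noise
smoothed with a separable Gaussian kernel of physical width
`correlation_length_mm`, standardized to unit variance) plus an
independent field `H_{p,m}` per modality `m`. The modality image is

```
I_{p,m} = T_m( sqrt(w) S_p + sqrt(1 - w) H_{p,m} + c z_p ) + noise
```

where `w = shared_weight` is the fraction of latent texture variance
common to all modalities, `T_m` is a monotone intensity transform
(identity; negation, emulating the contrast inversion between
T2-weighted and X-ray images; or a gamma curve applied to a linear
window of the unit-variance field), `c = volume_coupling` couples a
mean-intensity texture parameter to the patient's standardized
log-volume `z_p`, and the noise is i.i.d. Gaussian with a per-modality
standard deviation expressed relative to the transform gain. The ROI is
an axis-aligned ellipsoid with lognormal semi-axes; gold-fiducial seeds
are placed well inside it, and in-plane streak segments of alternating
sign are drawn around each seed on the two X-ray-like channels only.

Key defaults, and why:

* `n_patients = 47`, three modalities (`T2w`, `CT`, `CBCT`): the cohort
  layout of the clinical study the analysis mirrors.
* `grid_shape = 64^3` at 1 mm isotropic: makes the resampling stage a
  near-no-op so tests isolate one stage at a time; an anisotropic
  `0.7 x 0.7 x 2.8` mm preset mirrors a typical T2w acquisition grid
  and exercises the resampler.
* `roi_radii_mm`: lognormal with median semi-axes `(18, 14, 16)` mm and
  `sdlog = 0.15`, i.e. a median ROI of about 17 mL with a realistic
  spread — prostate volumes in radiotherapy cohorts commonly span
  roughly 15–50 mL.
* `correlation_length_mm = 4`: texture blobs a few millimetres across,
  small relative to the organ, so run/zone statistics are non-trivial.
* Modality transforms: gamma (0.8) for the T2w-like channel, negation
  for CT-like and CBCT-like; noise 5% of gain for T2w/CT and 10% for
  CBCT (cone-beam reconstructions are noisier). The gamma curve acts on
  a linear `[-4, 4]` window of the field rather than a saturating CDF:
  a contrast curve bends the histogram without destroying the
  correspondence of first-order moments across modalities, which is the
  behaviour a fully shared (`w = 1`) cohort must exhibit.
* `streak_params`: 6 streaks per seed, 12 mm long, on 3 axial slices,
  amplitude 8 in units of the (unit-variance) latent field. The
  clinical literature gives no quantitative streak-intensity model;
  this amplitude is chosen so that streaks sit far outside the
  3-sigma band of clean tissue — qualitatively, the regime in which
  run-length and size-zone features are the artifact-sensitive ones.

One global seed drives a per-patient seed sequence, so any patient can
be regenerated independently and an identical spec is guaranteed to
produce a bit-identical cohort.

What the generator does **not** emulate: scanner physics (beam
hardening, bias fields, reconstruction kernels), anatomical texture
(zonal anatomy, lesions), deformable registration error between
modalities, and out-of-plane streaks. Passing tests therefore
demonstrate that the *pipeline* recovers the statistical structure it
assumes — shared texture fraction, volume coupling, artifact geometry —
not that it would reach the same numbers on clinical images.

## Preprocessing

**Resampling.** Volumes are resampled to a 1 mm isotropic grid with
separable cubic convolution (Keys kernel, `a = -0.5`), masks with
linear interpolation re-binarized at 0.5 (smoother than
nearest-neighbour, still deterministic). Out-of-range kernel support
uses linear extension of the two edge samples, so constant and linear
intensity profiles are reproduced exactly everywhere, including at the
volume border. The output grid keeps the input origin and covers the
input extent without extrapolation.

**Re-segmentation.** In-mask intensities outside `mu +/- 3 sigma`
(population SD) are *excluded* from the mask — the re-segmentation
reading of 3-sigma normalization, not clamping. With a degenerate
(constant) ROI the mask is left unchanged and the range collapses,
flagged. Re-segmentation runs after resampling and artifact masking, so
its statistics reflect the grid and the ROI actually analysed.

**Quantization.** Gray levels come from a Lloyd-Max quantizer with 64
levels by default: codebook initialized at the centres of equal-width
bins over the re-segmentation range, then nearest-code assignment and
centroid updates alternate until the maximum codebook movement drops
below `1e-8` of the range width (at most 500 iterations). The
deterministic initialization trades a possibly better local optimum for
bit-reproducibility; ties at bin boundaries go to the lower level for
the same reason. ROIs with at most 64 distinct values map directly to
consecutive levels, with the effective level count recorded.
Within-bin MSE is tracked per iteration — it never increases, which the
test suite asserts — and the whole quantization is invariant to
positive affine intensity maps.

## Feature definitions and conventions

The 42 features (8 GLCM, 13 GLRLM, 3 intensity statistics, 5 NGTDM, 13
GLSZM; see `feature_registry()` for the IBSI codes) follow the standard
definitions with these stated conventions, each chosen once and tested
against an independent brute-force implementation:

* All matrices are 3D at distance 1 with the 13 unique directions
  *merged* into a single matrix (not averaged per direction).
* Run Percentage is `n_runs / (13 n_vox)` to match merged aggregation;
  Zone Percentage is `n_zones / n_vox`. Zones use 26-connectivity.
* GLCM entropy is base-2; GLCM Correlation is flagged undefined on a
  flat ROI.
* NGTDM excludes voxels with no in-mask 26-neighbour; Coarseness and
  Strength use the Amadasun–King forms with stabilizer `eps = 1e-6`, so
  a flat ROI reports the capped sentinel `1/eps`.
* Intensity statistics are population moments of the raw re-segmented
  intensities; Kurtosis is raw (Gaussian = 3), and skewness/kurtosis
  are flagged undefined at zero variance.
* Undefined values propagate as flags and are handled pairwise-complete
  downstream; they are never silently zeroed.

**Volume normalization.** Seven features are volume-normalized, as
recorded in the registry: GLRLM GLN/RLN and GLSZM GLN/ZSN are divided
by the ROI volume (Type 1; on the package's 1 mm grid the volume in
mm^3 equals the voxel count used by the normalizations this follows);
NGTDM Strength is multiplied by it (Type 2); NGTDM Busyness and
Coarseness are recomputed from the gray-tone difference parts with the
per-level normalizer `p_i s(i)/N(i)` (Types 3 and 4). The Type-3
denominator is read as the full double sum over occupied levels of
`|i p_i - j p_j|` — the printed formula omits the absolute-value bars
and the second index, and this is the only reading that is positive and
scale-consistent. A zero Type-3 denominator flags Busyness undefined.

## The correlation study

Every `(modality, feature)` column is one variable across patients.
The analysis:

1. computes `R_V`, the absolute Spearman correlation of each column
   with its own modality's ROI volume, and removes columns with
   `R_V > 0.75` (volume-confound filter, applied *before* the pairwise
   matrix so the multiple-testing family is unambiguous);
2. computes the absolute average-rank Spearman correlation and a
   two-sided p-value (t approximation on `n - 2` df, computed on the
   signed coefficient) for every unordered column pair — the upper
   triangle, diagonal excluded;
3. adjusts the pooled p-vector once with Benjamini-Hochberg and flags
   adjusted `p < 0.05`;
4. labels each pair intramodality, intermodality/same-feature or
   intermodality/cross-feature, and summarizes significant `|rho|` per
   class: percentage significant, percentage at or above 0.75/0.85/0.95,
   histograms in 0.05 bins and the mode bin.

Histograms and threshold percentages condition on *adjusted*
significance; both raw and adjusted p-values are reported, since which
one a published figure filtered on is ambiguous in general. Pairs
undefined after pairwise-complete handling (fewer than three complete
pairs, or zero rank variance) are excluded from the BH family and
listed separately. The t approximation rather than an exact permutation
p is the right tool at `n = 47`; the test suite checks the statistic
against exhaustive permutation enumeration at small `n`.

The paired masked-vs-unmasked comparison (`paired_feature_ttest()`)
mirrors the clinical check of whether artifact masking *itself* moves
features: the same patients' features with and without the artifact
mask applied, a two-sided paired t per feature plus the Spearman
correlation between conditions. On phantoms, the features that move are
predominantly run-length and size-zone statistics — removing disk- and
line-shaped regions cuts runs and zones — which is exactly the
behaviour reported for clinical images.

## Fiducial streak masking

The removal algorithm operates per axial slice, in 2D, as the artifact
itself does: the threshold band is `mu_AL +/- 3 sigma_AL` over in-ROI
voxels on artifact-free layers; on artifact layers the mask is the
union of (a) the 5 mm disk around the seed centre (pixel-centre
distance, in-plane spacing), (b) every in-ROI pixel outside the band,
and (c) the Bresenham line from each such pixel back to the seed
centre. Design choices worth stating: *every* out-of-band pixel spawns
a line (no restriction to the farthest pixel per ray); line pixels are
restricted to the ROI; out-of-ROI outliers do not seed lines; the
artifact-slice list is an explicit input, as it is in practice where
artifact layers are identified visually. Narrowing the band can only
grow the mask, and the mask never leaves the annotated slices — both
are asserted as properties.

## Power analysis

`power_correlation()` implements the standard point-biserial model: the
test of zero correlation at sample size `n` has noncentrality
`delta = |rho| sqrt(n) / sqrt(1 - rho^2)` on `n - 2` df, and power is
the noncentral-t mass beyond the critical value at `alpha/tails` (plus
the negligible opposite tail). At the study conditions — `n = 47`,
`rho = 0.75`, Bonferroni-adjusted `alpha = 4.0e-4`, two tails — the
power rounds to 1.00. `required_n()` and `min_detectable_rho()` invert
the same function monotonically; a Fisher-z approximation is included
as a cross-check only. A companion Monte-Carlo oracle (bivariate-normal
replicates tested at the same alpha) agrees with the analytic function
to the third decimal in the test suite.

## Problem sizes used by the test suite

The suite regenerates everything it tests. Oracle-equivalence tests use
hundreds of tiny ROIs (2–6 voxels per side, 2–5 levels) against plain-R
brute-force enumerations; parameter-recovery experiments use 47-patient
cohorts on 32^3 grids (20 replicates per shared-weight setting) and
12^3 grids for replicate-heavy null-band checks; the end-to-end
pipeline test runs 10 patients at 32^3. These sizes were chosen so the
whole suite completes in minutes while every Monte-Carlo check retains
a comfortable margin over its acceptance band.

## Known limitations

* Feature values depend on stated conventions (merged directions, RP
  and ZP normalizers, 26-connected zones); packages with different
  conventions will differ numerically while agreeing in rank structure.
* The volume filter uses a hard threshold (0.75); weaker volume
  dependences pass through, and on phantoms a small residual
  cross-modality correlation from shared ROI geometry remains even with
  no shared texture.
* The artifact-mask transfer between modalities assumes voxel-aligned
  grids; no registration is performed.
* The generator's realism limits are listed above; in particular,
  streak amplitude is a free parameter with no quantitative clinical
  model behind it.
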