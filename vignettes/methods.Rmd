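---
title: "Water-to-oil ratio mapping of periprostatic fat: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-to-oil ratio mapping of periprostatic fat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batcsi)
```

## The measurement model

Chemical-shift (DIXON) MRI separates the proton signal of a slice into a
water-only matrix `WOM` and a fat-only matrix `FOM`, both `H x W` grids of
12-bit intensities (0–4095). Brown adipocytes store lipid in many small
droplets and are rich in water-bearing cytoplasm and mitochondria, so their
water-to-fat signal ratio exceeds that of white adipocytes. The pipeline
turns that premise into a per-voxel statistic in four steps:

1. **Ratio map.** `R = WOM / FOM` elementwise (`water_oil_ratio()`).
2. **ROI masking.** Voxels outside the periprostatic-fat annulus are set to
   zero (`apply_roi()`), giving the masked map `PR`. Masks are *inputs*:
   segmentation of the prostate and the fascial boundary is manual and out
   of scope.
3. **Brown-fat extraction.** ROI voxels are sorted from large to small and
   the top `retain_fraction` (default 1%) keep their values; the rest are
   zeroed (`extract_brown_fat()`), giving `BPR`.
4. **Display.** Any matrix is rendered to 8 bits by
   `x_new = round((x − x_min)/(x_max − x_min) × 255)`
   (`rescale_intensity()`, `render_ratio_image()`), and ROI contours are
   painted green (outer) / red (inner) on the rendering
   (`overlay_contours()`).

Per patient, ROI voxels are pooled across slices and averaged
(`summarize_patient()`); that mean is the imaging feature for all cohort
statistics.

## Numerical choices

* **Division by zero fat.** `R` is undefined where `FOM = 0`. Dropping such
  voxels would delete exactly the extreme water-dominant voxels the method
  is designed to find, so they are assigned a finite ceiling
  (`ratio_policy()`, default `zero_fat_cap = 1000`, far above any
  anatomically plausible ratio); `0/0` is defined as 0 (no tissue signal).
  The number of capped voxels is reported per slice so the choice is
  auditable.
* **Rounding.** The level conversion rounds half-up (`floor(x + 0.5)`), not
  banker's rounding, so integer edge cases are identical across platforms.
* **Top-1% denominator.** The retained count is
  `ceil(retain_fraction × N)` with `N` the number of *ROI* voxels, not the
  full `H x W` grid: out-of-ROI zeros are placeholders, and a full-matrix
  denominator would make the count depend on the field of view.
  `denominator = "all_elements"` is available for sensitivity analysis.
  `ceil` guarantees at least one retained voxel for any nonempty ROI.
* **Ties.** Voxels tied at the cutoff value are retained in ascending
  row-major order — an arbitrary but fixed rule that makes the extraction a
  pure function of the inputs.
* **Degenerate rendering.** A constant matrix has no dynamic range; it
  renders all-zero with a warning rather than erroring mid-pipeline.
* **Coordinates.** (row, col), 1-based, as native to R matrices; the
  row-major tie-break index is `(row − 1) × W + col`.

## Cohort statistics

The clinically significant stratum (high + intermediate risk) is compared
with the low-risk group by a Welch t-test (variance heterogeneity between
risk strata is expected; the pooled-variance test is available by flag) plus
a two-sided Mann–Whitney test (`compare_groups()`). When both groups are
exactly constant the t interval degenerates to a point and the p-value is
reported as `NA` rather than inventing one.

ROC analysis (`roc_curve()`) sweeps every distinct score as a threshold and
integrates by trapezoid; with midrank handling of ties this equals the
Mann–Whitney concordance probability, and the test suite checks that
equality against a brute-force O(n²) pairwise count on every tested input.
High risk is the positive class. Three ROCs are reported: the per-patient
mean ratio alone, iPSA alone, and their combination.

* **Combination rule.** How the two markers were originally fused is not
  public; this package's own choice is maximum-likelihood logistic
  regression on `(log iPSA, mean ratio)` (`combine_features()`), with iPSA
  logged because serum PSA is heavily right-skewed. The in-sample linear
  predictor is the combined score. Under perfect separation the
  coefficients diverge but the ranking — hence the AUC — is still valid;
  the condition is flagged.
* **AUC uncertainty.** The uncertainty estimator behind the published SDs
  is likewise unstated; this package uses a stratified nonparametric
  bootstrap (resampling within class, default 2000 replicates, seeded),
  reporting the SD and percentile 95% CI of the replicate AUCs
  (`bootstrap_auc()`).
* **Which mean enters the ROC.** The full-ROI mean is the default
  (`roc_feature = "mean_rwo_full"`); the retained (top-1%) mean is offered
  as an alternative because the source analysis does not say which one fed
  its ROC.

## The phantom: what it emulates and what it does not

`generate_phantom_slice()` builds a stated world, not a tuned one:

* geometry — elliptical prostate (semi-axes 16 × 20 px in a 96 × 96 slice)
  with a 10-px annulus of fat around it, mirroring a mid-gland 2D slice;
* compartments — annulus voxels carry total signal `signal_peak` (default
  3000 of 4095) split by fat fraction: 0.85 for white fat and 0.5 inside
  brown-fat blobs, so the noiseless water-to-oil ratio is
  `(1 − f)/f` ≈ 0.18 vs 1.0. The 0.85/0.5 contrast encodes the premise
  that brown fat is water-richer; neither value is measured from patients,
  and published per-patient means (tens, not fractions) are on a different,
  scanner-dependent scale. Only orderings and AUCs transfer, not absolute
  ratio values.
* brown-fat burden — circular blobs (radius 3 px), centres uniform over the
  annulus, counts drawn per patient from group ranges 0–2 (low), 3–6
  (intermediate), 4–8 (high). The source only says brown fat is scarce and
  more concentrated near aggressive tumours; these ranges are free
  parameters chosen once to give the high/intermediate stratum a real but
  noisy imaging signal, and they are *not* revisited to make tests pass.
* noise — additive Gaussian per channel (SD 40 intensity units ≈ 1% of
  full scale) before clipping to [0, 4095] and half-up quantization.
  Rician noise, bias fields, motion, partial-volume effects and
  inter-scanner variation are deliberately absent — a green phantom test
  establishes algorithmic correctness, not clinical validity.
* iPSA — log-normal, moment-matched to the published group means/SDs
  (6.7 (2.3) / 10.4 (3.6) / 51.9 (50.6) ng/ml). Log-normal is this
  package's choice: iPSA is positive and the high-risk SD roughly equals
  its mean, implying heavy right skew that a normal cannot represent
  without negative draws.
* reproducibility — every patient gets sub-seeds derived deterministically
  from the master seed by a counter scheme, so cohorts are identical
  record-by-record across runs and independent of iteration order.

The default cohort is 4 low / 4 intermediate / 13 high — the published
cohort structure — so the group-size imbalance that the real analysis faced
(4 negatives for the ROC!) is faithfully present in tests.

```{r phantom, fig.alt = "phantom demo"}
sl <- generate_phantom_slice(phantom_params(seed = 1))
r  <- apply_roi(water_oil_ratio(sl$water, sl$fat), sl$mask)
ex <- extract_brown_fat(r, sl$mask)
c(n_roi = sum(sl$mask$in_roi), k_retained = ex$k,
  mean_full = mean(r[sl$mask$in_roi]))
```

## Known limitations

* No MR physics: echo times, phase errors, field inhomogeneity and the
  vendor water–fat separation itself are not simulated; the phantom starts
  from already-separated channels.
* 2D only; no registration, no 3D connected components, no automatic
  segmentation.
* DICOM and TIFF files are not read in this build (no reader available in
  the supported dependency set); use CSV, PGM/PPM or PNG. PNG output is
  8-bit.
* With 21 patients the bootstrap SD of an AUC is itself noisy; the
  percentile CI is reported for the same reason the SD alone should be
  read with caution.
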