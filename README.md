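# batcsi

Brown adipose tissue (BAT) detection in chemical-shift (DIXON) water–fat MRI
of periprostatic adipose tissue (PPAT), with risk-group statistics and ROC
analysis.

## The problem

DIXON MRI separates each slice into a water-only matrix (WOM) and a fat-only
matrix (FOM), both 12-bit intensity grids. Brown adipocytes hold more water
relative to lipid than white adipocytes, so they stand out in the per-voxel
**water-to-oil ratio**

    R(h, w) = WOM(h, w) / FOM(h, w)

Restricting R to the annular periprostatic-fat region of interest (all
non-PPAT voxels set to zero) gives the masked map `PR`; sorting its ROI
voxels from large to small and keeping only the top 1% (brown fat is scarce)
gives the brown-fat extraction `BPR`. For display, any matrix is mapped from
4096 to 256 levels by the affine conversion

    x_new = round((x - x_min) / (x_max - x_min) * 255)

Per patient, the mean ratio over the ROI (pooled across slices) is the
imaging statistic. Across a cohort it is compared between clinically
significant (high + intermediate NCCN risk) and low-risk patients, and fed
into ROC analysis — alone, and combined with initial serum PSA (iPSA) via
logistic regression on (log iPSA, mean ratio).

Because no patient images are deposited anywhere, the package ships a seeded
synthetic phantom generator: an elliptical prostate, a fat annulus of white
adipose voxels, sparse circular BAT blobs with elevated water fraction,
additive Gaussian channel noise, and group-conditional log-normal iPSA
(means/SDs 6.7 (2.3), 10.4 (3.6), 51.9 (50.6) ng/ml for 4 low / 4
intermediate / 13 high-risk patients). Every downstream stage is tested
against it.

## Worked example

```r
library(batcsi)
cohort <- generate_cohort(seed = 7)          # 21 synthetic patients
report <- cohort_report(cohort, n_boot = 500, seed = 7)
print(report)
```

```
Cohort analysis report
  21 patients, groups: high (n=13), intermediate (n=4), low (n=4)
  Clinically significant vs low mean_rwo_full: 0.25 vs 0.19 (95% CI of difference 0.05 to 0.08, t p=1.81e-07, MW p=0.000334)
  AUC (mean_rwo): 0.942 (bootstrap SD 0.052)
  AUC (ipsa): 0.962 (bootstrap SD 0.036)
  AUC (combined): 0.971 (bootstrap SD 0.032)
```

Reading: the clinically significant stratum shows a higher mean
water-to-oil ratio than the low-risk group (0.25 vs 0.19 — phantom ratios
live on the raw water/fat scale of the simulated annulus, not on any
clinical scale), with a Welch 95% CI for the difference excluding zero and
both t and Mann–Whitney p-values small. The three AUCs (with stratified
bootstrap SDs) score how well the imaging mean, iPSA, and their logistic
combination identify high-risk patients; in this synthetic world both
features are informative by construction.

Single-slice level:

```r
sl <- generate_phantom_slice(phantom_params(seed = 1))
r  <- water_oil_ratio(sl$water, sl$fat)        # full ratio map
pr <- apply_roi(r, sl$mask)                    # PPAT-masked
ex <- extract_brown_fat(pr, sl$mask)           # top 1% -> ex$bprwo, ex$k
img <- render_ratio_image(ex$bprwo)            # 8-bit display
rgb <- overlay_contours(img, sl$mask)          # green outer / red inner ROI
```

## Command line

```sh
exec/batcsi simulate --out run1 --seed 7        # phantom cohort to disk
exec/batcsi analyze --manifest run1/manifest.csv \
    --clinical run1/clinical.csv --out run1/report
exec/batcsi slice --water w.pgm --fat f.pgm --mask m.pgm --out sliceout
```

`analyze` writes per-slice display images (IWO/IFO/IRWO/IBPRWO as PGM plus
an RGB contour-overlay PPM), `patient_summaries.csv`,
`group_comparison.csv`, `roc_results.csv`, `roc_curves.csv` and a
`run_manifest.json` with the config hash and seed; reruns are bitwise
reproducible. Supported image formats: headerless CSV, netpbm PGM/PPM, and
grayscale PNG (read 8/16-bit, write 8-bit).

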