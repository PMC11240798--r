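# surrocor

Skin-surface surrogates of internal respiratory motion from 4DCT
contours.

## What it is for

In surface-guided radiotherapy (SGRT), an optical camera tracks a patch
of the patient's skin and gates the treatment beam on the patch's
position. The skin patch stands in for the internal target, so choosing
it well matters twice over: the patch must move *enough* relative to the
gating window, and its motion must *track* the internal motion. This
package evaluates torso skin regions on both counts, for physicists and
researchers working with ten-phase 4DCT contour data:

* **Per-beam analysis.** On every axial slice, 180 radial beams at 1°
  steps (θ = 0°…179°, 0° to the patient's right, 90° anterior) are cast
  from a central craniocaudal axis fitted by least squares through the
  per-slice skin-contour centroids. Per beam, the respiratory
  **magnitude** is max − min beam length over the phases (mm), and the
  **correlation** is the sample Pearson R between the beam-length series
  and the craniocaudal coordinate series of a tracking structure (TS)
  over the same phases — together a magnitude map and a correlation map
  over the whole torso surface.
* **Nine regions.** Beams are grouped by parasternal angular bands
  ([30°, 75°), [75°, 105°), [105°, 150°)) and by the xipho-sternal line
  and subcostal plane into regions A/A_R/A_L, B/B_R/B_L, C/C_R/C_L, and
  the maps are aggregated per region and patient.
* **Adiposity.** On one axial slice at L4, adipose tissue is thresholded
  at −150…−20 HU (inclusive) and split at the inner abdominal wall into
  subcutaneous and visceral compartments (SAT%/VAT%/TAT% of the slice
  surface).
* **Cohort statistics.** Friedman test with Dunn–Bonferroni post hoc
  across regions; Mann–Whitney U (U = min convention, tie- and
  continuity-corrected z, effect size r = |z|/√N) for sex comparisons;
  Spearman Rho matrices for covariates (SAT%, VAT%, TAT%, BMI, height)
  against regions; pooled t-test with Cohen's d.
* **Phantom.** A synthetic breathing torso — skin radius ρ(θ, z, p) =
  ρ₀ + M(θ, z)·w(p/P − φ(θ, z)) + noise with the raised-cosine waveform
  w(t) = (1 − cos 2πt)/2 — plus a concentric-ellipse L4 slice, both with
  analytic ground truth, so the whole pipeline is testable without
  patient data.

## Worked example

```r
library(surrocor)

cfg  <- phantom_config(slice_zs = 0:99, noise_sd = 0.3, seed = 42L)
torso <- generate_torso(cfg)                 # 10 phases x 100 slices
part <- roi_partition(z_xiphosternal = 60, z_subcostal = 30,
                      z_inferior_limit = 0, z_superior_limit = 100)
fit <- surrocor(torso$phases, generate_ts(cfg), partition = part)
summary(fit)
```

```
Skin-surface surrogate analysis: 10 phases x 100 slices x 180 beams
  TS magnitude 8.00 mm; invalid beams: 0
  beam magnitude quartiles: 1.05 / 1.81 / 3.79 mm
  skin-to-TS R quartiles: 0.445 / 0.892 / 0.979
  nine-region summary (mean):
 roi magnitude_mm pearson_r n_beams
   A     4.892666 0.9873677    1200
 A_R     2.486231 0.8782678    1800
 A_L     2.568091 0.8888399    1800
   B     4.885429 0.9876809     900
 B_R     2.496760 0.8753676    1350
 B_L     2.560208 0.8883543    1350
   C     4.872997 0.9874873     900
 C_R     2.485858 0.8792410    1350
 C_L     2.541510 0.8881333    1350
```

The default phantom moves most at the anterior midline (a 5 mm Gaussian
amplitude lobe centred at θ = 90°), so the central-column regions show
the largest mean magnitudes (≈4.9 mm) and the highest skin-to-TS
correlations (≈0.99), while the parasternal columns move less (≈2.5 mm)
and, with 0.3 mm vertex noise on near-motionless lateral beams, correlate
less tightly — exactly the trade-off the maps are built to expose. The
TS magnitude (8 mm) is the excursion of the tracking-structure
trajectory. `plot(fit)` draws the correlation map (bins anchored at
R < 0.5, black, and R > 0.95, deep blue); `plot(fit, "magnitude")` the
green-to-red magnitude map; `as.data.frame(fit)` the long-format table.

Adiposity on the matching synthetic L4 slice:

```r
l4 <- generate_l4_slice(cfg)
quantify_adipose(l4$slice, l4$inner_wall)
#> <adipose_result> SAT 6660 mm^2 (14.1%), VAT 1697 mm^2 (3.6%),
#>   TAT 17.7% of body area
```

Cohort-level reports (`generate_cohort()` for synthetic cohorts,
`build_reports()` for the statistical battery, `run_pipeline()` for the
end-to-end multi-patient run) are documented in the methods vignette,
`vignettes/skin-surrogate-analysis.Rmd`.

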