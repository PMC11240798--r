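---
title: "Skin-surface surrogates of respiratory motion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skin-surface surrogates of respiratory motion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surrocor)
```

## The problem

Optical surface-guidance systems track a patch of a patient's skin and
hold the treatment beam whenever the patch leaves a tolerance window. The
skin patch is a *surrogate*: the quantity of clinical interest is the
respiratory motion of an internal target (here represented by a tracking
structure, TS — a small blood-vessel segment in the lower lung lobe). A
good surrogate region needs two properties at once: its motion must be
*large* relative to the gating window, and it must be *strongly
correlated* with the internal motion. `surrocor` maps both properties
over the whole torso surface from ten-phase 4DCT skin contours and
summarises them over nine anatomical regions, so that regions can be
compared as candidate surrogates.

## The per-patient analysis

`surrocor()` runs the following procedure on one patient:

1. **Centroids and axis.** The area-weighted centroid of the skin contour
   is computed on every axial slice (shoelace construction, independent of
   vertex ordering and density). Two ordinary least-squares lines, $x(z)$
   and $y(z)$, through the centroids of one anchor phase give the central
   craniocaudal axis. The axis is fitted on a single phase (the first, by
   default) and *held fixed across phases*, so beam-length changes reflect
   skin displacement rather than centroid drift between phases.
2. **Radial beams.** On each slice, 180 radial beams are cast from the
   axis point at angles $\theta = 0^\circ, 1^\circ, \dots, 179^\circ$
   (half-open $[0^\circ, 180^\circ)$; $0^\circ$ points to the patient's
   right, $90^\circ$ anterior). Each beam's length is the distance from
   the axis to the *outermost* crossing with the skin polygon — when a ray
   crosses a skin fold several times, the outer crossing is what an
   optical camera sees. Beams that find no crossing are flagged invalid
   with a reason, never silently zeroed.
3. **Maps.** Per beam, the respiratory **magnitude** is the maximum minus
   the minimum beam length over the phases (mm), and the **correlation**
   is the sample Pearson R between the beam-length series and the TS
   craniocaudal coordinate series over the same phases. A beam whose
   length series has zero variance is motionless, which is not the same as
   "uncorrelated": it is flagged undefined rather than assigned $R = 0$.
4. **Nine regions.** Beams are partitioned by angular band — right
   $[30^\circ, 75^\circ)$, central $[75^\circ, 105^\circ)$, left
   $[105^\circ, 150^\circ)$, approximating the parasternal lines — and by
   slice height relative to two per-patient landmarks, the xipho-sternal
   line and the subcostal plane, into rows A (above the xipho-sternal
   line), B (between the landmarks) and C (below the subcostal plane,
   down to an inferior cutoff near L4). All intervals are half-open, so
   boundary beams and landmark slices belong to exactly one region; beams
   lateral of $30^\circ$/$150^\circ$ are deliberately unassigned. The
   per-region aggregator is the mean by default, with the median
   available; reports record which was used. Landmark heights are inputs
   located anatomically on the CT — automatic landmark detection is out of
   scope.

The TS trajectory itself is the volume-weighted centroid height of the
delineated TS contours per phase; only the craniocaudal component is
used, as it dominates for lower-lobe structures. The craniocaudal axis is
oriented so that the inhalation displacement of the TS is positive; with
that convention an in-phase skin beam correlates *positively* with the
TS, matching the sign of the reported region-to-TS correlations.

## The breathing-torso phantom

No public 4DCT contour data accompany the analysis, so validation rests
on a synthetic phantom with analytically known ground truth. The skin
radius about the phantom axis is

$$\rho(\theta, z, p) = \rho_0(\theta, z) + M(\theta, z)\,
  w\!\left(\frac{p}{P} - \varphi(\theta, z)\right) + \varepsilon,$$

with $w(t) = (1 - \cos 2\pi t)/2$ a raised cosine — a standard surrogate
for a tidal breathing cycle (0 at end-exhale, 1 at peak inhale; for even
$P$ the discrete samples span $[0, 1]$ exactly), $M \ge 0$ a local
amplitude field (mm), $\varphi$ a local phase-lag field (cycle fraction)
and $\varepsilon$ optional Gaussian vertex noise. The TS follows the same
cycle: $z_{TS}(p) = z_0 + A_{TS}\, w(p/P)$.

Ground truth is computed on the *noise-free discrete series of length P*
— exactly what the pipeline sees — not asymptotically: the magnitude
truth is $M \cdot (\max_p w' - \min_p w')$ for the lag-shifted waveform
$w'$, and the correlation truth is the exact Pearson R of the radius
series against the TS series (clamped to $[-1, 1]$ against last-ulp
rounding). With zero lag the radius series is a positive affine image of
the TS series, so the truth is exactly $+1$ wherever $M > 0$; anti-phase
lag ($\varphi = 0.5$) gives exactly $-1$; $M = 0$ beams have undefined
correlation.

Default phantom conditions, chosen once as a realistic torso: base radius
150 mm; an anterior Gaussian amplitude lobe
$M(\theta) = 5 \exp(-((\theta - 90)/40)^2)$ mm, i.e. chest/abdominal wall
motion peaking at 5 mm anteriorly and negligible laterally; TS excursion
8 mm (typical of a lower-lobe vessel); 100 slices at 1 mm spacing; no
lag; no noise. Contour vertices are sampled every $0.5^\circ$, so beams
cast at integer degrees pass exactly through phantom vertices and the
sub-1% chord error of coarser sampling never enters.

Two exactness conditions are worth stating because the validation suite
relies on them. First, beam lengths equal the polar radius function
exactly only when the beam origin coincides with the polar centre; the
fitted axis does coincide whenever the *anchor-phase* contour is
rotationally symmetric. The lag-free default phantom satisfies this
(phase 0 is the undeformed circle), and exact $R = -1$ recovery under
anti-phase lag is checked with a uniform amplitude field, which keeps
every phase circular. With an asymmetric lobe and a deformed anchor
phase, the fitted axis shifts by the centroid offset (about 2 mm for the
default lobe) and recovery is approximate rather than exact — which is
the realistic situation, and is covered by the 2%-tolerance checks.
Second, these exactness checks say nothing about features real 4DCT data
have and the phantom lacks: reconstruction artifacts, irregular and
drifting breathing cycles, skin folds that occlude beams, couch and
garment surfaces, and deformation that does not follow a global waveform.
Passing them validates the *geometry and statistics machinery*, not
clinical performance.

The L4 adipose phantom is a concentric-ellipse abdomen: a subcutaneous
fat ring at $-100$ HU between the skin ellipse and the muscle wall, a
muscle ring at $+40$ HU, a visceral interior at $+30$ HU with seeded
non-overlapping circular fat blobs at $-100$ HU, air at $-1000$ HU
outside. Compartment areas follow from ellipse and circle geometry, so
pixel-counted results can be checked against closed forms; at 1 mm
pixels the rasterisation error is comfortably below the 2% tolerance
used in the tests.

## Adipose quantification

Adipose tissue on the single L4 slice is the set of body pixels with HU
in $[-150, -20]$; both bounds are inclusive (the range is stated as
endpoints, and tissue at an endpoint is tissue). The total adipose mask
is split by a supplied inner-abdominal-wall polygon: pixels whose
centres fall inside the wall are visceral (VAT), the rest subcutaneous
(SAT) — an exact partition by construction. Percentages divide by the
body cross-section area by default; the full image frame is available as
an alternative denominator because "slice surface" is ambiguous, but the
body area is the default since it is the denominator under which
between-patient fractions are comparable.

## The statistical battery

The cohort stage follows common clinical-statistics conventions, each
cross-checked in the test suite against base R and brute-force oracles:

* **Friedman test** across the nine within-patient regions: mid-ranks
  within each patient, tie-corrected $\chi^2$ on $k - 1$ degrees of
  freedom. Missing cells are an error; nothing is imputed.
* **Dunn–Bonferroni post hoc**: all $k(k-1)/2$ pairwise mean-rank
  contrasts, $z = (\bar R_i - \bar R_j)/\sqrt{k(k+1)/(6n)}$, two-sided
  normal p, Bonferroni-multiplied and capped at 1.
* **Mann–Whitney U** for sex comparisons: U reported as the *smaller* of
  the two group statistics (the convention under which the printed U
  values are reproducible), z from the normal approximation with tie
  correction and a 0.5 continuity correction, and effect size
  $r = |z|/\sqrt{N}$. This effect-size formula is the one that
  reproduces every printed $(z, r)$ pair at two decimals; with the
  study's group sizes the normal approximation is appropriate, and an
  exact permutation test is not attempted.
* **Spearman's Rho** for covariate–region correlations: Pearson
  correlation of mid-ranks with the two-sided t-approximation p on
  $n - 2$ df; zero rank variance is flagged undefined.
* **Independent-samples t-test** with pooled variance, 95% CI and
  Cohen's $d = |\bar a - \bar b|/s_p$; the conversion
  $d = |t|\sqrt{1/n_a + 1/n_b}$ is algebraically identical and is
  exposed for recomputing $d$ from a printed $t$.

All tests are two-sided. No multiplicity control is applied beyond the
Bonferroni family inside the post hoc test; the covariate matrix flags
cells at unadjusted $p < 0.05$.

The cohort simulator (`generate_cohort()`) draws plausible joint
distributions (heights by sex, BMI around 27 kg/m², adiposity tracking
BMI with a male visceral offset, abdominal magnitudes of a few mm
exceeding upper-thoracic ones, high region-to-TS correlations) with
controllable couplings. It exists to validate the battery — e.g. that a
constructed anti-monotone BMI-to-row-A coupling is recovered as negative,
significant Rho — not to reproduce any particular cohort's numbers.

## Numerical choices and degenerate inputs

* Beam count honours the stated 180 at $1^\circ$ steps via the half-open
  fan $0^\circ \dots 179^\circ$ (a closed $0$–$180^\circ$ range at
  $1^\circ$ would hold 181 beams and double-count the lateral axis).
* Ray–edge intersections accept edge parameters in $[-10^{-9},
  1 + 10^{-9}]$ so rays passing exactly through a vertex are caught on
  both adjacent edges; taking the maximum crossing distance makes the
  duplicate harmless.
* Polygon orientation is normalised to counter-clockwise on
  construction; zero-area polygons, single-z axis fits, empty TS stacks,
  non-nested phantom rings and non-positive phantom radii are errors.
* Validation problem sizes: full-scale phantom recovery at 100 slices
  $\times$ 180 beams $\times$ 10 phases; beam-casting checked against an
  independent point-in-polygon bisection oracle to $10^{-6}$ mm on 100
  random star-shaped polygons; Friedman checked exhaustively against a
  counting-rank oracle on all two-level tables with $n, k \le 4$ plus
  sampled three-level tables; Mann–Whitney type-I error calibrated on
  2,000 seeded null simulations at the study's group sizes (26/31).
* Determinism: the phantom's randomness lives only in the vertex-noise
  and blob-placement draws, seeded from the configuration; identical
  configurations produce bit-identical outputs, and the contour JSON
  writer emits 17 significant digits so files round-trip exactly.

## Limitations

Beams are axial-plane only (no out-of-plane surface normals and no 3-D
meshing); TS motion is craniocaudal only; landmarks and the inner
abdominal wall are manual inputs; no DICOM-RT import is required by the
core (an adapter can map structure sets onto `phase_contour_set`
objects); phase-lag estimation between skin and TS is out of scope —
the correlation map treats lag as a property to be *detected* (lower R),
not corrected.
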