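---
title: "Quantifying thoracic deformity and lung function: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thoracic deformity and lung function: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thoraciq)
```

## The measurement chain

Early-onset deformity of the spine and rib cage constrains lung growth
during the period of alveolar multiplication, and the resulting deficit in
lung structure and respiratory function persists into adulthood.  In a
small-animal model of this disease, the quantitative link between the
three-dimensional spine deformity and respiratory outcome is established by
a chain of measurements:

1. **Spine deformity** from vertebral landmarks on CT: coronal and sagittal
   Cobb angles, their three-dimensional composite, and the trans-axial
   rotation at the curve apex.
2. **Lung densitometry** on breath-hold CT volumes acquired at airway
   pressures of 0, 5, 15 and 25 cmH2O: per-lung tissue mass, aerated
   volume, fractional tissue volume, and the capacity measures FRC
   (aerated volume at 0 cmH2O), TLC (at 25 cmH2O) and IC = TLC - FRC.
3. **Regional ventilation** by deformable image registration between
   successive breath-hold pressures: the Jacobian determinant of the
   recovered deformation gives the local specific volume `sVol = J - 1`,
   summarised regionally (anterior-posterior, left-right, apex-base).
4. **Respiratory mechanics** from ventilator pressure/flow recordings via
   the single-compartment equation of motion, and forced vital capacity
   from forced-expiration flow signals.
5. **Cohort statistics**: group summaries as percent-of-Normal and
   deformity-outcome regressions (Pearson r, R^2).

No raw animal data ship with the package.  Every stage is instead exercised
on synthetic phantoms and signals with exact ground truth, calibrated so
that the generative group effects equal the published group statistics of
the rabbit rib-tethering model; the pipeline is validated by *parameter
recovery* through the full measurement chain.

## Synthetic thorax phantom

`phantom_spec()` / `generate_phantom()` renders HU volumes of a simplified
thorax: an elliptic-cylinder soft-tissue body (0 HU), a vertebral column
(+700 HU) along a parametric space curve, and two lung regions flanking it.
Everything about the phantom is a modelling convention, not anatomy; the
design goal is that each downstream measurement has a known true value.

**Spine.**  The centerline is a pair of orthogonal sinusoidal arcs.  For a
curved segment of length $L$ and amplitude $A$, the tangent-angle range of
the projection is $2\arctan(A\pi/L)$, so the amplitude that realises a true
Cobb angle $\theta$ is $A = (L/\pi)\tan(\theta/2)$ in closed form.  For
angles whose amplitude would leave the grid, the curved segment is
shortened (Cobb depends only on $A/L$); generation fails with an
informative error when no segment fits.  Vertebral landmarks are sampled
along the curve, with the trans-axial rotation profile
$\mathrm{TRA}_{true}\,\sin(\pi t)$ (zero at the ends, maximal at the apex).

**Lungs and tissue.**  Each lung is an ellipsoid (clipped around the spine
by a protective margin) whose volume is set by `volume_scale`.  The
reference configuration is **total lung capacity**; lower pressures are
produced by an analytic contraction field (below).  The tissue fraction
field is a smooth deterministic texture (two incommensurate products of
sinusoids, relative amplitude 0.2, periods 14-20 mm) scaled so that its
integral equals the target lung mass *exactly*.  The texture stands in for
the vascular/parenchymal structure that real lungs carry; its spatial scale
is chosen larger than twice the maximum breathing displacement so that
intensity-driven registration is well posed, which mirrors the physical
requirement that trackable structure exist at the scale of the motion.
Voxel HU is $-1000\,(1-\mu)$ with $\mu$ the local tissue density in g/mL;
additive Gaussian CT noise (SD 20 HU, toggleable to 0) is applied last.

**Pressure series.**  Mean air fractions per pressure derive from a
saturating pressure-volume relation
$V(P) = \mathrm{FRC} + (\mathrm{TLC}-\mathrm{FRC})
\frac{1-e^{-P/\lambda}}{1-e^{-25/\lambda}}$ with $\lambda = 8$ cmH2O.
Healthy-adult defaults (right lung 9.3 g / FRC 10.4 mL / TLC 32 mL; left
6.7 g / 7.5 mL / 23.2 mL) encode the normal right-to-left TLC ratio of
1.38 and an aerated fraction of ~78% at TLC.  These absolute volumes are
package conventions consistent with adult rabbit physiology; the published
study reports only relative (percent-of-Normal) values, which is what the
recovery experiments target.

**Deformation with closed-form Jacobian.**  The contraction from TLC to a
lower pressure is, per lung,
$u(x) = a\,w(x)\,g(y)\,(x - c)$
with $c$ the lung centroid, $w(x)$ a logistic left/right weight (a function
of the left-right coordinate only), and $g(y) = 1 + \gamma (y-c_y)/b_y$ a
linear anterior-posterior gain (the knob behind gravity-dependent regional
ventilation; default $\gamma = 0.2$).  Because $w$ depends only on $x$ and
$g$ only on $y$, the Jacobian determinant of $x + u(x)$ is closed-form.
The amplitude $a$ is calibrated per lung and pressure by one-dimensional
root finding so that the mean Jacobian over the lung equals the volume
ratio implied by the air-fraction schedule; tissue is conserved exactly by
construction ($\mu_{low} = \mu_{TLC}/J$).  Lower-pressure volumes are
rendered through fixed-point inversion of the analytic map, and the stored
ground truth includes, for each consecutive pressure pair, the dense
displacement field (on the lower-pressure grid, pointing to the
higher-pressure image) together with its analytic Jacobian.

**What the phantom does not emulate.**  Airways, vessels and lobar
fissures; cardiac structures; rib cages (the deformity acts on the spine
and the per-lung size/density parameters only); hysteresis of the
pressure-volume curve; scanner physics beyond additive noise.  Recovery
results on phantoms therefore validate the *computational chain*, not
performance on clinical images.

## Deformity measures

`cobb_angle()` projects the landmark chain onto the coronal or sagittal
plane, fits a cubic spline centerline and reports the largest angle between
centerline tangents within one curvature-sign segment.  This
centerline-tangent convention replaces the clinical endplate construction,
which has no meaning for centroid chains.  The spline interpolates the
landmarks exactly by default: annotations in this pipeline are exact, and a
smoothing spline was found to bias a 60-degree arc by several degrees.  A
`spar` argument switches to a smoothing spline for noisy annotations.

The composite maximal deformity angle is
$$\theta_M = 2\arctan\sqrt{\tan^2(\theta_S/2) + \tan^2(\theta_K/2)},$$
which is algebraically the three-dimensional angle between the end tangents
of a curve bent by $\theta_S$ coronally and $\theta_K$ sagittally, and
equally the largest Cobb angle observable over all projection planes
containing the cranio-caudal axis (the package tests verify this against a
brute-force projection search).  Severity is classified from $\theta_M$:
Severe above 55 degrees, applied at the 10-week timepoint in pipeline runs.
The Moderate/Normal-range boundary at 15 degrees is a package convention
(healthy controls are never classified by angle in the study design).

`thoracic_rotation_angle()` takes the vertebra of maximal centerline
curvature as the apex and reports its trans-axial rotation relative to the
mean of the end vertebrae, so a whole-spine rotation reads as zero.

## Densitometry

With attenuation calibrated to density ($\mu = 1 + \mathrm{HU}/1000$), the
segmented lung's tissue mass is $\sum_n (1 + \mathrm{HU}_n/1000) V_{pixel}$
and its aerated volume $\sum_n (-\mathrm{HU}_n/1000) V_{pixel}$; their sum
is exactly the geometric volume of the mask, a conservation identity the
tests assert.  HU values outside $[-1000, 100]$ inside lung masks are
clamped with a reported count.  FTV is $m/(m + V_{air})$ at TLC.

Segmentation thresholds aerated voxels (default below -300 HU) inside the
filled body envelope and removes components below 0.1 mL.  Left and right
lungs are separated by connected components (the two lungs are disjoint,
separated by the mediastinum; each component takes the side of its
centroid).  A mid-sagittal split through the spine centroid line is the
fallback when the lungs form one component; it is not the default because
with large coronal deformity the spine centroid line swings deep into the
left hemithorax and mislabels para-spinal voxels.  Large airway lumens are
not excluded (phantoms contain none) — a documented limitation for real
data.

## Deformable registration and specific volume

No installed R package provides 3-D deformable registration, so the
package implements a multi-resolution demons-type algorithm
(`register()`), with compiled kernels for warping, gradients, Gaussian
smoothing and connected components.  Between breath-hold pressures the lung
drops ~30-40% in density, with a spatial pattern equal to the unknown
Jacobian itself — exactly the quantity being estimated — so similarity
choices matter more than usual:

* **Gain-invariant forces** (`metric = "lncc"`, default): demons forces are
  evaluated on locally mean-removed, variance-normalised images (Gaussian
  window, SD 3 voxels, with a variance floor so featureless regions are not
  noise-amplified).  This makes the match invariant to the smooth
  multiplicative intensity change of inflation while preserving the
  advected texture pattern.  A mass-preserving alternative
  (`metric = "ssd"`, `mass_preserving = TRUE`) compares densities with the
  warped image multiplied by the current field's Jacobian; in controlled
  experiments it recovered mean expansion but biased point correspondence,
  so it is not the default.
* **Per-lung similarity initialisation**: the field is seeded by matching
  each lung's centroid and per-axis spread between the two segmentations,
  blended with smoothed membership weights.  This removes the bulk
  (multi-voxel) deformation before the intensity-driven stage.
* **Compositive updates** (`u <- u o (id+dv) + dv`) and damped Gaussian
  field diffusion; per-voxel step capping; early stopping on a patience
  rule after a minimum iteration count.

`specific_volume()` evaluates the Jacobian by central differences on the
fixed (lower-pressure) grid in voxel units (the determinant is invariant
to the voxel/mm diagonal conjugation), falling back to one-sided
differences at volume faces *and at the lung mask boundary*, so that field
values outside the lung — where image information is weak — never enter a
lung voxel's Jacobian.  Folded voxels ($J \le 0$) become `NA` and are
excluded from all regional statistics with a reported count.

`validate_conservation()` mirrors the study's own registration check:
$\sum \mathrm{sVol}\, V_{pixel}$ over the lower-pressure lung is compared
with the volume change of the segmented lungs; the default pass threshold
is 5%.  `regional_analysis()` bins sVol into equal-thickness
anterior-posterior slabs (equal-thickness rather than equal-volume — a
declared convention, configurable via the bin count), splits
anterior/posterior and apex/base halves at volumetric medians, and reports
the posterior/anterior ratio of bin means plus per-lung means and their
left/right ratio.  The three inspiration phases are the 0-5, 5-15 and
15-25 cmH2O steps.

**Measured accuracy (stated sizes).**  On the default 64 x 64 x 96 phantom
(1.25 mm voxels) at the 0-to-5 cmH2O step — mean true displacement 1.7
voxels, maximum ~4 — the recovered field reproduces the total lung volume
change to within a few percent and the mean specific volume to within ~5%,
with a mean endpoint error of ~0.6 voxel; the voxelwise sVol error (RMS
~0.14 against the analytic Jacobian) remains larger than the integral
errors, since pointwise Jacobians amplify small-scale field noise.
Quantities built from per-lung or regional *means* (conservation, the
regional profile) are the reliable outputs; voxelwise sVol maps should be
read as spatial patterns, not point estimates.  In severe-deformity
phantoms, where the curved spine carves a channel through the enlarged
left lung, that lung's mean expansion is under-recovered by ~5-8%, which
propagates into the measured left/right sVol ratio.  These are honest
limitations of an intensity-driven method on nearly homogeneous parenchyma
at large inflation steps.

## Respiratory mechanics

`fit_single_compartment()` estimates the single-compartment equation of
motion $P = E V + R \dot V + P_0$ by recursive least squares with
exponential forgetting (default 0.995, covariance initialised at $10^6 I$).
Volume comes from trapezoidal integration of flow with a per-cycle linear
drift correction.  The reported elastance and resistance are the means of
the recursive trace over the final breath cycle (a declared convention; the
forgetting factor makes the final cycle dominate anyway).  With
forgetting 1 the final recursive estimate equals batch least squares, which
the tests assert to numerical tolerance.  MIP is the peak of the 25-ms
smoothed pressure; records with MIP above 14 cmH2O are flagged `gated` and
excluded from cohort statistics, since such inflations exceed the linear
elastic range of tidal breathing.  The fit is a classed model object with
`print`, `summary` (batch-OLS reference and standard errors), `coef`,
`predict`, `residuals`, `plot` and `simulate` methods.

`forced_vital_capacity()` integrates each forced-expiration flow signal
until flow ceases — below 2% of peak expiratory flow sustained for 50 ms
(the quantification of "until air ceased to flow") — flags maneuvers whose
cumulative volume retreats by more than 2% of its maximum as invalid, and
accepts FVC as the largest expired volume only when at least two valid
maneuvers agree within a 10% disparity margin, with disparity defined as
(max - min)/max.  The cessation rule truncates the exponential tail below
threshold, reading ~1.5% low on ideal signals; the bias is common to all
groups and cancels in percent-of-Normal summaries.

## Calibrated cohort

`generate_cohort()` draws a synthetic study population whose *generative*
parameters equal the published group statistics, so that recovering them
through the measurement chain is a meaningful end-to-end test.

* Disease animals lie on a deformity continuum: $\theta_M$ at 6 weeks is
  uniform on 25-75 degrees; progression to 28 weeks has true slope 1.45
  (deformity worsens with growth) with Gaussian noise sized in closed form
  so the 6-to-28-week $R^2$ equals its 0.88 target; severity is classified
  at the interpolated 10-week angle (threshold 55 degrees), and batches are
  drawn until both Disease groups are filled.
* Each 28-week outcome is affine in $\theta_M^{28}$ with the two
  coefficients solved from the Moderate and Severe group-mean targets
  (e.g. right lung mass 87% and 59% of Normal), and noise sized as
  $\sigma = |c_1|\,\mathrm{sd}(\theta)\sqrt{1/R^2 - 1}$ to meet the
  correlation target over the pooled Disease animals.  Outcomes without a
  correlation target use the tabulated SD fraction instead.  Where the
  published table lists both a group SD and a correlation, the correlation
  wins — both cannot be imposed simultaneously through one noise term.
* Normal animals scatter around the healthy means with a relative SD of
  8% (one number for all outcomes; the published table normalises by the
  Normal mean, not its spread).

`phantom_spec_from_animal()` turns a cohort row into a phantom whose
per-lung mass, FRC and TLC equal that animal's values;
`densitometry_for_cohort()` renders and measures whole groups.
`disease_phantom_spec()` additionally solves the left lung's 5-cmH2O air
volume so that the left/right mean expansion ratio on the first inflation
step equals a prescribed value (default 0.92, the published left/right
specific-volume asymmetry in Disease animals).

`percent_of_normal()` normalises group means by the Normal mean (treated
as fixed, so each cell carries a single SD — the published presentation);
`regress()` is closed-form OLS with the exact-t p-value for the Pearson
correlation, no multiple-testing correction (matching the study's
analysis); `build_table2()` assembles the deformity-outcome $R^2$ matrix
over the pooled Disease animals at both 6 and 28 weeks;
`slope_vs_unity_test()` tests the progression slope against 1.  The
repeated-measures ANOVA of the original analysis is routine hypothesis
testing and is deliberately not re-implemented; group differences are
checked against the generator's known effects instead.

## Problem sizes and reproducibility

The test suite runs phantoms at 40 x 40 x 60 (2 mm voxels) for speed and at
the full 64 x 64 x 96 (1.25 mm) for the acceptance checks; cohort recovery
uses n = 200 per group (the study's n = 5 per group is matched only in
qualitative runs); Monte-Carlo checks use 40-120 replicates.  All
randomness flows through explicit integer seeds (one seeded generator per
object; no global state is left behind), and fixed seeds reproduce
phantoms, signals and cohorts bit-identically.

## Known limitations

* Registration voxelwise accuracy lags its integral accuracy, and the
  left lung's expansion is under-recovered around the carved spine channel
  in severe-deformity phantoms; see above.  A full LNCC gradient force or
  a parametric pre-model would be the next step.
* The phantom's lungs do not follow the spine: deformity enters through
  per-lung size and density parameters, not mechanical coupling.
* Segmentation assumes the lungs are separated components; airway lumens
  and vessels are not modelled or excluded.
* The cohort model induces correlations only through the deformity
  continuum; residuals are independent across outcomes, so partial
  correlations between outcomes are not calibrated.
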