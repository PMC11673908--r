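---
title: "Centre-of-pressure cyclogram diagnostics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centre-of-pressure cyclogram diagnostics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclogait)
```

## The cyclogram and its markers

During walking, each foot's centre of pressure (COP) travels from heel to
toe along the *gait line*. When both feet's COPs are combined with
force weighting,

$$x_C = \frac{F_R x_R + F_L x_L}{F_R + F_L}, \qquad
  y_C = \frac{F_R y_R + F_L y_L}{F_R + F_L},$$

the combined COP traces a closed curve over repeated strides — the
*cyclogram* or butterfly diagram. During single support the curve coincides
with the loaded foot's gait line; during double support it jumps diagonally
from the trailing forefoot to the leading foot, and the two diagonal
families cross near the body midline, giving the butterfly its crossing
point.

`cyclogait` extracts ten marker points per stride:

* **E**, **A** — rearmost and frontmost COP of each foot over its own
  stance (the gait-line endpoints), found as the extremes of the
  antero-posterior (ap) coordinate;
* **D**, **B** — the combined COP at contralateral toe-off and
  contralateral heel strike, i.e. the endpoints of the single-support line,
  found as the extremes of the combined COP within the single-support
  window;
* **C** — the crossing of each double-support transfer path with the
  temporally adjacent opposite transfer, one C per transfer, labeled by the
  direction of the later transfer (`C_LR`, `C_RL`).

All coordinates are insole-length-normalized: the ap coordinate runs from 0
(heel end) to 1 (toe end), the lateral coordinate has each insole's midline
at 0 with the left foot mirrored, so both feet share one frame. Distances
between markers are therefore dimensionless.

From the per-stride markers, collected into ten clusters across strides, the
package computes fifteen parameters per dataset: the gait line AE and
single-support line BD; positions ap/lat C, ap A, ap B, ap D, ap E; the
distances AB, BC, CD, DE; the ratios $R_a = BC/AB$ and $R_p = CD/DE$; and
the Balance Index. Positions and distances use cluster *mean* positions,
averaged over sides; the alternative (mean of per-stride distances) is
larger under scatter and was rejected because the cluster-centred definition
matches how the markers are usually displayed and keeps the zero-scatter
limit exact.

## The Balance Index

For each cluster the sample standard deviations $\sigma_x$, $\sigma_y$
define a scattering area $\sigma_x \sigma_y$. Left and right areas are
summed per zone (A–E; the two C directions for zone C) and the Balance
Index is the sum of the five zone areas:

$$\mathrm{BI} = \sum_{z \in \{A..E\}} \left(
    \sigma_{x}\sigma_{y}\big|_{z,\mathrm{left}} +
    \sigma_{x}\sigma_{y}\big|_{z,\mathrm{right}} \right).$$

The raw BI is in squared insole-length units; for reporting it is
multiplied by a constant chosen so that the ROC-optimal threshold between
the impaired and reference cohorts sits at BI = 100
(`calibrate_bi_scale()`). The scale constant is cohort-dependent, so the
default is 1 (raw units) and calibration is applied at the comparison stage.
BI is translation invariant and scales quadratically with coordinates;
percentage contributions of the five zones always sum to 100 (undefined at
exactly zero scatter).

## Classifier evaluation

Cohorts are compared per parameter with the Mann–Whitney U test (midranks,
ties count one half; two-sided p by normal approximation with tie and
continuity corrections, cohort sizes of dozens justify it; an exact
permutation option exists for small samples). With the separation constant
$S = U/(n_1 n_2)$ taken in the smaller orientation, the rank effect size and
the AUC follow as identities:

$$r = 1 - 2S, \qquad \mathrm{AUC} = 1 - S = \tfrac{1 + r}{2}.$$

Parameters with a large effect ($r > 0.37$) are evaluated as classifiers:
an ROC sweep over midpoints of consecutive sorted pooled values (plus
sentinels) yields TPR/FPR, and the optimal threshold maximizes the
geometric mean $G = \sqrt{\mathrm{TPR}\cdot\mathrm{TNR}}$. Ties in $G$ are
broken by the larger Youden index, then by proximity to the pooled median —
the max-$G$ criterion alone does not fix the threshold, so a deterministic
tie rule had to be chosen. Confusion percentages are reported relative to
each cohort's size. Parameters with small effects get no threshold row, so
a comparison table has blank classifier cells exactly where the effect-size
rule says so.

Orientation (whether high or low values flag impairment) is chosen
automatically so AUC ≥ 0.5 and recorded per row. The statistical unit is
the dataset, not the participant; repeated datasets per participant
pseudo-replicate, which mirrors the usual practice in this kind of study
and is deliberately not "corrected" here.

Correlations between geometry parameters and the BI use ordinary least
squares on optionally log10-transformed axes (`correlate_with_bi()`),
since the BI spans an order of magnitude or more across mixed cohorts.

## The synthetic gait generator

Raw insole recordings of the kind this pipeline targets are rarely
public, so the package ships a generator whose output has the statistical
structure the analysis assumes, with known ground truth.

A `cohort_template()` fixes the mean positions of the E, D, B, A anchors
(ap and lateral half-width per side) and per-zone Gaussian scatter. The C
marker is *not* an anchor: it emerges as the crossing of the simulated
transfer paths, computed in closed form. The built-in templates encode the
healthy-vs-neuropathy contrast: healthy cyclograms have a long BC and a
short AB, the impaired cyclogram collapses (long AB, short BC) and scatters
more, with zone scatter ordered B > D > A > C > E.

Numerical choices, in the package's own words:

* **Timing.** 50 Hz sampling, 1.2 s stride (60 samples, so events fall on
  the grid), double support of 7 samples per transfer, stance = half stride
  plus one double support. A dataset of 12 steps yields 6 complete gait
  cycles; two extra strides pad the recording ends so every analysed cycle
  is complete.
* **Force model.** Per stance, a two-hump (heel-strike and push-off) shape
  with a mid-stance valley at 70% of peak, multiplied by linear
  loading/unloading cross-fades over the double-support windows with a 10%
  initial-contact floor. The floor makes heel strike sharp at sample
  resolution, so threshold detection (5% of the median stance peak, minimum
  stance 0.2 s — standard gait practice; the threshold is relative, hence
  detection is invariant to force rescaling) finds the planted events
  exactly.
* **COP path.** Piecewise linear through the anchors; after a brief loading
  phase (45% of double support) the COP dwells at D until the end of double
  support. This reproduces the straight-diagonal butterfly shape and places
  the emergent crossing near ap ≈ 0.57 for both cohorts, close to what such
  data show.
* **Geometry constants.** The anchor ap positions and the emergent
  distances AB, BC, CD of the default templates reproduce the cohort
  medians reported for healthy and neuropathic gait (healthy AB = 0.027,
  BC = 0.288; impaired AB = 0.126, BC = 0.193). The published medians of
  AE, BD and DE are *not* jointly realizable with the published marker
  positions in any single Euclidean geometry (e.g. ap A ≈ 0.8 and
  ap E ≈ 0.01 force AE ≥ 0.79); the templates therefore realize the marker
  positions and the short distances, and let AE, BD, DE follow from them.
  Medians of many datasets need not be geometrically consistent, which is
  the likely origin of the discrepancy; consequently $R_p$ also differs
  from published values while $R_a$ is reproduced.
* **Scatter.** Per-zone SDs keep the relative zone ordering of the BI
  components, with the absolute level calibrated so that the simulated
  healthy cohort's median AB reproduces the template value within a few
  percent — scatter inflates small distances (a noncentral-chi effect), and
  the healthy AB of 0.027 is the most sensitive quantity, so it anchors the
  calibration. Participant-level anchor offsets (SD 0.0025 insole lengths)
  are drawn once per participant; 56 impaired datasets over 14 participants
  and 70 reference datasets over 15 participants give the 126-dataset
  default study.
* **Scatter model limits.** Scatter is Gaussian and axis-aligned;
  correlated scatter is omitted because the BI uses only the product
  $\sigma_x\sigma_y$, which ignores covariance. Real pathological gait also
  shows skewed marker distributions, drift over a walk, and occasional
  missteps that the generator does not emulate — passing recovery tests on
  synthetic data therefore validates the pipeline's arithmetic and event
  logic, not its robustness to every real-world artefact.

Fixed seeds make studies bit-identical; the generator restores the caller's
RNG state.

## Degenerate inputs and tie rules

* COP samples with force below 1e-9 of the frame maximum are invalid
  (swing); combined-COP samples where both feet are unloaded are skipped,
  not errors.
* Marker extrema break ties by the earliest sample.
* Transfers that never cross (pathological gait) fall back to the midpoint
  of the closest-approach pair, flagged and counted in the QC report;
  dropping such strides instead would unbalance cluster sizes. For parallel
  overlapping segments the centre of the projection overlap is used, making
  the fallback symmetric in its arguments.
* Step validation keeps cycles whose stance durations and peak forces lie
  within ±30% of the per-recording median and logs each rejection; it
  refuses to run on fewer than 3 cycles, and extraction fails a dataset
  only if every cycle is lost.
* Zero-variance clusters make the BI exactly 0 with undefined percentage
  contributions (`NA` with a warning); identical cohorts make BI
  calibration fail, which the comparison reports as an uncalibrated BI
  column rather than an error.

## Problem sizes used in the tests

The test-suite study sizes are the package's defaults (126 datasets of 6
cycles at 50 Hz, generated as full time series in a few seconds); oracle
comparisons use hundreds of small random instances, and Monte-Carlo checks
of scatter recovery use 10,000 strides per cluster. These sizes give the
stochastic checks comfortable margins while keeping the whole suite fast.

## Known limitations

* Events are detected at sample resolution (no sub-sample interpolation);
  at 50 Hz this bounds marker timing error at 20 ms, which the marker
  definitions absorb by using window extremes.
* The per-sensor conversion assumes a rigid planar sensor layout; insole
  bending during push-off is not modelled.
* The comparison table applies no multiple-testing correction across the
  15 parameters, matching the source methodology; interpret the p-values
  accordingly.
* Whether "12 consecutive steps" means 12 strides or 12 half-strides is
  ambiguous in the protocol this emulates; the generator takes a step to be
  a half stride (6 cycles) and makes the count configurable.
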