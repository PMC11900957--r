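---
title: "Measuring the corneal exposure ratio: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the corneal exposure ratio: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cermetrics)
```

## The quantity being measured

The corneal exposure ratio (CER) is a two-dimensional outcome metric for
ptosis (drooping eyelid) assessment: the fraction of the corneal disc left
uncovered by the lids, expressed as a percentage. Unlike one-dimensional
metrics such as MRD1 (pupil-center-to-upper-lid distance) or palpebral
fissure height, the CER captures how much of the optically relevant surface
is actually exposed, which is what changes when ptosis surgery lifts the
upper lid.

The cornea is bounded by the limbus, the circle where the cornea meets the
sclera. In a frontal photograph the limbus is the outer boundary of the
visible iris, so the CER can be computed from segmentation masks alone:

1. localize the limbal circle (center, radius) and the pupil;
2. reconstruct the **full** corneal disc as a Boolean raster — every pixel
   whose center satisfies $(x - c_x)^2 + (y - c_y)^2 \le r^2$ — regardless
   of how much of it the lids cover;
3. intersect (logical AND) that disc with the exposed-eye mask, the open
   palpebral-fissure region between the lid margins;
4. report $\mathrm{CER} = 100 \cdot \#\{\text{disc} \cap
   \text{aperture}\} / \#\{\text{disc}\}$ by counting non-zero pixels.

The denominator is deliberately the whole limbal disc including the pupil
region — the cornea overlies both iris and pupil — and exposed pupil pixels
count as exposed cornea. Pixels are counted by center inclusion with no
partial-pixel weighting, so the ratio is an exact rational number for any
given circle and masks.

Pixel measurements are converted to millimetres with an anatomical
reference: the horizontal white-to-white corneal diameter (interlimbal
distance), taken as 11.7 mm by default, giving
`mm_per_px = 11.7 / (2 * iris_radius_px)`.

## Circle detection

The pupil and limbus are localized with a circle Hough transform. For each
edge pixel $(x, y)$, candidate radius $r$ and angle $\theta$ on a regular
1° grid over $[0°, 360°)$, a vote is cast at the candidate center

$$a = x - r\cos\theta, \qquad b = y - r\sin\theta,$$

rounded half-up to the nearest accumulator cell. Three numerical choices
matter and are worth stating explicitly:

* **One vote per edge pixel per cell.** At small radii, adjacent $\theta$
  samples round to the same cell, so raw vote counts would scale like
  $1/r$ per pixel and spurious small circles would outrank large ones.
  Votes are therefore deduplicated so a cell's support counts the distinct
  edge pixels consistent with that circle, comparable across radii.
* **Neighbourhood pooling.** A circle whose true center or radius falls
  between accumulator cells splits its votes across neighbours (a radius of
  31.5 px splits between the 31 and 32 cells). Support is pooled over the
  3×3×3 neighbourhood in $(a, b, r)$ before peak selection; without this,
  severely occluded irises with half-integer radii fall under the support
  threshold and the detector fails exactly where it is most needed.
* **Support threshold and ties.** A peak must collect at least
  `min_support_frac` (default 0.25) times $2\pi r$ votes. A discrete
  8-connected circle contains roughly $0.8 \cdot 2\pi r$ distinct boundary
  pixels, so this threshold corresponds to roughly a third of the limbal
  arc surviving — matching the detector's working range under partial lid
  occlusion. A fraction of 0.3, which reads as more natural, actually
  demands ~37% of the true arc and rejects severe-droop irises. Ties are
  broken deterministically: smaller radius, then smaller $b$, then smaller
  $a$. Greedy non-maximum suppression removes candidates within 10 px of an
  accepted stronger peak in both center and radius, which keeps concentric
  pupil/iris pairs (their radii differ by more than the separation) while
  collapsing accumulator ridges.

Detection runs on segmentation-mask boundaries by default (the boundary of
a binary mask is exact), with a grayscale image path available: Sobel
gradient magnitudes with hysteresis thresholding, defaults 0.2 and 0.08 of
the maximum gradient magnitude. Where a lid crosses the iris, the
visible-iris boundary contains the lid margin as well as the limbal arc;
margin pixels coincide with the exposed-eye boundary and are subtracted
before voting, so circles are fit to limbal arcs only. Without this step
the chord systematically drags the fit toward smaller, lower circles.

Sub-pixel refinement is out of scope: the accumulator has 1-px resolution,
and the measured CER inherits an error of roughly 1 percentage point per
pixel of circle error — acceptable against the ~1 pp rasterization noise
floor. Partial arcs shorter than ~120° are genuinely ambiguous at this
resolution; recovery within 2 px is only promised when at least a third of
the limbal arc survives.

## The synthetic eye generator

There is no public image set to test against, so the package ships a
parametric generator whose ground truth is exact by construction. An eye is

* a circular iris disc with concentric pupil (pupil/iris ratio drawn from
  0.35–0.45, the photopic physiological range);
* an aperture bounded by two parabolic lid curves — the simplest smooth
  family that reproduces a palpebral fissure;
* flat-shaded regions (pupil 20, iris 90, skin 160, sclera 235 on an 8-bit
  gray scale) with optional Gaussian noise.

Masks are always rendered without anti-aliasing: exact ground truth
requires hard binary masks, and the true CER is *defined* as the pixel
count ratio on them, so the generator and the measurement agree about what
the right answer is to the last pixel. Noise is clamped below half the
minimum palette gap (±34 intensity units), which guarantees the
nearest-palette-class reference segmenter reproduces the painted masks
exactly; this is what lets tests isolate circle-detection error from
segmentation error.

Cohorts draw lid droop uniformly from 0–8 mm. At zero droop the upper-lid
apex sits 0.5 mm above the superior limbus and the lower lid 0.5 mm below
the inferior limbus, so the disc is fully exposed (CER = 100); droop lowers
the upper lid by `droop_mm / mm_per_px` pixels. Eight millimetres of droop
leaves roughly a quarter of the disc exposed, so cohorts span CER ≈ 25–100
— fully open through severe ptosis. The 2 mm severity boundary (mild ≤ 2 mm
< moderate-to-severe) applies to the recorded droop. Iris center and radius
receive small per-eye jitter (±2% of the image, ±8% of the radius) so
cohorts do not share one geometry.

What the generator does **not** emulate: eyelashes, specular highlights,
iris texture, shadows, 3-D globe curvature, and camera pose variation.
Passing tests therefore demonstrate the correctness of the geometry and
arithmetic of the pipeline, and its robustness to lid occlusion — not
robustness to photographic nuisance factors, which belongs to the
segmentation backend. The reference segmenter is a stand-in with the same
contract (image in, per-class binary masks out) as a trained semantic
segmentation model; any such backend can be substituted, and `load_masks()`
accepts masks produced outside the package.

## Reliability statistics

The statistics mirror how automated ocular biometry is validated against a
manual reference:

* **Paired t-test** on pre/post differences (via `stats::t.test`). Two
  degenerate cases are explicit: identical series give $t = 0, p = 1$; a
  constant non-zero shift (zero-variance differences) raises an error
  rather than returning an unbounded statistic.
* **ICC**, two-way single-measure, from the variance components of the
  subjects-by-raters decomposition. The default form is absolute agreement
  — the appropriate choice for method comparison, where a systematic offset
  between methods *should* lower the coefficient — with consistency
  available by flag. Confidence intervals use the standard F-distribution
  bounds (Satterthwaite degrees of freedom for absolute agreement).
  Interpretation bands: 0.41–0.6 moderate, 0.6–0.8 substantial, 0.8–1.0
  excellent. Identical series return exactly 1.0 with an undefined
  interval, flagged; the variance components degenerate there, and 1.0 is
  the only sensible convention for a deterministic tool measured twice.
* **Bland–Altman**: bias = mean difference, 95% limits of agreement =
  bias ± 1.96 × SD of differences (sample SD, no small-sample
  t-correction, matching common practice).
* **One-way ANOVA** across measurement series and **two-way ANOVA**
  (severity × timepoint) for severity-stratified outcomes, via
  `stats::aov`.
* **Improvement rate**: $100 (\bar{x}_{post} - \bar{x}_{pre}) /
  \bar{x}_{pre}$, reported to two decimals.

Two eyes of one patient are treated as independent observations, matching
how cohort analyses of this kind are usually reported; per-patient
clustering is out of scope.

```{r stats-example}
pre <- c(55.2, 61.7, 70.3, 48.9, 66.0, 73.4)
post <- pmin(pre + c(19, 14, 11, 22, 12, 9), 100)
paired_t(pre, post)$t_stat
icc_agreement(pre, post)$icc
improvement_rate(mean(pre), mean(post))
```

## Problem sizes and numerical tolerances

The test suite and the reproduction script run cohorts of 100 eyes at
128 × 128 px (iris radius ≈ 32 px), the package's chosen balance between
geometric fidelity and turnaround; single-eye functions default to the
512 × 512 clinical crop geometry. At 128 px, measured CER tracks ground
truth with a mean absolute error near 1 percentage point across the full
droop range, dominated by the 1-px accumulator resolution; the suite
asserts a 2 pp bound. Brute-force Hough oracles run on rasters up to
32 × 32, where exhaustive enumeration over every (center, radius) cell is
cheap. Closed-form checks (circular-segment areas, explicit
sums-of-squares for ICC/ANOVA/Bland–Altman) are asserted to 10 significant
digits.

## Known limitations

* Circle localization is integer-resolution by design; ellipse fitting and
  gradient-direction-restricted voting are not implemented.
* The lid-margin subtraction assumes the exposed-eye mask is consistent
  with the visible-iris mask (as any single segmentation backend will
  produce); independently sourced masks with disagreeing boundaries fall
  back to the full visible-iris boundary.
* No exclusion of specular highlights or eyelash occlusions from the
  cornea mask: such pixels count as exposed if the masks say so.
* Analyses treat eyes as independent; inter-eye correlation within a
  patient is not modeled.
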