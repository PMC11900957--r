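# cermetrics

Automated measurement of the **corneal exposure ratio (CER)** from frontal
eye photographs or segmentation masks, with the method-agreement statistics
used to validate automated ocular biometry. The CER is a two-dimensional
outcome metric for ptosis (drooping upper eyelid) assessment and surgery
evaluation: the percentage of the corneal disc left uncovered by the lids.
It complements one-dimensional metrics such as MRD1 and palpebral fissure
height by quantifying the exposed optical surface itself.

## Who this is for

Oculoplastic outcome studies and image-analysis pipelines that need a
reproducible, fully automated CER: given per-class eye segmentation masks
(visible iris, pupil, sclera, exposed-eye aperture) from any segmentation
backend — or synthetic images from the built-in generator — the package
localizes the pupil and limbus, reconstructs the full corneal disc, and
reports the exposed fraction, calibrated to millimetres.

## Method

1. **Circle detection.** Edge pixels are taken from segmentation-mask
   boundaries (or Sobel + hysteresis on a grayscale image). A circle Hough
   transform votes at candidate centers *a* = *x* − *r* cos *θ*,
   *b* = *y* − *r* sin *θ* over *θ* ∈ [0°, 360°); accumulator peaks above a
   circumference-proportional support threshold yield the pupil and limbal
   circles. Lid-margin pixels are excluded from the edge sets so circles
   are fit to limbal arcs only.
2. **Full-iris mask.** Every pixel with
   (*x* − *c<sub>x</sub>*)² + (*y* − *c<sub>y</sub>*)² ≤ *r*² is set `TRUE`,
   reconstructing the complete corneal disc under the lids.
3. **CER.** The cornea mask is the logical AND of the full-iris disc with
   the exposed-eye mask;
   CER = 100 · #(disc ∩ aperture) / #(disc), counted at pixel centers.
4. **Calibration.** mm/px = interlimbal distance / (2 · iris radius), with
   the interlimbal (white-to-white corneal) diameter defaulting to 11.7 mm.
5. **Validation statistics.** Two-way single-measure ICC (absolute
   agreement or consistency) with F-based confidence intervals,
   Bland–Altman bias and 95% limits of agreement, paired t-tests, one- and
   two-way ANOVA, ptosis severity classification (mild ≤ 2 mm of droop),
   and pre/post improvement rates.

A parametric synthetic eye generator (circular iris and pupil, parabolic
lid curves, controllable droop in millimetres) provides analytically known
ground truth so the entire pipeline is testable without patient data.

## Worked example

```r
library(cermetrics)

# one synthetic eye, 512 x 512, iris radius 128 px, ~6 mm of lid droop
eye <- generate_eye(eye_spec(image_width = 512, image_height = 512,
                             iris_radius = 128,
                             upper_lid = lid_parabola(256, 256 - 128 + 55, 0.27 / 128),
                             lower_lid = lid_parabola(256, 256 + 128 + 11, -0.12 / 128)))
eye$truth$true_cer_percent
#> [1] 80.23642

measure_eye(eye$truth$masks)
#> CER: 81.03%  (exposed cornea 41014 px / full iris 50617 px)
#>   iris: center (256.0, 257.0), radius 127.0 px  [0.0461 mm/px; iris diameter 11.70 mm]
```

The measured 81.03% sits 0.8 points from the generator's exact ground
truth; the gap is the 1-px resolution of the Hough accumulator (the limbal
circle was recovered at radius 127 instead of 128). Across a graded
cohort the agreement between measurement and ground truth looks like a
good method-comparison study:

```r
cohort <- generate_cohort(20, image_size = 128, seed = 7, noise_sd = 0)
measured <- sapply(cohort, function(rec) measure_eye(rec$truth$masks)$cer_percent)
truth    <- sapply(cohort, function(rec) rec$truth$true_cer_percent)

mean(abs(measured - truth))
#> [1] 1.18                      # mean absolute error, percentage points

icc_agreement(measured, truth)
#> ICC (absolute_agreement, n=20): 0.998 (0.995-0.999)  [excellent agreement]

bland_altman(measured, truth)
#> Bland-Altman: bias 0.418, 95% LoA [-2.825, 3.661] (n=20)
```

Batch use from a shell goes through the thin CLI in `inst/cli/cer`
(subcommands `synth`, `measure`, `report`), which wraps `cer_synth()`,
`cer_measure()` and `cer_report()`.

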