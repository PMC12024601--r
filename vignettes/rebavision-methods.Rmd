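---
title: "Automated REBA scoring from multi-camera landmarks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated REBA scoring from multi-camera landmarks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rebavision)
```

## The problem

Rapid Entire Body Assessment (REBA) is an observational ergonomic method:
an assessor grades six joint regions (neck, trunk, legs, upper arm, lower
arm, wrist) into small integer *points* from observed postural angles,
combines them through three lookup tables into a 1–15 *score*, and maps
the score to a musculoskeletal-disorder risk band. Done by hand from
single photographs it is slow, subjective, and biased toward whatever
instant the photographer captured. `rebavision` automates the chain from
video-derived landmark streams: 33-point body landmarks per camera frame
and 478-point face landmarks (the conventions of modern pose/face
landmark detectors), three time-synchronized cameras to defeat occlusion,
and temporal averaging over all frames so that the score reflects the
sustained working posture rather than a single extreme instant.

## Pipeline

1. **Landmark IO and synchronization** (`read_landmark_stream`,
   `synchronize`). Streams are plain text (JSON-lines or CSV). Alignment
   is by integer frame offsets only; streams with different frame rates
   are rejected rather than silently resampled, because inventing a
   temporal interpolation would create data the cameras never recorded.
2. **Joint angles per camera** (`extract_joint_angles`). Angles are
   computed in each camera's 2-D image plane: the trunk against the image
   vertical, the upper arm against the trunk line, interior angles at
   elbow, wrist and knee. Each camera's view is graded independently;
   3-D reconstruction is deliberately out of scope — occlusion and
   foreshortening are handled downstream by fusion, which mirrors how the
   per-camera grading columns of a multi-camera worksheet are combined.
3. **Neck from head pose** (`estimate_head_pose`, `neck_angle`). Six
   stable face landmarks (nose tip, outer eye corners, mouth corners,
   chin) are matched to a canonical rigid template by
   perspective-n-point: a weak-perspective Procrustes initialization
   followed by Levenberg–Marquardt reprojection minimization, then
   Rodrigues conversion and Euler decomposition in the intrinsic x-y-z
   (pitch–yaw–roll) order. Pitch about the lateral axis is the neck
   angle. The default *absolute* reference returns camera-frame pitch —
   what a face-only chain actually measures; `trunk_relative` subtracts
   trunk flexion for anatomical neck flexion. The choice matters whenever
   the trunk leans; both are exposed and the default is documented
   because upstream conventions differ.
4. **Grading** (`grade_*`, `reba_total`). The worksheet bands are
   explicit, with the 0 *occlusion sentinel* reserved for joints whose
   landmarks were unobservable; 0 is never a grade and `reba_total`
   refuses it. Score A = Table A(neck, trunk, legs) + load; Score B =
   Table B(upper arm, lower arm, wrist) + coupling; total =
   Table C(A, B) + activity; bands: 1 negligible, 2–3 low, 4–7 medium,
   8–10 high, 11–15 very high.
5. **Fusion and averaging** (`fuse_frame`, `aggregate_series`). Per
   instant and joint, the maximum point across cameras — an occluded 0
   loses to any observed grade, so a joint is lost only if every camera
   loses it. Per joint over time: arithmetic mean *including* zeros,
   rounded half away from zero, then clamped to ≥ 1.
6. **Response surface** (`bbd_design`, `score_design`, `fit_linear`,
   `optimize_desirability`). A four-factor Box–Behnken design (neck,
   trunk, upper arm, lower arm; legs and wrist are constant in seated
   work and excluded) is scored by the chart and fitted with a
   first-order OLS model; desirability optimization over the factor box
   yields minimal/maximal attainable score profiles.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `visibility_threshold` | 0.5 | landmark confidence below which a joint is *missing* (becomes the 0 sentinel) |
| `adjustments()` | (1, 1, 1) | load, coupling, activity modifiers; the default is the calibration that reproduces 16/18 of the bundled survey totals and both verification profiles, and is configurable per session |
| `upright_tol` (trunk) | 2° | video angles are never exactly zero; within this tolerance the trunk counts as upright |
| posture flags | all `FALSE` | twist/side-bend, raised/abducted/supported arm, deviated wrist, unilateral stance: a sparse landmark set cannot infer these reliably, so they are analyst-asserted per session |
| `factor_spec()` | N 2–3, T 3–5, U.A 3–6, L.A 1–2 | min/max of the 14 seated survey profiles |
| desirability bounds | design response range | the standard response-surface software default |
| optimizer starts | 100 | multi-start bounded quasi-Newton, seed-deterministic |

## Averaging and zero handling

Two conventions were candidates: replace zeros *before* averaging, or
average zeros-included and clamp *after*. Only the latter reproduces both
bundled reference average rows cell-for-cell (including a trunk mean of
1.667 rounding to 2 and a wrist mean of 0.667 clamping to 1), so it is
the implemented rule: mean including zeros → round half away from zero →
clamp to ≥ 1. A joint lost by every camera in every frame therefore
scores the minimal grade 1, with a warning, which is the documented
fallback of the worksheet ("a grade of zero cannot be assigned").

Note the averaged-points vector is scored by the chart; the bundled
six-frame reference series carries an externally attributed overall score
that no chart-of-averages or average-of-charts convention reproduces, so
the per-joint average row, not that total, is the pinned expectation.

## Scoring fractional design levels

The chart is integer-only, but a Box–Behnken center point sits at factor
midpoints (e.g. neck 2.5). Rounding the level first (half-up, half-down
or half-even) quantizes 16 of 28 runs onto a handful of response values
and caps the first-order fit at an adjusted R² of about 0.79 — below the
quality a well-conditioned chart fit is known to reach. Multilinear
interpolation of the chart total over the neighboring integer corners
keeps the response exact at integer levels, is the natural continuous
extension of a monotone table, and lifts the fit to adjusted R² ≈ 0.90
(predicted R² ≈ 0.865, model p < 1e-8) with strictly positive
coefficients. `score_design()` therefore defaults to
`level_rounding = "interpolate"`, with the three integer conventions
available for sensitivity checks. The positive-coefficient property holds
under every convention.

The package also ships `reference_model()`, a pinned first-order
calibration (intercept −1.53635; coefficients 1.049, 1.0, 0.925148,
0.865374 for N, T, U.A, L.A) used for profile screening: across the 14
seated survey profiles its rounded predictions match every observed
total, with a maximum unrounded relative error of about 2%. Note that for
a purely linear model on a box, desirability optimization always selects
a corner; interior optima can only arise from interaction terms, which is
why only corner solutions are asserted for the pinned model.

## The synthetic scene generator

`scene_spec`/`render_views` build an articulated skeleton (pelvis →
trunk → neck/head; shoulders → elbows → wrists → index fingers; hips →
knees → ankles) realizing prescribed sagittal joint angles exactly, and
project it through three ideal pinhole cameras on a ring: camera A
frontal (face-directed, carrying the 478-point face stream with the six
pose landmarks exact), cameras B and C at ±120°, i.e. 30° away from pure
side views. Cameras are mounted at 1.2 m, aimed horizontally (so the
image vertical equals the world vertical), at a 6 m radius with a tele
focal — close to weak perspective, which keeps projective angle
distortion small and analyzable.

What it emulates:

* **Occlusion**: per camera, frame and joint, independently at
  `occlusion_rate`, by zeroing the visibility of the joint's *indicator
  landmarks*. Indicator sets are disjoint across joints (hips for trunk,
  elbows for upper arm, wrists for lower arm, index fingers for wrist,
  ankles for legs), so per-joint occlusions multiply independently:
  at rate 0.3 per camera the post-fusion rate is 0.3³ ≈ 0.027.
* **Foreshortening**: a segment pointing more than 35° out of a camera's
  image plane is depth-dominated; its joint's indicators get low
  visibility in that camera. The threshold is sized to the ring: sagittal
  motion is at most 30° out of plane for B and C (never gated), while the
  frontal camera is gated exactly where its projected angles could
  *inflate* a grade (the non-monotone lower-arm band is the critical
  case: an 80° elbow projects to ≈ 180° frontally).
* **Noise**: Gaussian, in normalized image units, on all landmark
  coordinates.

`random_scene_spec()` samples grade-representative postures with angles
kept a safety margin inside each grading band. The margins absorb the
worst-case projective distortion of the ring (≈ 4° per segment at 30°
off-side plus a small perspective residual), which is what makes the
noiseless end-to-end test *exact*: every camera that measures a joint
assigns the prescribed grade, and max-fusion then recovers the
ground-truth point vector identically.

What it does **not** emulate — and hence what a green test does not
establish: landmark detector bias and outliers (noise here is i.i.d.
Gaussian), clothing/soft-tissue artifacts, camera desynchronization,
rolling shutter, postures outside the sagittal plane (twists and
abductions enter only through analyst-set flags), or real angle
time-series dynamics (frames replicate one static posture). The
noisy/occluded property (fused total within ±1 of truth in ≥ 90% of
scenes) is a statement about this generative model, not about any real
camera system.

## Numerical choices and degenerate inputs

* Rotation handling: Rodrigues conversion with a second-order small-angle
  expansion at zero; axis extraction near 180° falls back to the
  symmetric-part method. Euler decomposition flags gimbal lock
  (|cos yaw| < 1e-9) and zeroes roll by convention.
* PnP: collinear observations are rejected up front (rank test);
  non-convergence raises an error carrying the iteration count.
  Reprojection RMS is reported on every estimate.
* `angle_at` uses `atan2(|cross|, dot)`, stable at 0° and 180°;
  zero-length limb vectors are errors, not NaNs.
* Grading band edges are closed on the benign side (e.g. exactly 20° of
  neck flexion still grades 1; exactly 60° or 100° of elbow flexion
  grades 1).
* Per-side joints grade both sides and keep the conservative (worse)
  side; for the lower arm, whose best grade is the *middle* band, "worse"
  means the worse grade with ties broken by distance from the 80° band
  center.
* When the hips are unobservable the upper arm is measured against the
  image vertical instead of the trunk line (documented fallback, keeps
  upper-arm availability independent of trunk occlusion).
* `predicted_r2` uses the PRESS statistic from leave-one-out hat values;
  `adjusted_r2` uses the n − p − 1 denominator. The ordering
  predicted ≤ adjusted ≤ plain holds on every tested design and is
  asserted for the chart-scored design.

## Known limitations

* Angles are graded per camera in 2-D; a posture whose risk is only
  visible in a view no camera covers is under-graded. This is inherent
  to the fusion design, which trades reconstruction complexity for
  occlusion robustness.
* Twist/abduction/support modifiers cannot be inferred from the landmark
  sets used; they must be asserted per session.
* Two of the 18 bundled survey totals (subjects 4 and 16) compute one
  point lower than observed under the default (1, 1, 1) adjustments; the
  original per-subject adjustment choices are unknown, and no constant
  setting reproduces all 18.
* The maximization optimum of the pinned linear model is necessarily a
  box corner; published interior maximization profiles can only stem
  from higher-order models, so only chart *verification* of such
  profiles is asserted, not optimizer agreement.
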