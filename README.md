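# rebavision

Automated **Rapid Entire Body Assessment (REBA)** from multi-camera pose
landmark streams.

REBA is the standard observational method for screening musculoskeletal
disorder (MSD) risk in sustained work postures — dentists, surgeons,
assembly workers. An assessor grades six joint regions into integer
*points* from postural angles, combines them through the REBA worksheet
tables into a 1–15 *score*, and reads off a risk band. Manual grading
from single photographs is slow, subjective, and biased toward whichever
instant was photographed.

`rebavision` automates the whole chain for video-derived landmark data
(33-point body and 478-point face schemas, as produced by modern pose
estimators), for ergonomics researchers and practitioners who want
repeatable scores from recordings:

* **joint angles** per camera frame from 2-D image geometry, with a
  visibility-gated missing-joint model;
* **neck angle via head pose**: perspective-n-point on six face
  landmarks, Rodrigues conversion, intrinsic x-y-z Euler decomposition
  (pitch drives the neck grade);
* **the REBA graders and tables**: Score A = Table A(neck, trunk, legs) +
  load, Score B = Table B(upper arm, lower arm, wrist) + coupling,
  total = Table C(A, B) + activity; bands 1 / 2–3 / 4–7 / 8–10 / 11–15 =
  negligible / low / medium / high / very high;
* **occlusion-resistant fusion** of up to three synchronized cameras:
  per instant and joint, the maximum point across cameras — an occluded
  joint (sentinel 0) loses to any observed grade;
* **temporal averaging** over all frames (zeros-included mean, round half
  away from zero, clamp to ≥ 1), so the score reflects the sustained
  posture, not one extreme frame;
* **response-surface layer**: four-factor Box–Behnken design generation,
  chart scoring, first-order OLS fit with ANOVA and adjusted/PRESS
  predicted R², and Derringer–Suich desirability optimization of point
  profiles;
* **a synthetic scene generator**: articulated skeleton with prescribed
  angles, projected to a three-camera ring with occlusion and noise
  injection — ground truth for every stage.

## Worked example

One instant seen by three cameras; camera C1 loses the trunk and leg to
occlusion (the 0 sentinels):

```r
library(rebavision)
tab <- make_points_fixture("fusion_instant")
tab
#>   frame camera neck trunk leg upper_arm lower_arm wrist
#> 1     0     C1    3     0   0         2         2     3
#> 2     0     C2    1     1   1         1         1     1
#> 3     0     C3    3     3   1         3         2     3

assess_points_table(tab)
#> <session_result> 1 frames, 3 cameras
#> averaged points: neck=3 trunk=3 legs=1 upper_arm=3 lower_arm=2 wrist=3
#> REBA total 9 (high risk); occlusion single C1=0.333 C2=0.000 C3=0.000, fused 0.000
```

Fusion recovers every joint (fused occlusion 0 despite 33% in C1) and
the chart scores the fused profile 9 — high risk (8–10), meaning change
in the working posture is needed soon.

End to end from landmarks, on a simulated 5-frame scene with 20%
per-camera occlusion and landmark noise:

```r
sc <- random_scene_spec(seed = 7, n_frames = 5,
                        occlusion_rate = 0.2, noise_sigma = 0.002)
rv <- render_views(sc)
assess_session(rv$session, rv$face_stream, intrinsics = rv$face_intrinsics)
#> <session_result> 5 frames, 3 cameras
#> averaged points: neck=2 trunk=2 legs=3 upper_arm=3 lower_arm=2 wrist=2
#> REBA total 9 (high risk); occlusion single A=0.733 B=0.267 C=0.333, fused 0.067
rv$truth$points   # prescribed ground truth: 2 2 3 3 2 2 -> recovered
```

The response-surface layer:

```r
fit <- fit_linear(score_design(bbd_design(factor_spec(), 4)))
fit
#> <reba_lm> REBA = 2.6369 + 0.66667 N + 0.6875 T + 0.56944 U.A + 0.41667 L.A
#> R2 0.9141, adj 0.8992, pred 0.8651

m <- reference_model()      # pinned calibration for profile screening
round(predict(m, c(2, 3, 3, 1)), 1)
#> [1] 7.2
head(optimize_desirability(m, goal = "minimize", seed = 1)$solutions, 1)
#>   N T U.A L.A response desirability
#> 1 2 3   3   1 7.202468            1
```

The minimal attainable profile (neck 2, trunk 3, upper arm 3, lower
arm 1; legs and wrist fixed at 1 and 2) predicts 7.2 and chart-verifies
at 7 — the design target a seated practitioner can aim for.

A command-line interface is installed as `exec/rebavision`
(`score`, `fuse`, `assess`, `design`, `simulate`); see `?rv_cli`.

## Scope

No video decoding, camera calibration, 3-D reconstruction, or RULA/OWAS
scoring. Posture modifiers that landmarks cannot reveal (twist,
abduction, support, stance) are analyst-asserted per session. See the
methods vignette (`vignettes/rebavision-methods.Rmd`) for the model,
conventions, and known limitations.
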