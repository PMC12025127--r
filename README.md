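# rgbdgaze

Measuring gaze intention from RGB-D landmark streams: where is a person
looking, and when is a child looking at a clinician's face?

`rgbdgaze` is for researchers and clinicians who work with consumer RGB-D
sensors (Azure-Kinect-style skeleton streams plus an eye-landmark
detector) and need quantitative gaze behaviour — target fixations,
child→clinician gaze periods, mutual gaze — without hand-annotating video.
The package consumes per-frame 3D landmarks (it does not process images)
and produces gaze rays, target intersections, interaction periods, and
period-level accuracy scores.

## The method

Two geometric estimators, switched by subject depth:

* **Eye-centre model** (depth ≤ 70 cm). The eyeball is a sphere carrying
  three detected surface landmarks: corners C₁, C₂ and a frontal surface
  point Oₑ′. With chord c = |C₁C₂| and sagitta h = |Oₑ′ − C|,
  C = (C₁+C₂)/2, the chord–sagitta relation gives the radius

      R = h/2 + c²/(8h)

  and the centre Oₑ lies at distance R from Oₑ′ along Oₑ′→C. Gaze is the
  anatomical axis Oₑ→Oᵢ (iris centre); the two monocular rays combine into
  a binocular ray (midpoint origin, bisector direction).

* **Skeletal head pose** (depth > 70 cm). From five face joints
  (eyes, nose, ears, each with a confidence score 0–3), the gaze ray runs
  from the face centroid MN = (N₁+N₂+N₃)/3 along ME→MN, where
  ME = (E₁+E₂)/2 is the ear midpoint. Joints scoring < 2 are recovered by
  rigidly (Kabsch) aligning the last fully-observed joint template onto
  the ≥ 3 remaining valid joints.

Rays are intersected with a target plane and with spheres enclosing other
people's heads; per-second hit flags become closed periods `[start, end]`
(majority vote within each second over valid frames). Detected periods are
scored against annotations with the interval IoU

    IoU = (min(Eₜ,Eₚ) − max(Sₜ,Sₚ)) / (max(Eₜ,Eₚ) − min(Sₜ,Sₚ))   (clipped at 0)

and OBOA, the indicator that the two durations differ by ≤ 1 s. A
synthetic generator (board-fixation sessions and scripted two-person
interactions, with landmark noise and confidence dropouts) provides ground
truth for every stage.

## Worked example

Simulate a subject 120 cm from the camera fixating board target 4 with
0.2 cm landmark noise, estimate gaze, and compare with ground truth:

```r
library(rgbdgaze)

sim <- simulate_board_session(
  synthetic_config(duration_s = 10, noise_sd = 0.2, seed = 42),
  position = 2, target = 4
)
est <- estimate_gaze(sim$frames, scene_config())
dplyr::count(est, method, valid)
#> 1 head   TRUE    300

head(dplyr::select(est, t, method, depth_cm, plane_x, plane_y, target_hit), 3)
#>        t method depth_cm plane_x plane_y target_hit
#> 1 0      head       120.   13.2    -454. target_4
#> 2 0.0333 head       120.   -1.37   -411. target_4
#> 3 0.0667 head       120.    4.32   -434. target_4

err <- angular_error(as.matrix(est[, c("dir_x", "dir_y", "dir_z")]),
                     as.matrix(sim$truth[, c("head_dir_x", "head_dir_y", "head_dir_z")]))
round(mean(err), 2)
#> 1.46
```

At 120 cm the gate selects the head method for all 300 frames; every noisy
ray still lands nearest target 4, with a mean angular error of 1.46°.

Scoring the packaged child–clinician session (manual annotations vs
pipeline detections):

```r
m <- match_periods(session_periods(1, "truth"), session_periods(1, "detected"))
m
#> <period_matches> 11 matched, 0 missed truth, 1 false detections
#>    truth       detected    overlap        iou  oboa
#>  1 5:37-5:38   5:37-5:38   5:37-5:38   1          1
#>  ...
#>  5 20:44-20:45 20:44-21:12 20:44-20:45 0.0357     0
#> 10 45:18-45:20 45:17-45:19 45:18-45:19 0.333      1

glance(m)
#>   mean_iou mean_oboa n_matched n_missed_truth n_false_detections
#> 1    0.673     0.727        11              0                  1
```

Every annotated period is detected (mean IoU 0.67, mean OBOA 0.73 over the
11 matched periods); one detection at 30:33–30:34 has no annotated
counterpart. `autoplot(m)` draws the truth/detected/overlap timeline.

A thin CLI wraps the same functions
(`inst/cli/rgbdgaze.R`: `simulate`, `estimate`, `periods`, `evaluate`,
`replicate-table7`).

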