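# skilledreach

Reach-to-grasp kinematics for the rodent single-pellet skilled reaching
task, tracked with a single high-speed camera plus angled mirrors.

Rats learning to reach through a slot for a sugar pellet refine both
"gross" forelimb transport and "fine" digit control, on different
timescales. Quantifying that refinement requires going from two-view 2D
keypoints (e.g. DeepLabCut output for the hand dorsum, digit tips 1–4, the
second MCP joint, and the pellet, at 300 frames/s) to 3D trajectories in a
pellet-centred frame, and from those to a small set of kinematic
statistics. This package implements that pipeline end to end for
researchers analysing automated skilled-reaching experiments:

* **Mirror-pair calibration** — the direct camera and the "virtual" camera
  behind the mirror are related by an essential matrix `E` estimated from
  checkerboard-cube correspondences (normalized 8-point with Hartley
  conditioning, Sampson-error refinement, cheirality-resolved
  decomposition); metric scale comes from the known 4 mm checker square.
* **Triangulation and quality control** — homogeneous DLT triangulation
  with reprojection-error filtering; keypoints are gated by the tracking
  confidence rule (valid above 0.97; mislabeled below 0.85; in between,
  mislabeled when the displacement between consecutive frames surpasses
  50 px).
* **Segmentation** — frame-level rules for reach start (backtracking from
  the slot crossing to the onset of forward hand velocity), reach end
  (onset of digit-2 retraction), and the grasp (digit-2 flexion minimum to
  its subsequent maximum), with multiple reaches enumerated per trial.
* **Kinematics** — trajectories resampled at 100 arc-length-uniform points
  (pchip); session trajectory variability

  D̄ = [ Σ_trials Σ_{i=1..100} |X_i − X̄_i| / 100 ] / n  (mm),

  the mean 3D distance of each interpolated trial trajectory from the
  session-mean trajectory; endpoint **generalized variance** det(Σ̂) of 3D
  reach endpoints; grasp aperture `a` (digit-1 to digit-4 distance), hand
  orientation `θ`, digit flexion `δ`; circular consistency via the mean
  resultant length (MRL); and coordination profiles of a/θ/δ on the
  z_digit2 grid (−20.0 … +15.0 mm, 0.1 mm steps, sampled at +3 mm).
* **Session statistics** — first-reach success rate (score-1 trials over
  trials scored 1, 2, 3, 4 or 7; undefined under 10 qualifying trials),
  moving 10-trial averages with carry-forward alignment across rats, and
  learner classification: a rat is a *learner* when a Pearson χ² test on
  first-success proportions (days 1–2 vs 9–10) gives p < 0.05 **and** the
  proportion increased.
* **Inference** — linear mixed models with per-rat random intercepts and
  day × group (or day × outcome) fixed effects (Satterthwaite df via
  lmerTest), within-session variability–success correlations, and
  5000-resample bootstrap estimates of each day's mean difference from
  day 1.
* **Synthetic cohorts** — a ground-truth generator renders parametric
  reach-to-grasp movements as two-view DLC-style keypoint tables with
  configurable learner/non-learner schedules, occlusions and mislabels, so
  every stage is testable without raw video.

## Worked example

```r
library(skilledreach)
set.seed(1)

scene <- synthetic_calibration()                       # ground-truth geometry
pairs <- generate_checkerboard_correspondences(scene)  # calibration images
cal   <- calibrate_mirror_views(pairs, scene$camera)
cal
#> mirror_calibration: rotation 75.0 deg, scale 365.257 mm/unit, median epipolar residual 2.02e-14

g   <- generate_reach_trajectory()          # one synthetic trial
obs <- project_to_views(g$traj, scene)      # two-view keypoints

# triangulate digit 2 and place it in the pellet frame
o1 <- obs[obs$bodypart == "digit2" & obs$view == "direct", ]
o2 <- obs[obs$bodypart == "digit2" & obs$view == "mirror", ]
tri <- triangulate_points(cbind(o1$x, o1$y), cbind(o2$x, o2$y), cal)
rec <- to_pellet_frame(tri$points, scene$pellet_origin, "right")
max(abs(rec - g$traj$positions$digit2))     # reconstruction error, mm
#> [1] 4.945377e-12

segment_trial(g$traj)
#>   reach_ordinal reach_start slot_crossing reach_end grasp_start grasp_end
#> 1             1          30            38        52          53        60
#>   truncated degenerate_grasp
#> 1     FALSE            FALSE
```

The recovered events match the generator's analytic ground truth frame for
frame; with realistic 0.2 mm tracking jitter they stay within ±2 frames on
over 95% of trials (see the test suite).

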