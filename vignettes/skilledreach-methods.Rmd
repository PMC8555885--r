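---
title: "Methods: reach-to-grasp kinematics from mirror-based pose tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reach-to-grasp kinematics from mirror-based pose tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(skilledreach)
```

# The measurement problem

In the automated single-pellet skilled reaching task a rat reaches through
a narrow slot for a sugar pellet presented 15 mm beyond the slot front,
while one high-speed camera (300 frames/s) films the slot head-on and
angled mirrors provide side views in the same image. Pose-tracking
software labels the hand dorsum, the four digit tips, the second
metacarpophalangeal (MCP) joint and the pellet in both the direct and
mirror views, with a per-point confidence. The analysis must (i) turn
those two 2D views into 3D trajectories in a pellet-centred frame, (ii)
cut each trial into reach and grasp phases, and (iii) summarise sessions
with a handful of kinematic statistics that track motor learning.

# Mirror-pair geometry

The mirror view is the image of a *virtual camera* behind the mirror.
Because a mirror reverses handedness, mirror-view x pixel coordinates are
reflected (`x -> image_width - x`) before any estimation, making the
virtual camera a proper rotation of the real one; the flag is recorded in
the calibration object (`mirror_flip`). Both cameras share one intrinsic
matrix (same physical lens), supplied as input; lens distortion is not
modelled.

Calibration uses corner correspondences of a cube carrying 4 mm
checkerboards, imaged at several positions across the reaching workspace.
The essential matrix is estimated by the normalized 8-point algorithm
(pixels mapped through the intrinsics, Hartley conditioning, smallest
singular vector, projection onto the essential manifold with equal
nonzero singular values), then refined by minimizing the mean Sampson
distance over the rotation and the translation direction. The refinement
matters: with half-pixel corner noise, the linear estimate alone leaves
rotation errors of a few degrees in this narrow-baseline geometry, while
the refined estimate is reliably within a fraction of a degree. The four
rotation/translation candidates are disambiguated by a cheirality test
(triangulated calibration points must lie in front of both cameras).

The epipolar translation is only defined up to scale. Metric scale is
fixed by least squares so that reconstructed distances between
grid-adjacent checker corners match the physical 4 mm square; the
correspondence tables therefore carry `frame`/`face`/`row`/`col` ids so
neighbours can be identified within a single cube pose.

Keypoints valid in both views are triangulated by homogeneous DLT, and
points whose mean two-view reprojection error exceeds a threshold are
excluded. The threshold default is 10 px (configurable); the reprojection
filter targets points identified correctly in one view but misidentified
in the other. A point displaced *along* its epipolar line is invisible to
this residual, which is why the confidence/jump validity rule below gates
every point before reconstruction rather than relying on reprojection
alone.

Finally, trajectories are translated so the pellet (median valid pellet
position over the 10 valid frames preceding reach start) is at the
origin, with +x to the right of the pellet, +y above it, and +z on the
far side of the pellet from the chamber; left-hand reaches have x negated
so both hands are directly comparable.

# Keypoint validity

A tracked point is taken as correctly labeled when its confidence exceeds
0.97 and as mislabeled below 0.85. In the intermediate band the decision
falls to movement: a displacement of more than 50 px from the reference
frame marks the point mislabeled. All three boundaries are strict
(exactly 0.97, 0.85 and 50 px are on the permissive side), a convention
fixed here because the verbal rule is directional but silent at equality.
By default the jump reference is the most recent frame already classified
valid, which avoids flagging the first good frame after an occlusion; a
strict previous-frame variant is available (`reference = "previous"`),
and under it the monotonicity of the rule in its thresholds is exact.
Mislabeled points are excluded from all downstream reconstruction, never
imputed. The per-trial mislabeled-frame percentage counts a frame as
mislabeled when either view is flagged, over the reach-start-to-grasp-end
window.

# Segmentation rules

* **Slot crossing**: first frame in which any valid digit tip has z beyond
  the slot plane. The slot plane sits at z = −15 mm in the pellet frame
  (the pellet is 15 mm beyond the slot front); it is configurable for
  other chambers.
* **Reach start**: scanning backwards from the slot crossing, the reach
  begins at the frame after the hand dorsum's forward (z) velocity was
  last non-positive for k consecutive valid-frame steps (k = 2 default).
  If the backtrack reaches the series start, the first frame is used.
* **Reach end**: the first frame after the slot crossing at which digit-2
  z decreases on the next valid frame — the onset of retraction.
* **Grasp**: the grasp starts at the first frame after the global flexion
  minimum (maximum digit extension) in the search window at which flexion
  strictly increases, and ends at the first frame attaining the maximum
  flexion of the post-start segment. Ties take the earliest frame;
  monotone flexion flags a degenerate grasp.

Invalid frames inside a search window are skipped, not interpolated.
Multiple reaches per trial are enumerated by repeating the rules after
digit 2 retracts back inside the slot plane; analyses consume the first
reach. No smoothing is applied before extremum detection by default: a
centred 3-frame median filter (`smooth = "median3"`) is available, but on
a clean unimodal advance it can shift the detected retraction onset by one
frame (the filtered peak ties with its neighbour), so the raw-series rule
is the default and is exact on noiseless data. Robustness to label noise
comes instead from the steepness of real flexion/extension transients;
with 0.2 mm jitter the five events stay within ±2 frames on >95% of
synthetic trials.

# Kinematic statistics

* **Arc-length resampling.** Each segment (reach or grasp) is resampled at
  100 points uniform in cumulative chordal arc length, using monotone
  piecewise cubic Hermite (pchip) interpolation per coordinate. The
  parameterization is purely geometric: trajectories traversed at
  different speeds (or with pauses, which appear as repeated samples) give
  identical resampled point sets, so matched station indices correspond
  across trials.
* **Trajectory variability.** D̄ is the mean over trials of the mean 3D
  Euclidean distance between a trial's 100 stations and the session-mean
  trajectory, in mm; within-session series use moving 10-trial blocks with
  each window's own mean as reference. D̄ is invariant under rigid motions
  applied to all trials.
* **Endpoint dispersion.** The generalized variance is the determinant of
  the 3×3 sample covariance (n−1 denominator) of per-trial endpoints at
  reach end, in mm^6; below 4 endpoints it is flagged undefined. The
  hand-subtracted variant applies the same statistic to digit-minus-hand
  endpoints, removing transport variability.
* **Hand shaping.** Aperture is the 3D digit1–digit4 tip distance;
  orientation is the angle of the (undirected) digit1–digit4 line against
  horizontal in the direct camera view, in [0, 180), computed from the
  2D direct-view labels (with y up and left-hand x negated); flexion is
  the angle at MCP2 between the dorsum→MCP2 and MCP2→tip directions, with
  0° = fully extended. Angular consistency is summarised by the mean
  resultant length.
* **Coordination.** For the first reach of each trial, aperture,
  orientation and flexion are pchip-interpolated onto a z_digit2 grid of
  −20.0 … +15.0 mm in 0.1 mm steps (351 stations), each trial
  contributing only over the z range it covers (its z series reduced to
  the strictly increasing advance); stations are averaged over
  contributing trials and compared across days at z_digit2 = +3 mm.
* **Velocity and duration.** Speed is the hand-dorsum displacement between
  consecutive valid frames times the frame rate; duration is
  (reach_end − slot_crossing)/300 s.

# Session statistics and learner calls

First-reach success rate is score-1 trials divided by trials scored 1, 2,
3, 4 or 7, undefined when fewer than 10 qualifying trials were performed.
Within-session series use moving 10-trial blocks; when rats perform
different trial counts, each rat's last value is carried forward to the
group maximum before averaging, which avoids dropout artefacts in group
means. Outcome breakdowns report the percentage of each score 0–9 (these
sum to 100); the hand-through-slot category is a flag on otherwise scored
trials and is reported as an additional percentage.

A rat is classified a learner when a Pearson χ² test (df = 1, no
continuity correction; a Yates-corrected variant is available) comparing
first-success proportions among qualifying trials between days 1–2 and
days 9–10 gives p < 0.05 *and* the proportion increased; a significant
decrease is a non-learner. Because every truly flat rat is an exact null
for this rule, its false-positive floor is about α/2 per rat — with ten
flat rats in a cohort, perfect 14/14 label recovery occurs in roughly
(1 − α/2)^10 ≈ 78–88% of replicates even though per-label accuracy is
≈ 98–99%. This ceiling is a property of the decision rule, not of the
implementation; the acceptance script reports both rates.

# Group-level inference

Day and group effects are estimated with linear mixed models
(`response ~ day * group + (1 | rat)`), day numeric 1–10 and the
non-learner level as reference, with t statistics and Satterthwaite
approximate degrees of freedom (lmerTest). Success/failure contrasts use
the same structure with outcome replacing group, fitted per group. An
exactly constant response short-circuits to zero slopes (the mixed-model
machinery degenerates there). Within-session correlations between moving
variability and moving success rate are Pearson correlations with
two-sided p. Day-vs-day-1 contrasts are estimated by resampling both
days' values with replacement (5000 resamples, percentile 95% CI,
deterministic under a seed).

# The synthetic cohort generator

No raw tracked videos accompany the study design this package targets, so
validation rests on a generator whose ground truth is known analytically.

* **Shape model.** The digit-2 tip advances along z with a raised-cosine
  bump from inside the box (−22 mm) to a single peak past the pellet
  (+8 mm by default) and retracts below the slot plane; hand height and
  pronation follow the advance; flexion holds at its transport value,
  dips steeply to a single minimum at the advance peak and rises steeply
  to a single maximum during the grasp. Raised-cosine segments guarantee
  the unimodal, monotone-segment structure that the segmentation rules
  assume, so every event frame is known in closed form. Segment
  steepness (8-frame extension/grasp transients) reflects the
  tens-of-milliseconds digit transients seen at 300 fps and keeps
  extremum detection well-conditioned under label noise. Before movement
  onset the hand drifts slowly backwards (0.5 mm/frame over 10 frames),
  as after withdrawal from a previous attempt; this makes the onset of
  forward velocity a genuine sign transition rather than a zero-noise
  tie.
* **Hand construction.** The MCP joint and hand dorsum hang behind the
  digit-2 tip along the hand axis so the designed flexion is reproduced
  exactly by the angle definition; digits 1 and 4 flank digit 2
  perpendicular to the reach axis so designed aperture and orientation
  are exact. The pellet is stationary at the origin and never jittered.
* **Noise model.** I.i.d. Gaussian per-frame, per-coordinate jitter (the
  day's "trajectory noise", mm) plus a rigid per-trial offset with SD
  half the jitter SD, giving both within-trial wobble and between-trial
  endpoint dispersion, the two components D̄ and the generalized variance
  respond to.
* **Schedules.** Defaults encode the emulated study design: 14 rats
  (4 learners), 10 daily sessions, 30–40 trials each. Learners raise
  first-success probability linearly 0.10 → 0.50 while trajectory noise
  falls 2.0 → 0.5 mm; non-learners stay at 0.25 and 1.5 mm. Non-success
  scores are spread over the full outcome taxonomy (failed first reaches
  dominating) so every scoring path is exercised.
* **Projection.** Trials are rendered through a simulated real + virtual
  camera pair (75° mirror rotation, ~30 cm working distance, 2400 × 1024
  sensor). Clean points draw confidence above 0.97; planted mislabels are
  displaced 60–200 px with confidence below 0.97 (mixing the intermediate
  band and sub-0.85); occlusions drop a point from one randomly chosen
  view. Raw mirror pixels are written reflected, as a physical mirror
  produces them.
* **Randomness.** One sequential RNG stream per rat-day, derived from the
  cohort seed, keeps per-rat data reproducible when cohort composition
  changes. A per-trial reseeding scheme was rejected: first draws of
  structured nearby seeds are super-uniform, under-dispersing binomial
  trial counts and visibly biasing the χ² classification toward
  conservatism.
* **Trial-to-trial correlation** of kinematics beyond the rigid offset is
  not asserted (real data may drift within a session); the offset scale
  is the single exposed knob.

# Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to make
binomial/Monte-Carlo tolerances meaningful on one CPU in a few minutes:
300–500 segmentation trials per condition, 100 cohort replicates for
label recovery, 10 rendered learner cohorts for the variability trend,
n = 200 endpoints for generalized-variance recovery, 500 null
simulations for mixed-model size and 100 for slope coverage, 5000
bootstrap resamples, and 10^4 draws for the von Mises MRL check against
the Bessel ratio I1(2)/I0(2). Key numerical conventions: Hartley
conditioning before the 8-point solve; essential-matrix singular values
averaged for the manifold projection; Frobenius normalisation of E;
chordal (not arc-exact) cumulative length as the resampling parameter;
consecutive duplicate points collapsed before pchip; earliest-frame
tie-breaks at extrema; strict inequalities at all quality boundaries;
n−1 covariance denominators.

# Known limitations

* The generator's reaches are smooth and single-peaked by construction;
  real reaches include aborted advances, double pumps and collisions, so
  passing tests demonstrate rule fidelity, not robustness to every
  behavioural irregularity.
* Estimating an occluded digit tip from epipolar geometry (to rescue
  aperture frames) is not implemented; frames missing either tip are
  skipped.
* Intrinsics are accepted as input and shared between real and virtual
  cameras; no distortion or bundle adjustment.
* Mixed-model degrees of freedom use the Satterthwaite approximation;
  other df conventions will give slightly different t/df/p triplets.
* The learner rule's per-replicate recovery ceiling discussed above means
  cohort-level "all labels correct" rates cannot approach 1 for flat
  non-learners at α = 0.05, whatever the trial counts.
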