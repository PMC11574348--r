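---
title: "Methods: tail-mediated balance analysis on a tiltable ridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tail-mediated balance analysis on a tiltable ridge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailbalance)
```

## The analysis problem

A mouse crosses a 500 mm ridge, 4–45 mm wide, that can tilt abruptly in
the roll plane (10/20/30 degrees over 150/190/230 ms). Two cameras record
at 300 frames/s: a rear camera sees the roll plane (tail elevation, hip
line), a top camera sees the yaw plane (body axis, forward progress). A
markerless tracker supplies per-frame (x, y, likelihood) for named
bodyparts; a silhouette centroid from the top view stands in for the
centre of mass (CoM). From these, the package computes posture angles,
step-cycle-aligned kinematics, balance-performance metrics, a
rod-and-cylinder estimate of the angular momentum carried by tail, body
and perturbation, and the tail–body momentum coupling through the step
cycle.

## Conditioning the trajectories

Samples with tracking likelihood below the cutoff (default 0.9) are
invalidated and **linearly interpolated** between the nearest valid
neighbours (edge gaps take the nearest valid value). Interpolation — as
opposed to dropping or holding samples — keeps every downstream gradient
defined; the choice is exposed through the cutoff parameter and the
per-bodypart replacement counts are reported. A bodypart with no valid
sample aborts the trial with an `unusable bodypart` error, which cohort
runs record in the exclusions table.

All coordinate series are then smoothed with a **Hanning window of 10
frames (33 ms)**, weights normalized to unit sum. Two numerical details:

* Edges are reflect-padded (the edge sample itself is not repeated), so
  output length equals input length and constant series pass unchanged.
* An even-length kernel cannot be centred on a sample; convolving with
  it shifts every series by half a frame and, on ramps, biases means.
  We therefore average the kernel's two half-sample placements, i.e.
  smooth with the equivalent zero-phase odd kernel of length 11. This
  preserves linear trends exactly and the mean of constant-padded series
  to better than 1e-9.

The two views are aligned on the first frame at which the top-view
centroid is visible, and the **500 time-centred samples** of the aligned
streams form the analysis window (an odd surplus drops the extra sample
from the end). Image coordinates (y down) become math coordinates
(y up) at the I/O boundary; every angle definition below assumes y up.

## Angle conventions

* **Roll-plane tail angle** (rear view): direction of the tail base →
  first post-base marker segment, measured from straight down; 0 = down,
  90 = horizontal on the animal's right, 180 = up, range [0, 360). The
  initial segment is used because the swing starts from the tail base
  and the tail stays straight at swing onset.
* **Yaw-plane tail angle** (top view): signed angle from the backward
  ridge direction; 0 = straight back, positive = clockwise (toward the
  animal's right when the top view's +y is its left), range (−180, 180].
* **Hip angle** (rear view): angle of the hip-marker line to vertical,
  folded to [0, 180]; 90 = horizontal. A *signed* variant
  (`hip_angle_signed`, >90 when the right hip is lower) preserves tilt
  direction and is the trace differentiated for body angular velocity.
* **Back angle** (top view): signed angle at the tail base between the
  forward ridge-parallel line and the base → centroid vector; 0 = hind
  body straight back.
* **Front angle**: signed angle between the centroid → nose direction
  and the ridge axis; 0 = head straight ahead.
* **Tail-on-body angle**: yaw-plane tail angle minus back angle, wrapped
  to (−180, 180].

Angular velocity is the frame-by-frame gradient of the **unwrapped**
angle (central differences in the interior, one-sided at the ends,
scaled by the frame rate). Central differences are second-order
accurate; unwrapping first prevents spurious 360-degree jumps from the
branch cut.

**Laterality and mirror-normalization.** The side the tail is held on is
read from the roll angle (below 180 = right); a tilt toward that side is
ipsilateral (IL), away contralateral (CL). A tail exactly vertical at
onset is unclassifiable and flags the trial. Because left- and
right-held trials are pooled, every trial is mirror-normalized to a
canonical right-held tail (roll → 360 − roll, signed yaw-plane angles →
−θ, signed hip → 180 − θ); raw signed traces are retained alongside.
Applying the mirror twice is the identity, which the tests check on all
trace types.

## Step cycles

Step events are local maxima of the contralateral (to the tail) hind
paw's forward excursion. Because the camera-frame paw coordinate is a
staircase riding a ramp, the pipeline peaks the paw position *relative
to the tail base*. Peak detection enforces a minimum separation (default
half the expected stride period; the expected stride rate is 4 Hz) and a
minimum topographic prominence (default a quarter of the series IQR),
accepting candidates greedily by height. Epochs of ±1 median stride
period around each event (two-cycle windows) are stacked; windows that
would overrun the trial are excluded, and a trial with no detected peaks
is excluded from cycle analyses with a logged reason. Per-epoch summary
statistics are the trace mean (mean position) and max − min (range),
averaged per trial.

## Balance metrics

All five metrics derive from the top-view centroid and the ridge
geometry in the trial metadata (the midline is taken from metadata, not
fitted; the mm-per-pixel scale is calibrated from the known 500 mm ridge
length). Traversing speed is endpoint forward displacement over elapsed
time; a variant excluding stop time is also reported, since it is not
obvious whether stops should count toward the denominator — both are
kept. Stops are maximal runs of instantaneous forward speed (gradient of
the smoothed forward coordinate — deliberately distinct from the
endpoint-based trial speed) below 1 mm/s. Time outside the base of
support counts frames with |lateral offset| *strictly* greater than half
the ridge width. Lateral movement is the mean absolute offset; central-
ity is 1 − |offset|/(width/2), clipped at 0 beyond the edge (the
definition anchors only the midline at 1 and the edge at 0; clipping is
the natural extension that keeps the trial mean in [0, 1]).

## The biomechanical model

Angular momentum is L = I·ω per source:

* **Tail**: uniform rod, I = ⅓ m l² about an axis through its **base**
  (default m = 0.5 g, l = 7 cm). The base axis is chosen because the
  swing starts from the tail base; a centre-axis variant (1/12 m l²) is
  a one-argument switch.
* **Body**: solid cylinder about its central axis, I = ½ m r²
  (m = 20 g, r = 1 cm), with ω from the signed hip angle.
* **Perturbation**: the platform ramp imposes ω_p = amplitude/duration
  during the tilt and 0 elsewhere, on the whole animal
  (M = m_body + m_tail). What "radius" means for an animal at the edge
  of a tilting platform is genuinely ambiguous, so three inertia
  readings are implemented: a cylinder of the platform radius
  (½ M r_p²), a point mass at the edge (M d²), and — the default — the
  body cylinder displaced to the edge by the parallel-axis theorem
  (½ M r_b² + M d², d = r_b), which avoids the implausibly small
  momentum the bare-cylinder reading gives at small radii. The variant
  is recorded in every output.

Window totals are trapezoidal time-integrals (exact on the
piecewise-linear interpolant, with fractional endpoints interpolated, so
adjacent windows add exactly); both signed and absolute modes exist, and
cohort summaries default to **absolute** totals, reading "total
momentum" as the magnitude of momentum generated. Relative momentum
divides tail, body and sum totals by the perturbation total over the
same window; the response is analysed over 0.5 s after tilt onset, split
into an early phase (the ramp itself) and a late phase (ramp end to
window end). Under the default parallel-axis variant and these
conditions the tail-plus-body total *exceeds* the perturbation total
severalfold on synthetic cohorts (`scripts/acceptance.R` prints the
value); the ratio scales inversely with the assumed perturbation
inertia, so it should be read comparatively across conditions, not as an
absolute compensation fraction.

## Coupling analysis

For a given ridge width, tail and body momentum epochs (non-perturbation
trials only — tilt responses are not step-locked and would swamp the
locomotor coupling) are pooled and correlated **across epochs**: C[i, j]
is the Pearson correlation of tail momentum at bin i with body momentum
at bin j. The across-trial reading follows from the matrix ("cells")
form of the analysis; a within-trial variant (epochs mean-centred first)
is available behind a flag. Zero-variance bins give undefined cells,
excluded from percentile pools. Hotspots/coldspots collect cells in the
upper/lower 5% tails of the correlation distribution and return the
largest 8-connected component; ties go to the component whose mean
correlation is more extreme in the tail's direction (this, rather than
the largest absolute mean, keeps detection invariant to adding a
constant). The diagonal C[i, i] is the zero-lag coupling through the
step cycle.

## Statistics

One-way ANOVA uses the classic between/within sum-of-squares
decomposition; post hoc comparisons are all pairwise pooled-variance
t-tests with Bonferroni multiplication (capped at 1, flagged at 0.05);
the unpaired t-test is pooled-variance (df = n₁ + n₂ − 2), matching the
ANOVA workflow, with Welch's variant behind a flag. Tail probabilities
come from R's F and t distributions. Zero within-group variance with
equal means is a degenerate case and is flagged rather than fabricating
a statistic. Cohort statistics aggregate to per-animal means before
testing, so animals — not trials — are the experimental unit.

## What the synthetic generator emulates

`simulate_trial` produces both camera views, the centroid trace,
metadata and ground truth from: step-locked sinusoidal paw/hip/tail
oscillations at 4 Hz with a shared slowly varying per-stride "vigor"
gain (s.d. 0.3) that couples tail and hip amplitudes; a side-held tail
(width-dependent mean roll, below 90° on ≤5 mm ridges, oscillation
amplitude increasing as ridges narrow); anti-phase tail-hip phasing
(φ = π); centroid progress at 150 mm/s with ~1.5 mm lateral wander;
Gaussian pixel noise (1 px) and likelihood dropouts (2%) that exercise
the conditioning path; and, on tilt trials, a **minimum-jerk** tail
swing away from the held side whose amplitude A follows from the peak
speed s and time to peak D via the minimum-jerk identity
v_peak = 1.875·A/D (defaults s = 2.2 rotations/s, D = 0.16 s; hip
deflection 14° with D = 0.12 s), with the rhythmic oscillation smoothly
gated off during the response. CL swings keep the same peak speed over a
0.6× range, emulating the ridge limiting the movement. The minimum-jerk
waveform is the standard smooth, bell-shaped-velocity model for
stereotyped, invariant movements; the generator's defaults are the study
conditions and are not adjusted per analysis.

What it does **not** emulate: perspective and lens distortion, marker
occlusion structure (dropouts are i.i.d.), slip biomechanics (slips are
labels only), stance/swing asymmetries, inter-limb coordination beyond
one anti-phase pair, and any learning or fatigue across trials. Passing
recovery tests on this generator therefore validates the *computational
chain* — conditioning, angle conventions, event detection, momentum
arithmetic — not the biological realism of real videos.

## Numerical and estimator choices

* Peak swing speed is read from a 7-point median-filtered velocity
  trace: the median filter suppresses residual pixel-noise spikes that
  otherwise bias a max-statistic upward, while leaving the smooth swing
  peak essentially unattenuated (the known Hanning attenuation of the
  minimum-jerk peak at these window/duration ratios is below 2%).
* Times to peak are argmax of the re-smoothed displacement from onset.
  When the deflection plateau is flat relative to residual noise (the
  14° hip deflection, unlike the ~68° tail swing), the argmax wanders
  late by a few tens of ms; the reported body time-to-peak therefore
  over-reads the emulated 0.12 s. This is a property of the estimator
  at this signal-to-noise, documented rather than hidden.
* Stride frequency uses the mean inter-event interval
  ((last − first)/(n − 1)), which averages out the ±2-frame
  quantization of individual peak positions; the median interval is
  kept as the robust per-trial period for epoch widths.
* Angles are computed with `atan2`; coincident points raise errors
  rather than returning arbitrary values.
* Problem sizes: validation suites use 20-seed batches of 3 s trials;
  cohort-level checks use 15 animals × 4 widths × 2 trial types with
  one or two trials per condition, sizes at which every property is
  stable while the full suite runs in about a minute.

## Known limitations

* No 3-D reconstruction: each angle lives in one camera's plane, and
  the scalar mm-per-pixel calibration ignores perspective.
* The perturbation inertia is model-dependent (three variants span an
  order of magnitude); relative momentum is comparative, not absolute.
* The correlogram's across-trial reading needs ≥3 epochs per bin pair
  and is undefined on zero-variance bins.
* HDF5 keypoint containers are not read; the CSV dialect is the
  interchange format (the writer round-trips it at full precision).
* Automated slip detection is out of scope; slip counts are consumed as
  manual labels.
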