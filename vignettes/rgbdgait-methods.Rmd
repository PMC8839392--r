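---
title: "Markerless gait analysis from a single RGB-D camera: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless gait analysis from a single RGB-D camera: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgbdgait)
```

## The problem

Quantifying how a person walks — step length, step timing, stance and
double-support phases, cadence, step width, and how much the body sways —
normally requires an instrumented gait laboratory: a marker-based
optoelectronic system, force platforms, trained operators. People with
Parkinson's disease or post-stroke hemiparesis, who are exactly the people
whose gait most needs monitoring, rarely have access to such a laboratory
outside occasional hospital visits.

A single consumer RGB-D camera (a Kinect-v2-class depth sensor) offers a
cheap alternative: its body-tracking produces a 25-joint skeleton at about
30 frames/s while the subject walks toward the sensor. Because depth
accuracy degrades both far from and very close to the sensor, the analysis
is restricted to a *gait analysis path* (GAP): a corridor whose start line
is 4.2 m and whose end line is about 1.5 m from the camera. That corridor is
short — it fits in a living room — but long enough to capture at least one
complete gait cycle per leg in slow, pathological gait.

`rgbdgait` implements the complete processing chain from raw skeletal
trajectories to the eight reported gait parameters, a synthetic gait
generator that makes every stage testable without hardware or patients, and
the two-system agreement statistics used to compare such a camera against a
gold-standard system.

## The pipeline

`analyze_gait()` runs five stages, each exported on its own.

1. **Resampling** (`resample_uniform()`). Capture timestamps jitter around
   30 FPS, so every coordinate channel is interpolated with a natural cubic
   spline onto an exact 50 Hz grid spanning the original support. No
   extrapolation is performed, and resampling an already uniform 50 Hz
   sequence is the identity on its samples. Frames flagged `not-tracked`
   are bridged by the spline; a bridged gap longer than 200 ms (config
   `max_gap_ms`) raises a structured warning rather than splitting the
   recording — every downstream contract operates on a single sequence, so
   the decision to discard an interrupted trial is left to the caller.
2. **Filtering** (`lowpass()`). A 4th-order Butterworth low-pass at 10 Hz,
   applied forward and backward so that it is zero-phase: group delay would
   shift every detected gait event. Edge transients are controlled by
   odd-reflection padding around the two passes (the padding `filtfilt` in
   the `signal` package lacks; without it a constant channel picks up an
   edge error of order 1). DC gain is exactly 1. Stride fundamentals are
   below 2 Hz, so the 10 Hz band keeps all gait information while removing
   sensor noise; the amplitude response leaves a 2 Hz sine above 99.8% and
   suppresses a 20 Hz sine below 10^-4^.
3. **GAP window** (`com_body()`, `detect_gap_window()`). The body center of
   mass is proxied by the unweighted centroid of SpineBase, SpineMid,
   HipLeft and HipRight — trunk joints, robust against limb tracking noise;
   the joint set is an argument so the estimator can be swapped. Entry is
   the first frame whose full 3D Euclidean COM distance from the sensor
   origin falls to 4.2 m; exit is the first later frame below 1.5 m, or the
   last frame. Both distances are configuration (`gap_start_m`,
   `gap_end_m`): the end line in particular is approximate and rooms differ.
4. **Step segmentation** (`binarize_ankle()`, `clean_activity()`,
   `extract_steps()`, `exclude_boundary_steps()`). Each ankle's depth (z)
   channel is binarized: a frame is *in movement* when the absolute
   difference to the next sample strictly exceeds 2 cm, i.e. when the ankle
   moves faster than 1 m/s at 50 Hz; it is *stationary* otherwise, and a
   displacement of exactly 2 cm stays stationary. The z component alone is
   used — the walk is along the sensor axis, and 3D displacement would mix
   in lateral sway. The same threshold is used for all subjects and both
   pathology presets; no per-subject tuning exists anywhere in the
   pipeline. Binary runs shorter than 100 ms (`min_run_ms`, 0 disables) are
   merged into their surroundings, shortest first, to a fixpoint: raw
   per-frame thresholding at 50 Hz is noise-fragile, and 100 ms is well
   below any physiological stance or swing phase. Every stationary run
   whose contact falls inside the GAP window becomes a step event: contact
   at the start of the run, liftoff at its end, contact position the ankle
   (x, z) averaged over the run. Events whose stationary run is clipped by
   the window (the first and last placements of a walk) are marked
   incomplete and excluded from parameter estimation.
5. **Parameters** (`gait_spatiotemporal()`, `com_sway()`). Definitions are
   spelled out in the help pages; notable conventions: step length is the
   depth-axis distance to the preceding contralateral contact; per-side
   mean velocity is the mean of per-step length/time ratios (not a COM
   speed, which would be side-less); stance percent divides the stationary
   run by the same-side stride; double support is the overlap of the two
   stationary interval sets per stride, in seconds, attributed to the side
   whose stride contains it; cadence counts complete steps of both sides.
   Medio-lateral sway is the peak-to-peak of the hip-midpoint x after
   removing linear drift (a path misaligned with the sensor axis would
   otherwise read as sway); vertical sway is the raw peak-to-peak of y.

### Event timing below the frame quantum

Two refinements sharpen event timing beyond the naive run boundaries, and
both matter at the tolerances the recovery tests demand:

* **Liftoff convention.** A stationary run's frames are `[start..end]`; the
  transition happens inside the interval `(end, end + 1)`. Using
  `time[end + 1]` as liftoff balances the half-frame latency of the contact
  boundary; using `time[end]` systematically shortens every stance by about
  two frames per cycle (~40 ms), which is most of a double-support
  tolerance at 50 Hz.
* **Half-maximum crossing.** The raw threshold-crossing time of a smoothed
  speed transition depends on swing speed: for a transition with rise time
  *R* it sits about *R*(1/2 − v~thr~/v~swing~) away from the true event, so
  a 3.5 m/s swing would read ~3 pp of stance differently from a 2 m/s
  swing. The sub-frame timing is therefore interpolated at the
  *half-maximum* of the local speed transition (the plateau estimated as
  the 90th percentile of the adjacent movement run), a classic edge locator
  that is insensitive to the plateau height. Which frames belong to which
  run is still decided by the 2 cm threshold alone.

Cadence is computed over whole strides: with an odd number of inter-contact
intervals, an asymmetric gait (unequal left/right step times) would bias
the mean interval by up to several steps/min, so the last contact is
dropped when necessary to keep equally many left- and right-ending steps.

For the medio-lateral sway, the drift line is fitted jointly with stride
frequency harmonics when a cycle estimate is available (it always is after
segmentation): a plain least-squares line fitted over a non-integer number
of sway cycles tilts into the sinusoid and can inflate the peak-to-peak by
more than the 1 cm reporting precision.

## The synthetic gait generator

`generate_gait()` exists so that every claim above is testable against
known truth. It emulates specifically the capture geometry of this
protocol: a subject starting beyond the GAP start line and walking toward
the sensor along the depth axis.

* Ankles alternate *plants* (exactly constant position in the noiseless
  limit) and *swings*. A swing transports the foot one stride length
  forward with a constant-speed core and half-cosine speed blends over 2%
  of the swing at each end, plus a half-sine vertical lift. A constant-core
  profile is used deliberately: the detection threshold is a speed
  threshold, so the commanded stance/swing boundary is only recoverable if
  the swing spends essentially all its time above threshold — with this
  profile, frame-to-frame displacement at 50 Hz clears 2 cm on well over
  90% of swing frames for every preset. A bell-shaped (minimum-jerk-style)
  profile cannot achieve that: its speed is zero at both ends, so a fixed
  fraction of every swing is undetectable by construction and the commanded
  stance percentages would not be recoverable by any threshold method.
* Commands with a swing core speed below 2 m/s are rejected as
  inadmissible: the reference detection speed is 1 m/s, and below a
  factor-2 margin the threshold crossings smear into the transition and no
  displacement-threshold segmentation can time them. Physiological swing
  transports the foot at 2-4 m/s even in slow gait, so the constraint
  excludes nothing real.
* Per-side step widths are commanded as lateral offsets of each landing
  relative to the preceding contralateral contact; unequal widths make the
  walking line drift laterally, as hemiparetic gait does, which is also why
  the ML sway estimator detrends.
* The hip midpoint advances at the implied mean speed, with sinusoidal ML
  sway (one cycle per stride) and vertical sway (two cycles per stride).
  The remaining 17 joints ride on the hip midpoint with fixed offsets —
  enough to exercise the COM estimators; nothing more is claimed for them.
* Degradation model: timestamps at nominal 30 FPS with uniform ±5 ms
  jitter, and additive white Gaussian position noise (default SD 2 mm, the
  depth accuracy of these sensors in the corridor's sweet spot) on every
  coordinate of every joint. Everything is seeded and reproducible.

What the generator does *not* emulate: body-tracking failure modes
(joint swaps, occlusion dropouts), skeleton proportion errors, foot
deformation at contact, turning or multi-pass walks. Passing recovery tests
therefore demonstrates the correctness of the signal chain under realistic
noise and jitter, not robustness to tracking pathology.

### Worked-example presets

`gait_preset("pd_table2")` and `gait_preset("ps_table2")` carry the
published per-side worked-example parameters of one parkinsonian and one
post-stroke trial: short, variable, fast steps with low ML sway (PD,
cadence 114.65 steps/min) versus longer, slower, strongly swaying gait
(PS, cadence 79.47 steps/min). Printed to two decimals, those eight numbers
are mutually inconsistent in two small ways, and the presets reconcile them
once, a priori:

* per-side step times are the length/velocity ratios rescaled by one common
  factor so the overall cadence is exact (the velocities then sit within
  0.02 m/s of their printed values);
* stance percentages and the double-support time are linked
  (`DS = stride × (stance_L + stance_R − 100)/100` in an alternating event
  model), and the printed triple misses that identity by ~0.04 s; a common
  offset added to both stance percentages (+0.61 pp for the PD preset,
  +0.40 pp for PS) splits the discrepancy by least squares weighted with
  the reporting tolerances (2 pp stance, 0.04 s double support).

`gait_preset("healthy")` is a symmetric normative adult gait (0.65 m steps
at cadence 110) intended as the normative anchor for radar normalization.
Note that on the 2.7 m corridor such long fast strides may not leave two
complete gait cycles per side inside the window — the corridor was sized
for pathological gait; analysis-oriented tests use the two patient presets.

## Statistics layer

The two-system comparison battery follows standard method-comparison
practice; each piece wraps the established base-R/CRAN routine behind the
package's interface and is cross-checked in the tests against independent
brute-force oracles (exhaustive sign enumeration for the signed-rank test,
explicit sums of squares for ICC and the mixed ANOVA).

* Normality screening uses the Kolmogorov-Smirnov statistic with
  **Lilliefors** critical values by default, because the normal parameters
  are estimated from the sample; the naive variant is a flag.
* The paired **Wilcoxon** test drops zero differences (the classical
  treatment) and uses the exact distribution for up to 25 untied nonzero
  differences, the continuity-corrected normal approximation beyond.
* **Spearman's rho** uses midranks for ties and a t-approximation p-value.
* The **ICC** defaults to ICC(2,1) — two-way random effects, absolute
  agreement, single measurement — which is the form that penalizes a
  constant offset between systems; ICC(3,1) and ICC(2,k) are available via
  `icc_form` since the appropriate form is a modeling choice.
* The **mixed repeated-measures ANOVA** has measurement System (2 levels)
  within subjects and patient Group (2 levels) between subjects, reporting
  F, p and partial eta squared per effect; with 2x2 levels the omnibus F is
  its own post hoc. Per-subject values are means over trials; averaging is
  done before testing, and no multiple-testing correction is applied across
  parameters (each parameter is reported at alpha = 0.05).

## Problem sizes and test design

The suite validates the central recovery property at 20 random admissible
commands x 5 seeds (patient-range parameters: step lengths 0.25-0.60 m,
step times 0.5-0.8 s, stance 58-80%, overall speed capped at 0.95 m/s so
the corridor always contains two cycles per side), with 2 mm noise and
±5 ms jitter, requiring step lengths and widths within 0.02 m, cadence
within 2 steps/min, stance within 2 pp, double support within 0.04 s and
sways within 0.01 m of their commanded values. Type-I calibration of the
statistical tests uses 2000 null replicates per test at n = 20 (12 subjects
for the ANOVA), accepting empirical rates in [0.03, 0.07] at alpha = 0.05.
Oracle equivalence of the segmentation core runs on 1000 random binary
arrays. A full synthetic trial is 9-10 s of simulated capture (~280 frames
at 30 FPS), so the entire suite completes in a few minutes on one CPU.

## Known limitations

* The COM body estimator is a declared trunk-centroid proxy, not a
  segmental-mass model; absolute COM positions are not claimed, only the
  crossing times of the GAP lines and relative sway.
* Step width from a frontal depth camera is intrinsically the least
  reliable of the eight parameters (feet close together approach the
  lateral tracking noise); the generator recovers it exactly, real sensors
  often do not.
* One straight pass toward the sensor is assumed: no turning detection, no
  back-and-forth, no treadmill.
* The stance/swing boundary inherits a small constant bias (~+1 pp of
  stance) from locating smoothed speed transitions; it is flat across
  swing speeds and well inside the 2 pp reporting tolerance, but it is
  there.
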