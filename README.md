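# rgbdgait

Markerless spatio-temporal gait analysis from a single RGB-D (depth)
camera, for people who cannot easily get to an instrumented gait
laboratory — typically parkinsonian and post-stroke cohorts monitored at
home or in outpatient settings.

A Kinect-v2-class sensor tracks a 25-joint skeleton at ~30 frames/s while
the subject walks toward it. `rgbdgait` turns those joint trajectories into
the eight standard gait parameters (per-side step length, step time, mean
velocity, stance %, double support; overall cadence, step width, and
medio-lateral / vertical center-of-mass sway), restricted to the *gait
analysis path* (GAP): the corridor between 4.2 m and 1.5 m from the sensor
where body tracking is accurate.

## The method

For each trial the pipeline is:

1. resample every joint channel onto a uniform 50 Hz grid with natural
   cubic splines (capture timestamps jitter around 30 FPS);
2. zero-phase 4th-order Butterworth low-pass at 10 Hz;
3. locate the GAP window: entry/exit are the frames where the 3D Euclidean
   distance of the body center of mass (trunk-joint centroid) from the
   sensor crosses 4.2 m and 1.5 m;
4. binarize each ankle's depth trajectory: a frame is *in movement* when
   the frame-to-frame |Δz| strictly exceeds 2 cm (an ankle speed of
   1 m/s), *stationary* otherwise — the stationary runs are the foot
   placements, giving contact/liftoff times and contact positions with
   sub-frame refinement;
5. drop placements clipped by the GAP boundaries and aggregate the step
   events into the eight parameters; hip-midpoint peak-to-peak excursions
   (x detrended, y raw) give the two sway measures.

The same 2 cm threshold is used for all subjects and both pathologies — no
per-subject tuning exists anywhere.

A seeded synthetic gait generator (`generate_gait()`, presets
`gait_preset("pd_table2" | "ps_table2" | "healthy")`) produces
ground-truth-annotated walks with commanded per-side step lengths/times,
stance percentages, step widths and sway amplitudes, degraded by timestamp
jitter and position noise, so the whole chain is verifiable without
hardware. A method-comparison layer (`agreement_table()`, `rm_anova()`,
`bland_altman()`, `icc_agreement()`, `wilcoxon_paired()`,
`spearman_rank()`) implements the usual two-system agreement battery.

## Worked example

Simulate the parkinsonian worked-example trial (short asymmetric steps,
high cadence, low sway) and analyze it:

```r
library(rgbdgait)
sim <- generate_gait(gait_preset("pd_table2", noise_sd = 0.002, jitter_ms = 5),
                     seed = 1)
analyze_gait(sim$sequence)
#> <gap_window> 4.20-1.50 m corridor: frames 140..372 (2.780-7.420 s)
#> <gait_parameters>
#>   left  n=4  step length 0.390 m  velocity 0.752 m/s  stance 77.7 %  double support 0.597 s  width 0.130 m
#>   right n=4  step length 0.290 m  velocity 0.550 m/s  stance 79.3 %  double support 0.597 s  width 0.190 m
#>   overall: cadence 114.75 steps/min  step width 0.155 m  ML sway 0.054 m  V sway 0.033 m
```

Reading: 8 complete steps fell inside the corridor; the left side steps
0.39 m per step, the right only 0.29 m (the commanded asymmetry, recovered
to the millimeter); cadence 114.75 steps/min against a commanded 114.65;
stance occupies ~78-79% of each gait cycle with 0.60 s of double support
per stride — a slow, shuffling pattern — and the hips sway 5.4 cm
laterally and 3.3 cm vertically over the pass.

`plot_gait_pattern()` draws the footfall map with the hip-midpoint trace
between the GAP lines, `radar_normalize()` + `plot_radar()` the normalized
0-1 gait profile (1 = normative best, 0 = cohort worst), and
`plot_bland_altman()` the agreement panels for a paired two-system table.
A thin CLI (`exec/rgbdgait`) exposes `analyze`, `simulate` and `compare`
subcommands.

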