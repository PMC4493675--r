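# hoofstride

Footfall event detection and stride segmentation for hoofed gait from the
3D trajectory of a **single marker on the proximal dorsal hoof wall**.

Studies of quadruped locomotion need the foot-on (touch-down) and foot-off
(lift-off) instants of each limb to cut continuous recordings into strides
and to derive stance time, swing time and duty factor. Force plates are the
gold standard — a vertical force above threshold means the foot is
weight-bearing — but they are often unavailable (circles, tracks, hydro-
therapy, field work). `hoofstride` is for researchers who capture hoof
kinematics optically and need validated, condition-independent event
detection: one marker, one algorithm family, walk and trot, straight line
and circle, fore and hind limbs.

## What it implements

**Four kinematic detectors**, operating per stride on windows anchored by a
pre-segmentation pass (downward crossings of the width-10 moving average of
the resultant speed through 2.5 m/s):

| Method | Event | Rule |
|---|---|---|
| A | foot on | first frame with raw resultant speed v_res = sqrt(v_x² + v_y² + v_z²) below a threshold (0.5 m/s; 1.0/1.2 m/s for fore/hind limbs inside the circle at trot) |
| B | foot off | last frame with horizontal marker travel below the stance marker height — beyond that, translation cannot be hoof rotation about the toe |
| C | foot on | argmax of zero-lag low-pass-filtered acceleration (vertical at 25 Hz trot / 20 Hz walk; resultant at 15 Hz for hind limbs on the circle at trot) |
| D | foot off | first negative local minimum of the 15 Hz-filtered vertical velocity after breakover start, refined on the raw signal (±3 frames) |

**Kinetic reference events** from vertical ground-reaction force: offset
correction against a 0.2 s unloaded window, plain decimation to 100 Hz, and
strict 75 N crossings, plus a 50–150 N threshold-sensitivity sweep.

**Method comparison**: per-stride differences (kinetic − kinematic, ms),
Bland–Altman limits of agreement (mean ± 2 SD), and hierarchical accuracy /
between-subject / within-subject precision.

**A seeded synthetic gait generator** producing marker trajectories and
time-aligned force traces with known truth events for all six conditions
(walk/trot × straight/circle-inside/circle-outside), used by the validation
suite.

A command-line interface (`inst/cli/hoofstride.R`) wraps the pipeline:
`simulate`, `segment`, `kinetic-events`, `sweep`, `compare`.

## Worked example

```r
library(hoofstride)

trial   <- make_trial("straight_walk", n_strides = 5, seed = 42)
profile <- condition_profile("walk", "straight", "fore")

kinematic <- segment_trial(trial$trajectory, profile,
                           method_on = "A", method_off = "B")
head(as.data.frame(kinematic), 4)
#>   stride     kind frame time method quality_flag
#> 1      1  foot_on    25 0.25      A           ok
#> 2      1 foot_off    97 0.97      B           ok
#> 3      2  foot_on   148 1.48      A           ok
#> 4      2 foot_off   227 2.27      B           ok

cfg     <- kinetic_config()                 # 75 N threshold, 100 Hz target
force   <- decimate_to(baseline_correct(trial$force, cfg), cfg)
kinetic <- detect_kinetic_events(force, cfg)

pairing <- pair_events(kinematic, kinetic)
limits_of_agreement(pairing$differences$diff_ms)
#> $low   -6.66    $high  12.66    $mean  3    $sd  4.83    $n  10
```

Frames are 0-based (`time = frame / rate`). The mean difference of +3 ms
says the kinetic events fall on average 3 ms after the kinematic ones —
under half a frame at 100 Hz — and the limits of agreement say 95% of
individual events in this trial agree within about ±10 ms (one frame).
Stride durations from successive foot-on events:

```r
dur <- stride_and_stance_durations(kinematic, kinetic)
#> stride 1178 +/- 46 ms, stance 762 +/- 44 ms
```

For cohort-level statistics, pool per-stride differences with a `horse_id`
column and call `horse_level_stats()`; `cohort_agreement(make_cohort(...))`
runs the whole layer on simulated cohorts with known injected bias.

## Package layout

- `R/sampled-series.R` — differentiation, resultant magnitude, moving
  average, zero-lag Butterworth filtering
- `R/trajectory.R`, `R/condition.R` — marker-trajectory container and
  condition-to-parameter resolution
- `R/event-detection.R` — pre-segmentation, methods A–D, trial orchestration
- `R/kinetics.R` — baseline correction, decimation, 75 N events, threshold
  sweep
- `R/comparison.R` — pairing, limits of agreement, accuracy/precision,
  introduced time shifts, durations
- `R/synthetic-gait.R` — condition presets, trajectory/force generators,
  cohort simulation
- `R/io.R`, `R/cli.R` — CSV/YAML ingest and emission, CLI subcommands
- `vignettes/footfall-detection-methods.Rmd` — models, assumptions,
  parameter choices and limitations
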