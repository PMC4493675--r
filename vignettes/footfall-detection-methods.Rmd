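---
title: "Footfall detection from a single hoof marker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Footfall detection from a single hoof marker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoofstride)
```

## The problem

Segmenting continuous motion-capture recordings of hoofed gait into strides
requires the foot-on (touch-down) and foot-off (lift-off) instants of each
limb. Force plates give these directly — a measurable vertical force means
the foot is weight-bearing — but they cover a small capture area and are
unavailable in many settings (circles, tracks, field work). `hoofstride`
detects both events from the 3D trajectory of a *single* marker on the
proximal dorsal hoof wall, a placement that is robust to occlusion and
marker loss, and validates the detections against force-plate reference
events on synthetic data with known ground truth.

All signals live in SI units (metres, seconds, newtons); files declaring
other units are converted on ingest. Frames are 0-based everywhere, with
`time = frame / rate`.

## The four kinematic detectors

Hard ground and a stiff hoof capsule justify treating the hoof as a rigid
body: impact is an abrupt collision, and terminal stance is a rotation of
the hoof about its toe (breakover). Four detectors exploit this, two
threshold-based (A, B) and two event-based (C, D). All operate per stride on
windows anchored by a pre-segmentation pass: the width-10 moving average of
the resultant marker speed
$v_\mathrm{res} = \sqrt{v_x^2 + v_y^2 + v_z^2}$
is scanned for downward crossings of 2.5 m/s, each crossing marking an
approaching contact.

**A — foot-on by velocity threshold.** The first frame, within 0.2 s of the
pre-segmentation point, at which the *raw* resultant speed falls strictly
below a condition-specific threshold: 0.5 m/s by default, raised to 1.0 m/s
(fore) and 1.2 m/s (hind) for the limbs on the inside of the circle at trot,
where altered impact mechanics otherwise bias the estimate. Raising the
threshold can only move the detection earlier (first-crossing monotonicity).

**B — foot-off by trigonometric distance threshold.** While the toe is on
the ground, horizontal marker translation is bounded by the hoof's rigid
geometry; treating the hoof as approximately square, translation beyond the
marker's own stance height cannot be rotation, so the foot must have lifted.
The detector extracts the marker position and height at foot-on, locates the
start of breakover as the end of the near-zero-speed stance plateau, and
returns the last frame within 0.15 s of breakover start at which the
horizontal Euclidean distance from the stance position is below the stance
marker height. Records that open mid-stance fall back to the end-of-stance
frame for the height reference.

**C — foot-on by acceleration peak.** Double forward-differencing of the
displacement followed by zero-lag low-pass filtering (25 Hz trot, 20 Hz
walk) turns the impact into a sharp peak; the detection is its argmax within
the foot-on window. For the hind limbs on the circle at trot the vertical
impact peak is unreliable, so the detector switches to the *resultant*
acceleration filtered at 15 Hz. The argmax is invariant to amplitude
scaling, which makes C less sensitive to differences in animal size.

**D — foot-off by vertical-velocity minimum.** At the end of breakover the
vertical velocity changes direction from downwards to upwards as the foot is
lifted into protraction. The vertical velocity is filtered at 15 Hz
(zero-lag); the preliminary event is the first local minimum with *negative*
(downward) value after breakover start, refined to the minimum of the raw
vertical velocity within ±3 frames. The sign requirement is part of the
event definition — a direction change requires downward motion — and in
practice rejects shallow noise dips that occur while the marker is still
rising during breakover.

## Kinetic reference events

The gold standard is the vertical ground-reaction force: foot on is the
first frame strictly above 75 N, foot off the first subsequent frame
strictly below (a frame exactly at the threshold belongs to neither
crossing). Before detection the trace is offset-corrected by subtracting the
mean over a 0.2 s unloaded window (trial start, or trial end when the start
is loaded — "loaded" meaning a mean |fz| above 25 N, below the smallest
threshold of the sensitivity sweep) and decimated to 100 Hz by retaining
every 10th sample, deliberately without anti-alias filtering so retained
samples equal raw recorded values (a filtered variant is available but off
by default). Contacts separated by less than 0.1 s of sub-threshold force
are merged to guard against threshold chatter; this merge rule is this
package's own safeguard for multi-contact records.

`threshold_sweep()` quantifies how the threshold choice moves the events:
between 50 and 150 N, foot-on can only get later and foot-off earlier, and
hind-limb-like force traces with a gradual late-stance "tailing-off" are
substantially more sensitive on the foot-off side than fore-limb-like traces
with steep unloading.

## Method comparison statistics

Differences are always *kinetic minus kinematic*, in milliseconds, computed
over events greedily paired within 100 ms (under half the shortest expected
stance, so events cannot jump strides; unpaired events are reported and
excluded). Three descriptive layers follow:

* **Limits of agreement**: mean ± 2 SD of the pooled per-stride differences,
  the interval expected to contain about 95% of individual differences.
  Its width is exactly 4 pooled sample SDs.
* **Accuracy and precision**: per horse, the mean and SD of its differences
  are computed first; accuracy is the mean of horse means, between-horse
  precision the SD across horse means, within-horse precision the average
  horse SD. Sample (n−1) SDs are used throughout, and unequal per-horse
  stride counts are retained.
* **Introduced time shift**: foot-on accuracy minus foot-off accuracy, also
  as a percentage of stride duration — the bias a pipeline injects into
  derived stance/swing splits even when each event is individually accurate.

Inferential testing (normality tests, repeated-measures ANOVA, post-hocs) is
deliberately out of scope; the module stops at descriptive agreement.

## The synthetic gait generator

`make_trial()` produces marker trajectories and time-aligned force traces
with known truth events, emulating exactly the movement structure the
detectors assume — and nothing more:

* **Stance**: the marker is fixed at its contact position, `hoof_height`
  (default 0.05 m) above the ground.
* **Breakover** (default 20% of stance, a fore-limb trotting figure applied
  to both limbs and configurable): rigid rotation about a toe pivot
  0.6 hoof-heights ahead of the marker, with angle accelerating as $s^2$
  from the stance angle ($\arctan(1/0.6) \approx 59^\circ$) to
  $\approx 110^\circ$. The final angle is chosen so the horizontal marker
  translation equals the stance marker height exactly at toe-off (method B's
  premise); because it lies past the marker zenith the vertical velocity
  dips into a negative trough at toe-off (method D's premise).
* **Swing**: quintic (minimum-jerk style) interpolation per axis from the
  breakover exit state to the next contact, plus a $\sin^2$ vertical arch
  for ground clearance (0.06 m walk, 0.12 m trot). The swing ends with a
  downward impact velocity (0.8 m/s walk, 1.6 m/s trot) that the first
  stance frame annihilates, producing the one-frame velocity collapse and
  the acceleration spike that methods A and C key on.
* **Force**: 1,000 Hz vertical force per contact with a steep onset
  beginning 5 ms before the contact frame (so the 75 N crossing lands on the
  contact frame after decimation, with the first supra-threshold frame
  around 400–500 N), a double-hump plateau scaled to body weight (448 kg
  horse; 0.6 body weights at walk, 1.1 at trot), and a configurable offload:
  `"steep"` (fore-like, 30 ms linear) or `"gradual"` (hind-like, 80 ms
  quadratic tail). Marker noise defaults to 0.8 mm Gaussian per axis, the
  calibrated linear accuracy of the optical capture volume; force noise
  defaults to 2 N.

Stride and stance durations (means and SDs) for the six conditions — walk
and trot, straight and on the circle with inside/outside limbs — are drawn
per stride from the observed distributions (e.g. straight walk: stride
1153 ± 55 ms, fore stance 734 ± 41 ms). Records open and close in the fast
mid-swing region so pre-segmentation sees a clean crossing at both ends;
the force record may extend slightly past the marker record to guarantee an
unloaded end-baseline window. All randomness flows from one integer seed;
identical seeds give bit-identical trials.

**What the generator does not emulate**: soft or deforming ground, hoof
slip, partial-contact landing phases, circle-specific lean-angle kinematics,
canter or gallop, and the altered inside-limb impact mechanics that
motivated the raised method-A thresholds (the generator reproduces the
threshold bookkeeping, not the bias itself). Passing recovery tests
therefore demonstrate algorithmic correctness under the rigid-body movement
model, not field performance on such data.

## Numerical choices

* **Differentiation** is a forward difference scaled by the rate; the value
  from samples $k, k+1$ is assigned frame $k$. Applying it twice shifts a
  smooth second-derivative extremum exactly one frame early. This shift is
  asserted, not corrected: the zero-lag low-pass applied afterwards nudges
  peaks the opposite way, and correcting both would double-count.
* **Moving average**: centred window shrinking symmetrically at the edges;
  even widths are reduced to the next lower odd width (Matlab `smooth`
  semantics, matching the width-10 smoothing convention this field uses),
  so output length equals input length and constants map to themselves.
* **Zero-lag filtering**: "4th-order zero-lag Butterworth" is read as a
  2nd-order design applied forward then backward (effective 4th-order
  magnitude response), the common biomechanics convention;
  `design_is_effective = FALSE` selects the other reading. Edges use
  point-reflected padding of three design-order cut-off periods plus
  steady-state initialisation from the border value, long enough that
  constants pass exactly and filtering commutes with time reversal to
  ~1e-12.
* **Strict inequalities** implement every threshold crossing ("fell below",
  "exceeded"): a sample exactly at a threshold belongs to neither side, and
  ties resolve to the next frame.
* **Stance plateau end** (breakover start): last frame of smoothed speed
  below `plateau_v` followed by at least 3 frames above it. The ceiling is
  0.35 m/s: the smoothed *magnitude* of the velocity noise does not average
  to zero, leaving a stance noise floor of ≈0.18 m/s at 0.8 mm marker noise
  and 100 Hz (χ₃ mean of three 0.113 m/s components), and the ceiling sits
  about six smoothed-floor SDs above that floor while staying below the
  0.5 m/s foot-on threshold. A ceiling at or below the noise floor ends the
  plateau tens of frames early on most noisy strides.
* **Windows** are specified in seconds (0.2 s foot-on search, 0.15 s
  lift-off search) and converted to frames by rounding, so the canonical
  20- and 15-frame windows arise at 100 Hz and other rates remain usable.
* **Degenerate inputs** produce flagged events (`window_exhausted`,
  `no_local_minimum`, `detection_failed`) rather than exceptions, so batch
  processing keeps per-stride bookkeeping; downstream statistics exclude
  flagged events explicitly, never silently.

## Problem sizes used in the validation suite

The test-suite and acceptance-script runs use deliberately compact
configurations: 3-stride zero-noise and 8-stride noisy trials per preset and
limb for detector recovery, 250 random fixtures per scanning detector for
oracle equivalence, cohorts of 8 horses × 20 strides for bias/precision
recovery (the scale of a typical validation study), 40 contacts for the
force-threshold sweep, and 10⁵ draws for the limits-of-agreement coverage
check. These sizes give stable estimates for every reported quantity;
enlarging them changes nothing but runtime.

## Worked example

```{r example, eval = FALSE}
trial <- make_trial("straight_walk", n_strides = 5, seed = 42)
profile <- condition_profile("walk", "straight", "fore")

kinematic <- segment_trial(trial$trajectory, profile,
                           method_on = "A", method_off = "B")

cfg <- kinetic_config()
force <- decimate_to(baseline_correct(trial$force, cfg), cfg)
kinetic <- detect_kinetic_events(force, cfg)

pairing <- pair_events(kinematic, kinetic)
limits_of_agreement(pairing$differences$diff_ms)
```

## Known limitations

* Validation is synthetic-only by necessity; the original recordings behind
  the published agreement tables are not deposited, so those numbers are not
  reproducible here and the package verifies properties (recovery, sign
  patterns, parameter recovery) instead.
* Method B inherits the square-hoof approximation; animals with acute hoof
  angles would need the allowable-distance rule re-calibrated.
* Method A's thresholds were tuned for hard ground; soft ground damps the
  velocity drop and calls for a pilot re-calibration.
* The C3D container is not parsed; force data enter as tabular text, with
  per-channel offset/scale calibration applied on ingest for raw analog
  exports.
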