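---
title: "Zero-velocity-aided gait analysis: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-velocity-aided gait analysis: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugait)
```

## Scope

`imugait` estimates spatio-temporal gait parameters (stride length and
time, stance/swing time, clearance, speed, cadence) from a single
foot-mounted 6-axis IMU, and evaluates those estimates against a
reference stride table.  Because public raw recordings for this class of
study are rare, the package treats the *synthetic* walking session as a
first-class citizen: the generator produces ground truth exact enough
that the whole pipeline can be validated to the millimetre, and its
artifact models reproduce the failure modes that dominate real
device-comparison studies (range saturation, packet loss, left/right
miscalibration).

## The estimator

### Strapdown integration

The global frame is z-up; gravity is `g = (0, 0, -9.80665)` m/s².  The
attitude `R_t` (body to global) advances by the closed-form rotation
increment `R_{t-1} (I + sin(s)/s B + (1-cos(s))/s² B²)` with
`s = |w_t dt|` and `B = skew(w_t dt)`, which equals the exponential map
of the rotation vector `w_t dt`.  For `s < 1e-8` the trigonometric
coefficients are replaced by their series (`1 - s²/6`, `1/2 - s²/24`) to
avoid cancellation.  Velocity and position use the explicit Euler scheme
`v_t = v_{t-1} + dt (R_t f_t + g)`, `s_t = s_{t-1} + dt v_t` — the
scheme is kept exactly in this printed form (no trapezoidal upgrade), and
the synthetic generator inverts exactly this discretization, so
forward-integrating generated signals reproduces the generating
trajectory to machine precision rather than to discretization error.

### Error-state Kalman filter and its sign convention

The 9-state error vector is ordered (attitude, velocity, position).  The
transition matrix has the velocity-error block `+dt S` with
`S = skew(R_t f_t)`.  That sign pins down the attitude-error convention:
writing the innovation analysis out, `+dt S` is consistent with
`R_true = (I - skew(dθ)) R_est`, so the multiplicative correction applied
on a zero-velocity update must be `R <- (I - skew(dθ)) R` followed by
re-orthonormalization.  With the opposite sign each correction becomes
positive feedback on the tilt error: the filter still zeroes the
velocity at every stance, but gravity leaks into the horizontal axes and
stride lengths degrade by two orders of magnitude.  This is easy to get
wrong silently, which is why the test suite checks end-to-end recovery
and not just the algebra of a single update.

Covariance updates enforce symmetry by averaging with the transpose;
attitude matrices are renormalized each step with one Newton polar step
(`R (3I - R'R)/2`) and with a full SVD projection after each
multiplicative correction.  The minimum eigenvalue of `P` can be tracked
per step (`check_psd`), which the acceptance run turns on.

### Stance detection

The detector is a windowed double threshold: a sample is stationary when
over a centred `window` both the peak gyroscope magnitude stays below
`gyro_threshold` and the peak deviation of the accelerometer magnitude
from 1 g stays below `accel_threshold`; stationary runs shorter than
`min_duration` are discarded.  The technique the pipeline is built on
names the zero-velocity principle but not a specific detector, so this
minimal magnitude detector was chosen and every threshold left
configurable.

### Gait events

Temporal parameters come from the raw gyroscope, not the integrated
trajectory.  The sagittal channel is selected as the gyro axis of
maximal variance (mounting orientations vary across devices), and its
sign is disambiguated by comparing rectified peak heights in both
polarities, so a global sign flip of the channel yields the same events.
Midswing = peaks above `prominence` separated by `min_stride_time`;
initial contact (IC) = the signal minimum in the window after a midswing
peak; foot off (FO) = the minimum in the window before it.  Which
flanking minimum corresponds to which event is a documented choice, not
a claim about the original study's (unpublished) rule; both the window
and the light pre-smoothing (`smooth_window`) are configurable.

## Tunable parameters

| key | default | unit | why |
|---|---|---|---|
| `zupt.window` | 0.1 | s | about 10 samples at 100 Hz; shorter windows chatter |
| `zupt.gyro_threshold` | 0.6 | rad/s | an order below the midswing peak (~6 rad/s) |
| `zupt.accel_threshold` | 0.8 | m/s² | passes sensor noise, rejects swing dynamics |
| `zupt.min_duration` | 0.05 | s | rejects spurious single-window stances |
| `eskf.accel_noise_sd` | 0.02 | m/s² | consumer-MEMS white-noise level |
| `eskf.gyro_noise_sd` | 0.0035 (0.2 deg/s) | rad/s | consumer-MEMS white-noise level |
| `eskf.zupt_noise_sd` | 0.01 | m/s | residual stance micro-motion |
| `eskf.max_gap` | 3.5 nominal dt | s | two lost samples tolerated, three abort |
| `events.prominence` | 1.5 | rad/s | well below midswing peaks, above stance noise |
| `events.min_stride_time` | 0.4 | s | below any plausible stride time |
| `turns.heading_threshold` | 20 | deg | straight-walk yaw wander stays far below |
| `match.tol` | 0.25 | s | under half the minimum plausible stride time |

Process noise is diagonal per axis, `(gyro_sd² dt², accel_sd² dt², 0)`
for the attitude/velocity/position blocks; the zero block reflects that
position error is driven only through velocity error in this model.

## The synthetic world

One session is: a stationary lead-in (default 2 s, doubling as the
filter's initialization rest and the synchronization standstill), a
lead-in step, `n` strides (each an exactly stationary stance followed by
a swing), and a stationary tail.  Per-stride length and time are drawn
from normal distributions truncated at ±3 sd and at zero.  Swing
kinematics are minimum-jerk in the direction of travel plus a C²
clearance bump (peak = `clearance`); minimum-jerk is smooth, standard for
point-to-point movement, and has analytically known peak acceleration
`5.77 L/T²`, which is what lets the ±4 g clipping experiment target long
strides deliberately.  The foot pitches about the sagittal axis with a
profile whose rate shows the classic pattern: a dominant positive
midswing lobe flanked by negative dips whose minima fall exactly at foot
off and initial contact, with lobe areas balanced so the net rotation per
swing is zero.  The lead-in step exists so that *every* truth initial
contact is a real touchdown with a gyro signature; without it the first
truth stride would be undetectable in principle and measured/reference
series would desynchronize by one stride.

Artifacts are applied in physical order: per-axis scale error, bias,
white noise, range clipping (saturation acts on the analog sum), i.i.d.
packet loss, timestamp jitter.  A zero-magnitude specification is the
identity.  All randomness flows from explicit seeds.

The per-axis accelerometer scale factor deserves a note: it is the
mechanism used to emulate a miscalibrated unit in a left/right device
pair.  A pure additive bias cannot shift stride lengths much, because
constant biases are largely absorbed by the zero-velocity corrections;
a scale error on the travel axis, by contrast, scales the double
integral of swing acceleration and therefore the stride length almost
proportionally (8% on a 1.2 m stride gives close to +0.1 m), while
leaving the stance signature — and hence stance detection — untouched.

What the generator does **not** emulate: soft-tissue and mounting
vibration, temperature-dependent bias drift, non-white noise (no Allan
variance model), quasi-stationary stances (real feet roll slightly),
magnetometer or barometer channels, bursty packet loss, and left/right
asymmetric gait.  A green test therefore establishes that the estimator
is *correct* and robust to the modelled artifact classes at realistic
magnitudes — not that any particular commercial device will achieve the
same numbers.

## Numerical choices

- Gravity fixed at 9.80665 m/s²; 1 g and deg/s conversions are exact
  definitional constants.
- The SO(3) logarithm uses three branches: first-order for angles below
  1e-10; the standard `asin`-free formula in the middle; and near π
  (within 1e-2) an axis from the symmetrized matrix refined by two power
  iterations, with the angle from the antisymmetric part via `asin`.
  Round-tripping `exp(log(R))` stays below ~1e-10 everywhere including at
  exactly π.
- Stride-time statistics are snapped to sample times; the stance/swing
  split is accurate to one sample by construction.
- Clearance is measured above each stride's own stance ground height
  (median height over stance), making it immune to slow vertical drift.
- Clipping detection uses 0.999 of full scale, since quantization can
  leave saturated values one LSB inside the rail.
- Turn flagging uses `>=` against the heading threshold so that a zero
  threshold degenerates to "flag everything", which is the more useful
  degenerate behaviour for sensitivity analyses.
- Duplicate timestamps are collapsed to the first occurrence on file
  read (streamed packets stamped on arrival are not distinct samples),
  but recordings constructed in memory may carry ties so that the QC
  layer can count them.
- RMSE in the agreement report is measured about the identity line, not
  the regression line: it quantifies disagreement with the gold
  standard, which is why a slope well away from 1 can coexist with a
  small RMSE.
- Limits of agreement use the n−1 standard-deviation denominator;
  regression is measured-on-reference (an under-reading device then
  shows slope < 1, the intuitive direction).
- Stride matching is greedy nearest-neighbour on initial-contact times
  within 0.25 s, one-to-one, same foot only.
- K-means on stride differences runs with a fixed seed and 10 restarts;
  with k equal to the number of points each point becomes its own
  cluster without invoking the solver.  The mean silhouette coefficient
  is computed directly (1-D, Euclidean) and cross-checked against an
  independent implementation in the tests.

## Failure behaviour

Recordings with inter-sample gaps longer than `eskf.max_gap` abort with
an error listing the gap intervals — integrating across missing data
silently would corrupt stride estimates in exactly the way a
retained-fraction of 0.8 corrupts real sessions.  Optional bridging
(`eskf.bridge_gaps`) linearly interpolates gaps of at most 3 samples and
never more.  A missing initial standstill, all-identical differences in
the cluster screen, and zero reference variance in the regression are
all hard errors rather than silent degradations.

## Known limitations

- Yaw is unobservable to a ZUPT-only filter; heading drifts slowly with
  gyro bias.  Stride *length* (a norm) is insensitive to this, but the
  full trajectory is not, and turn flagging relies only on relative yaw
  across a single stride.
- Sensor biases are not part of the filter state; they are partially
  absorbed by the corrections instead of being estimated.
- The explicit Euler scheme is first-order; fidelity to the published
  recursion was preferred over integration accuracy, and the generator's
  discrete inverse makes the pair exactly consistent anyway.
- Left/right feet are analyzed independently; step-level parameters that
  need both feet (double support) are out of scope.
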