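# imugait

Estimation and validation of spatio-temporal gait parameters from
foot-mounted inertial measurement units (IMUs).

## The problem

A single 6-axis IMU (3-axis accelerometer + 3-axis gyroscope) strapped to
the shoe can, in principle, measure where the foot went: integrating the
angular rate gives the attitude, rotating the specific force into the
global frame and subtracting gravity gives the acceleration, and double
integration gives the foot's displacement.  In practice sensor noise and
bias make naive double integration diverge within seconds.  The standard
remedy exploits gait itself: during stance the foot is flat on the floor
and its true velocity is zero, so every detected stance provides a
pseudo-measurement ("zero-velocity update", ZUPT) that resets the drift.

`imugait` implements this pipeline end to end, together with the tooling
needed to *validate* it: a synthetic-gait generator with exact ground
truth, vendor-style artifact injection (noise, bias, scale error, range
clipping, packet loss, timestamp jitter), raw-signal quality control, and
agreement statistics against a reference stride table (regression,
Bland-Altman limits of agreement, and a k-means/silhouette screen that
flags a miscalibrated left/right device pair).  It is aimed at movement
scientists and engineers who need to qualify consumer or research IMUs
for gait analysis before trusting their stride estimates.

## The model

State of the foot at time *t*: attitude matrix `R_t`, velocity `v_t`,
displacement `s_t`.  With specific force `f_t`, angular rate `w_t`, and
sampling interval `dt`, the strapdown recursion is

    R_t = R_{t-1} (I + sin(s)/s B + (1 - cos(s))/s^2 B^2),   s = |w_t dt|, B = skew(w_t dt)
    a_t = R_t f_t + g
    v_t = v_{t-1} + dt a_t
    s_t = s_{t-1} + dt v_t

An error-state Kalman filter tracks the 9-dimensional error (attitude,
velocity, position).  Prediction propagates the error covariance with the
block transition matrix

    F = [ I      0     0 ]
        [ dt S   I     0 ]          S = skew(R_t f_t)
        [ 0      dt I  I ]

and during detected stance the zero-velocity pseudo-measurement
(`H = [0 I 0]`) is applied:

    K = P H' (H P H' + Sigma_v)^{-1},  dx = -K v,  P <- (I - K H) P

with `dx` folded back additively into `v` and `s` and multiplicatively
(small-angle rotation) into `R`.  Gait events (initial contact, foot off,
midswing) are detected by peak picking on the raw sagittal angular
velocity; strides span consecutive initial contacts, and stride length is
the horizontal displacement between them.

## Worked example

Simulate a 40-stride walk with realistic sensor artifacts, analyze it,
and evaluate against the generator's ground truth:

```r
library(imugait)
sim <- simulate_session("out/sim", gait_spec(n_strides = 40, seed = 7),
                        artifact_spec(seed = 8))
res <- run_pipeline(sim$rec_path, sim$ref_path, out_dir = "out/ana")
st  <- res$strides
cadence(st)
res$evaluation$stride_length
```

Output (as printed by the code):

    [eskf] 2514 corrections over 4769 samples
    [gait] 40 strides (40 after turn exclusion)
    strides: 40, mean length 1.214 m, mean time 1.106 s, cadence 108.5 steps/min
    stride length vs truth: n = 40, r = 0.9998, slope = 0.996, intercept = 0.004 m
    rmse = 0.0011 m, bias = -0.0000 m, LoA half-width = 0.0021 m

Reading: all 40 strides were matched to the truth table; stride length
agrees with ground truth to about a millimetre (r near 1, slope near 1,
negligible bias), i.e. the filter fully recovers the simulated walk at
the default noise level.  `out/ana/` contains `states.csv` (per-sample
navigation states), `strides.csv`, `qc.json` and `eval.json`.

A command-line interface wraps the same stages:

    Rscript -e 'imugait::imugait_cli()' simulate --out out/sim --seed 7
    Rscript -e 'imugait::imugait_cli()' run --in out/sim/rec.csv \
        --reference out/sim/ref.csv --out out/ana
    Rscript -e 'imugait::imugait_cli()' print-config

## Vignette

`vignettes/methods.Rmd` documents the model and its assumptions, every
tunable parameter with units and defaults, what the synthetic data do and
do not emulate, and the numerical choices made where the literature is
silent.
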