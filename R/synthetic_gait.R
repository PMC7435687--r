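# Seed hygiene: every stochastic generator routes through this helper so the
# caller's RNG stream is left untouched and identical seeds give identical
# output.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Specification of a synthetic walking bout
#'
#' Describes the ground-truth gait to synthesize: a stationary lead-in, a
#' sequence of strides (each an exactly stationary stance followed by a
#' smooth swing), and a stationary tail.  Per-stride length and time are
#' drawn from truncated normal distributions (truncated at +/-3 sd and at
#' zero).  Defaults emulate normal adult walking recorded at 100 Hz.
#'
#' @param n_strides number of strides.
#' @param stride_length_mean,stride_length_sd stride length distribution, m.
#' @param stride_time_mean,stride_time_sd stride time distribution, s.
#' @param clearance peak foot elevation during swing, m.
#' @param stance_fraction fraction of the gait cycle spent in stance, (0,1).
#' @param turn_every strides between 180-degree turns (0 = straight walk).
#' @param fs sampling rate, Hz.
#' @param rest_before,rest_after stationary periods bracketing the walk, s.
#'   The lead-in doubles as the still-standing phase used to initialize the
#'   navigation filter and to synchronize with a reference system.
#' @param pitch_amplitude peak sagittal foot-pitch excursion, rad.
#' @param foot `"left"` or `"right"` label carried into the truth strides.
#' @param seed integer RNG seed.
#' @return list of class `gait_spec`.
#' @export
gait_spec <- function(n_strides = 20,
                      stride_length_mean = 1.2, stride_length_sd = 0.05,
                      stride_time_mean = 1.1, stride_time_sd = 0.05,
                      clearance = 0.05, stance_fraction = 0.6,
                      turn_every = 0, fs = 100,
                      rest_before = 2, rest_after = 1,
                      pitch_amplitude = 0.25,
                      foot = "right", seed = 1) {
  if (stride_length_mean <= 0 || stride_time_mean <= 0)
    stop("stride length and time means must be positive")
  if (stride_length_sd < 0 || stride_time_sd < 0)
    stop("standard deviations must be nonnegative")
  if (stance_fraction <= 0 || stance_fraction >= 1)
    stop("stance_fraction must lie in (0, 1)")
  structure(as.list(environment()), class = "gait_spec")
}

# one-sided truncated normal: reject draws outside mean +/- 3 sd or <= 0
rtruncnorm3 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  lo <- max(mean - 3 * sd, .Machine$double.eps)
  hi <- mean + 3 * sd
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# minimum-jerk position profile on [0,1]: 0 -> 1 with zero velocity and
# acceleration at both ends
min_jerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

# C2 clearance bump on [0,1], peak 1 at tau = 0.5
clearance_bump <- function(tau) 64 * tau^3 * (1 - tau)^3

# Sagittal foot-pitch angle profile over swing, normalized time tau in [0,1].
# Its derivative (the gyro signature) has a dominant positive lobe centred at
# midswing flanked by negative lobes whose minima sit at the swing
# boundaries, i.e. at foot off and initial contact -- the standard pattern
# peak-detection event finders rely on.  P is the positive-lobe amplitude in
# rad per unit tau; the negative-lobe amplitude 2P/3 makes the net rotation
# over the swing zero so the foot lands flat.
#
# d(theta)/d(tau) = P cos^2(pi (tau - 1/2) / 0.4)   on |tau - 1/2| < 0.2
#                 - (2P/3) cos^2(pi tau / 0.6)      on tau < 0.3
#                 - (2P/3) cos^2(pi (tau - 1)/0.6)  on tau > 0.7
pitch_profile <- function(tau, P) {
  D <- 2 * P / 3
  # antiderivative of cos^2(pi (x - c) / w): (x-c)/2 + w/(4 pi) sin(2 pi (x-c)/w)
  A <- function(x, c, w) (x - c) / 2 + w / (4 * pi) * sin(2 * pi * (x - c) / w)
  seg <- function(x, c, w, lo, hi) {
    x <- pmin(pmax(x, lo), hi)
    A(x, c, w) - A(lo, c, w)
  }
  P * seg(tau, 0.5, 0.4, 0.3, 0.7) -
    D * seg(tau, 0, 0.6, 0, 0.3) -
    D * seg(tau, 1, 0.6, 0.7, 1)
}

#' Synthesize a ground-truth walking trajectory
#'
#' Builds the foot trajectory implied by a [gait_spec()]: position is
#' constant during each stance (the zero-velocity premise holds exactly),
#' and each swing advances the foot along the current heading with a
#' minimum-jerk horizontal profile plus a C2 vertical clearance arc.  The
#' foot pitches about the sagittal axis during swing so that the angular
#' rate shows the usual midswing peak and touchdown/lift-off dips.  When
#' `turn_every > 0` the heading rotates 180 degrees smoothly across the
#' designated stances.
#'
#' @param spec a [gait_spec()].
#' @return An object of class `foot_trajectory`: `t` (s), `position`
#'   (n x 3, m), `velocity` (n x 3, m/s, backward difference), `attitude`
#'   (3 x 3 x n rotation matrices), `truth_strides` (data.frame with
#'   `foot`, `ic_time`, `stride_length`, `stride_time`, `is_turn`), and
#'   `fs`.
#' @export
synth_walk_trajectory <- function(spec) {
  stopifnot(inherits(spec, "gait_spec"))
  n <- spec$n_strides
  draws <- with_local_seed(spec$seed, list(
    L = rtruncnorm3(n, spec$stride_length_mean, spec$stride_length_sd),
    Tm = rtruncnorm3(n, spec$stride_time_mean, spec$stride_time_sd)))
  L <- draws$L
  Tm <- draws$Tm
  st_frac <- spec$stance_fraction
  P <- spec$pitch_amplitude / 0.1  # max |theta| of pitch_profile is 0.1 P

  # a lead-in step precedes stride 1 so that every truth initial contact is
  # a real touchdown (an IC without a preceding swing has no gyro signature
  # and could never be detected, which would desynchronize matching)
  lead_swing <- (1 - st_frac) * spec$stride_time_mean
  lead_len <- spec$stride_length_mean
  ic <- spec$rest_before + lead_swing + cumsum(c(0, Tm[-n]))
  turn_here <- rep(FALSE, n)  # turn executed during the stance of stride i
  if (spec$turn_every > 0 && n > spec$turn_every)
    turn_here[seq(spec$turn_every + 1, n, by = spec$turn_every)] <- TRUE
  heading <- pi * (cumsum(turn_here) %% 2)  # heading while swinging stride i

  total <- spec$rest_before + lead_swing + sum(Tm) + spec$rest_after
  dt <- 1 / spec$fs
  N <- floor(total / dt + 1e-9) + 1
  t <- (seq_len(N) - 1) * dt

  pos <- matrix(0, N, 3)
  att <- array(0, c(3, 3, N))
  yaw <- numeric(N)
  pitch <- numeric(N)

  # lead-in step: swing from the origin onto the first stance
  base <- c(0, 0)
  k <- which(t >= spec$rest_before - 1e-9 & t < ic[1] - 1e-9)
  tau <- (t[k] - spec$rest_before) / lead_swing
  pos[k, 1] <- lead_len * min_jerk(tau)
  pos[k, 3] <- spec$clearance * clearance_bump(tau)
  pitch[k] <- pitch_profile(tau, P)
  base <- base + c(lead_len, 0)

  # then walk stride by stride, filling the samples inside each segment
  prev_heading <- 0
  for (i in seq_len(n)) {
    t0 <- ic[i]
    t_fo <- t0 + st_frac * Tm[i]
    t1 <- t0 + Tm[i]
    dir2 <- c(cos(heading[i]), sin(heading[i]))
    # stance: position fixed; heading may rotate (turn) with min-jerk yaw
    k <- which(t >= t0 - 1e-9 & t < t_fo - 1e-9)
    pos[k, 1] <- base[1]; pos[k, 2] <- base[2]
    if (turn_here[i]) {
      tau <- (t[k] - t0) / (t_fo - t0)
      yaw[k] <- prev_heading + (heading[i] - prev_heading) * min_jerk(tau)
    } else {
      yaw[k] <- heading[i]
    }
    # swing: advance along heading
    k <- which(t >= t_fo - 1e-9 & t < t1 - 1e-9)
    tau <- (t[k] - t_fo) / (t1 - t_fo)
    pos[k, 1] <- base[1] + dir2[1] * L[i] * min_jerk(tau)
    pos[k, 2] <- base[2] + dir2[2] * L[i] * min_jerk(tau)
    pos[k, 3] <- spec$clearance * clearance_bump(tau)
    yaw[k] <- heading[i]
    pitch[k] <- pitch_profile(tau, P)
    base <- base + dir2 * L[i]
    prev_heading <- heading[i]
  }
  # lead-in rest keeps the initial pose; tail rest keeps the final pose
  k <- which(t < ic[1] - 1e-9)
  yaw[k] <- heading[1]
  k <- which(t >= ic[n] + Tm[n] - 1e-9)
  pos[k, 1] <- base[1]; pos[k, 2] <- base[2]
  yaw[k] <- heading[n]

  for (j in seq_len(N)) att[, , j] <- rot_z(yaw[j]) %*% rot_y(pitch[j])

  vel <- rbind(0, diff(pos) / dt)
  truth <- data.frame(
    foot = spec$foot, ic_time = ic, stride_length = L, stride_time = Tm,
    is_turn = turn_here, stringsAsFactors = FALSE)
  structure(list(t = t, position = pos, velocity = vel, attitude = att,
                 truth_strides = truth, fs = spec$fs),
            class = "foot_trajectory")
}

#' @export
print.foot_trajectory <- function(x, ...) {
  cat(sprintf("<foot_trajectory> %d samples at %g Hz, %d strides\n",
              length(x$t), x$fs, nrow(x$truth_strides)))
  invisible(x)
}

#' Convert a trajectory to the ideal IMU signals that would produce it
#'
#' Inverse strapdown: the specific force is `f_t = R_t' (a_t - g)` where
#' `a_t` is the (gravity-excluded) acceleration of the foot and `g` is the
#' gravity vector, and the body angular rate is recovered from consecutive
#' attitudes via the SO(3) logarithm of `R_{t-1}' R_t` divided by the
#' sampling interval.  Discrete backward differences are used for `a_t` so
#' that explicit-Euler forward integration of the emitted signals
#' reproduces the input trajectory to machine precision.
#'
#' @param traj a `foot_trajectory` sampled at a uniform rate.
#' @param accel_range,gyro_range metadata for the emitted recording.
#' @return an [imu_recording()].
#' @export
trajectory_to_imu <- function(traj, accel_range = 8, gyro_range = 2000) {
  stopifnot(inherits(traj, "foot_trajectory"))
  dts <- diff(traj$t)
  if (length(dts) && diff(range(dts)) > 1e-9)
    stop("trajectory must be uniformly sampled")
  dt <- dts[1]
  N <- length(traj$t)
  acc <- rbind(0, diff(traj$velocity) / dt)
  g <- gravity_vec()
  f <- matrix(0, N, 3)
  w <- matrix(0, N, 3)
  for (j in seq_len(N)) {
    f[j, ] <- crossprod(traj$attitude[, , j], acc[j, ] - g)
    if (j > 1) {
      dR <- crossprod(traj$attitude[, , j - 1], traj$attitude[, , j])
      w[j, ] <- matrix_to_rotvec(dR) / dt
    }
  }
  imu_recording(t = traj$t, f = f, omega = w, fs_configured = traj$fs,
                accel_range = accel_range, gyro_range = gyro_range,
                timestamp_mode = "relative", device_label = "synthetic")
}

#' Specification of vendor-style sensor artifacts
#'
#' Defaults represent a decent consumer-grade MEMS IMU after factory
#' calibration: white noise of 0.02 m/s^2 (accel) and 0.2 deg/s (gyro),
#' small constant biases, no scale error, no range clipping, no packet
#' loss, no timestamp jitter.  Individual artifacts are switched on by
#' setting the corresponding field.
#'
#' @param accel_noise_sd accelerometer white noise sd, m/s^2.
#' @param gyro_noise_sd gyroscope white noise sd, rad/s.
#' @param accel_bias length-3 accelerometer bias, m/s^2.
#' @param gyro_bias length-3 gyroscope bias, rad/s.
#' @param accel_scale length-3 per-axis accelerometer scale factor
#'   (1 = calibrated); models the miscalibration that makes one device of a
#'   pair systematically over- or under-range.
#' @param clip_accel_range saturation limit in g units, or `NULL` for no
#'   clipping (e.g. 4 reproduces a +/-4 g accelerometer).
#' @param packet_loss_fraction probability that each sample is lost, [0,1).
#' @param jitter_sd timestamp jitter sd, s.
#' @param seed integer RNG seed.
#' @return list of class `artifact_spec`.
#' @export
artifact_spec <- function(accel_noise_sd = 0.02,
                          gyro_noise_sd = 0.2 * pi / 180,
                          accel_bias = c(0.03, -0.02, 0.03),
                          gyro_bias = c(0.1, -0.05, 0.08) * pi / 180,
                          accel_scale = c(1, 1, 1),
                          clip_accel_range = NULL,
                          packet_loss_fraction = 0,
                          jitter_sd = 0, seed = 1) {
  if (accel_noise_sd < 0 || gyro_noise_sd < 0 || jitter_sd < 0)
    stop("noise magnitudes must be nonnegative")
  if (packet_loss_fraction < 0 || packet_loss_fraction >= 1)
    stop("packet_loss_fraction must lie in [0, 1)")
  if (!is.null(clip_accel_range) && clip_accel_range <= 0)
    stop("clip_accel_range must be positive when set")
  structure(as.list(environment()), class = "artifact_spec")
}

#' An artifact specification that leaves the signal untouched
#' @param seed integer RNG seed (unused when nothing is stochastic).
#' @return an [artifact_spec()] with every artifact disabled.
#' @export
no_artifacts <- function(seed = 1) {
  artifact_spec(accel_noise_sd = 0, gyro_noise_sd = 0,
                accel_bias = c(0, 0, 0), gyro_bias = c(0, 0, 0),
                seed = seed)
}

#' Inject sensor artifacts into an ideal recording
#'
#' Applies, in physical order: per-axis scale error, constant bias,
#' i.i.d. Gaussian noise, accelerometer range clipping (saturation acts on
#' the analog sum of signal, bias and noise), i.i.d. packet loss, and
#' finally timestamp jitter followed by re-sorting.  With an all-zero
#' specification the output equals the input.
#'
#' @param rec an [imu_recording()].
#' @param art an [artifact_spec()].
#' @return the corrupted recording; `accel_range` metadata reflects the
#'   clipping limit when clipping is enabled.
#' @export
inject_artifacts <- function(rec, art) {
  stopifnot(inherits(art, "artifact_spec"))
  n <- n_samples(rec)
  with_local_seed(art$seed, {
    f <- sweep(rec$f, 2, art$accel_scale, `*`)
    f <- sweep(f, 2, art$accel_bias, `+`)
    w <- sweep(rec$omega, 2, art$gyro_bias, `+`)
    if (art$accel_noise_sd > 0)
      f <- f + matrix(stats::rnorm(3 * n, 0, art$accel_noise_sd), n, 3)
    if (art$gyro_noise_sd > 0)
      w <- w + matrix(stats::rnorm(3 * n, 0, art$gyro_noise_sd), n, 3)
    if (!is.null(art$clip_accel_range)) {
      lim <- art$clip_accel_range * GRAVITY
      f <- pmin(pmax(f, -lim), lim)
      rec$accel_range <- art$clip_accel_range
    }
    tt <- rec$t
    if (art$packet_loss_fraction > 0) {
      keep <- stats::runif(n) >= art$packet_loss_fraction
      if (sum(keep) < 2) stop("packet loss removed nearly all samples")
      f <- f[keep, , drop = FALSE]
      w <- w[keep, , drop = FALSE]
      tt <- tt[keep]
    }
    if (art$jitter_sd > 0) {
      tt <- sort(tt + stats::rnorm(length(tt), 0, art$jitter_sd))
      dup <- duplicated(tt)
      if (any(dup)) {
        f <- f[!dup, , drop = FALSE]
        w <- w[!dup, , drop = FALSE]
        tt <- tt[!dup]
      }
    }
    rec$t <- tt
    rec$f <- f
    rec$omega <- w
    rec
  })
}

#' Synthesize a stationary (bench) recording
#'
#' The ideal rest signal is pure gravity reaction, `f = (0, 0, 9.80665)`
#' m/s^2 and zero angular rate; artifacts are then injected.  Used for
#' baseline quality-control fixtures.
#'
#' @param duration recording length, s (`duration * fs` samples).
#' @param fs sampling rate, Hz.
#' @param art an [artifact_spec()].
#' @return an [imu_recording()].
#' @export
synth_stationary <- function(duration, fs = 100, art = no_artifacts()) {
  if (duration <= 0) stop("duration must be positive")
  n <- round(duration * fs)
  rec <- imu_recording(
    t = (seq_len(n) - 1) / fs,
    f = cbind(0, 0, rep(GRAVITY, n)),
    omega = matrix(0, n, 3),
    fs_configured = fs, timestamp_mode = "relative",
    device_label = "synthetic-rest")
  inject_artifacts(rec, art)
}
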