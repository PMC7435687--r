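# rolling maximum over a centred window of +/- h samples
rolling_max <- function(x, h) {
  n <- length(x)
  y <- x
  if (h < 1 || n < 2) return(y)
  for (k in seq_len(h)) {
    lead <- c(x[-seq_len(k)], rep(x[n], k))
    lag <- c(rep(x[1], k), x[seq_len(n - k)])
    y <- pmax(y, lead, lag)
  }
  y
}

#' Detect zero-velocity (stance) samples
#'
#' A sample is stationary when, over a centred window, the peak angular
#' rate magnitude stays below `gyro_threshold` and the peak deviation of
#' the specific-force magnitude from 1 g stays below `accel_threshold` --
#' both must hold for the foot to be flat on the floor with no rotation.
#' Stationary runs shorter than `min_duration` are discarded as spurious.
#'
#' @param rec an [imu_recording()].
#' @param window detector window length, s (must span at least 2 samples).
#' @param gyro_threshold rad/s.
#' @param accel_threshold m/s^2.
#' @param min_duration minimum stance duration retained, s.
#' @return list of class `zupt_mask` with logical `stationary` (one per
#'   sample) and the parameters used.
#' @export
detect_zero_velocity <- function(rec, window = 0.1, gyro_threshold = 0.6,
                                 accel_threshold = 0.8, min_duration = 0.05) {
  fs <- rec$fs_configured
  if (round(window * fs) < 2)
    stop("detector window must span at least 2 samples")
  h <- max(1L, as.integer(round(window * fs / 2)))
  wmag <- sqrt(rowSums(rec$omega^2))
  fdev <- abs(sqrt(rowSums(rec$f^2)) - GRAVITY)
  stat <- rolling_max(wmag, h) < gyro_threshold &
    rolling_max(fdev, h) < accel_threshold
  # drop stationary runs shorter than min_duration
  r <- rle(stat)
  min_n <- max(1L, as.integer(round(min_duration * fs)))
  r$values[r$values & r$lengths < min_n] <- FALSE
  structure(list(stationary = inverse.rle(r), window = window,
                 gyro_threshold = gyro_threshold,
                 accel_threshold = accel_threshold,
                 min_duration = min_duration),
            class = "zupt_mask")
}

#' One attitude integration step
#'
#' Propagates the attitude by the closed-form rotation increment
#' `R_prev (I + sin(s)/s B + (1 - cos(s))/s^2 B^2)` with `s = |omega dt|`
#' and `B = skew(omega dt)` -- the exponential map of the rotation vector
#' `omega dt`.  Small angles use series expansions of the trigonometric
#' coefficients; the result is re-orthonormalized.
#'
#' @param R_prev 3x3 rotation matrix.
#' @param omega body angular rate, rad/s (length 3).
#' @param dt step, s.
#' @return 3x3 rotation matrix.
#' @export
attitude_update <- function(R_prev, omega, dt) {
  renormalize_rotation(R_prev %*% rotvec_to_matrix(omega * dt))
}

#' One strapdown integration step
#'
#' Explicit Euler scheme: the attitude is advanced first, the
#' gravity-excluded acceleration is `a = R f + g`, then
#' `v <- v + dt a` and `s <- s + dt v`.
#'
#' @param state list with `R` (3x3 rotation), `v`, `s` (length-3).
#' @param f specific force sample, m/s^2.
#' @param omega angular rate sample, rad/s.
#' @param dt step, s.
#' @return updated state list, with the acceleration estimate `a` attached.
#' @export
strapdown_step <- function(state, f, omega, dt) {
  R <- attitude_update(state$R, omega, dt)
  a <- as.numeric(R %*% f) + gravity_vec()
  v <- state$v + dt * a
  s <- state$s + dt * v
  list(R = R, v = v, s = s, a = a)
}

# 3x9 measurement matrix selecting the velocity error block
eskf_H <- function() cbind(matrix(0, 3, 3), diag(3), matrix(0, 3, 3))

#' Error-covariance prediction step
#'
#' Assembles the error-state transition matrix with block rows
#' (attitude error, velocity error, position error):
#' `F = [[I,0,0], [dt S, I, 0], [0, dt I, I]]` where `S = skew(R f)`
#' couples attitude error into velocity error through gravity-referenced
#' acceleration, then propagates `P <- F P F' + Sigma_w`.  Symmetry is
#' enforced by averaging with the transpose.
#'
#' @param P 9x9 symmetric error covariance.
#' @param R current attitude (3x3 rotation).
#' @param f specific force sample, m/s^2.
#' @param dt step, s.
#' @param Sigma_w 9x9 process-noise covariance.
#' @return list with updated `P` and the transition matrix `F_mat`.
#' @export
predict_covariance <- function(P, R, f, dt, Sigma_w) {
  S <- skew(as.numeric(R %*% f))
  F_mat <- diag(9)
  F_mat[4:6, 1:3] <- dt * S
  F_mat[7:9, 4:6] <- dt * diag(3)
  P <- F_mat %*% P %*% t(F_mat) + Sigma_w
  list(P = (P + t(P)) / 2, F_mat = F_mat, S = S)
}

#' Zero-velocity correction step
#'
#' During stance the true foot velocity is zero, so the innovation is
#' `0 - H x = -v`.  The Kalman gain is
#' `K = P H' (H P H' + Sigma_v)^-1`, the error state is `dx = -K v`, and
#' the covariance shrinks to `P - K H P`.  The error estimate is folded
#' back into the state: additively for velocity and position, and
#' multiplicatively for the attitude, whose error sub-vector is a
#' small-angle rotation vector: `R <- (I - skew(dtheta)) R`,
#' re-orthonormalized.  The sign follows from the transition matrix: with
#' the velocity-error coupling `+dt skew(R f)` the attitude-error vector
#' is defined by `R_true = (I - skew(dtheta)) R_est`, so folding the
#' estimated error back in uses the minus sign (flipping it turns every
#' correction into positive feedback on the tilt error).
#'
#' @param P 9x9 error covariance after prediction.
#' @param state list with `R`, `v`, `s`.
#' @param Sigma_v 3x3 measurement-noise covariance of the pseudo-measurement.
#' @return list with corrected `P`, `state`, and the error estimate `dx`.
#' @export
zupt_correct <- function(P, state, Sigma_v) {
  H <- eskf_H()
  PHt <- P[, 4:6, drop = FALSE]          # P H'
  Sinn <- P[4:6, 4:6] + Sigma_v          # H P H' + Sigma_v
  K <- t(solve(Sinn, t(PHt)))            # P H' Sinn^-1
  dx <- as.numeric(K %*% (-state$v))
  P <- P - K %*% P[4:6, , drop = FALSE]  # (I - K H) P
  P <- (P + t(P)) / 2
  state$v <- state$v + dx[4:6]
  state$s <- state$s + dx[7:9]
  state$R <- orthonormalize((diag(3) - skew(dx[1:3])) %*% state$R)
  list(P = P, state = state, dx = dx)
}

# initial attitude from the mean specific force over the initial rest:
# the rotation (yaw-free) taking the measured gravity direction to +z
attitude_from_gravity <- function(f_mean) {
  u <- f_mean / sqrt(sum(f_mean^2))
  ez <- c(0, 0, 1)
  axis <- c(u[2] * ez[3] - u[3] * ez[2],
            u[3] * ez[1] - u[1] * ez[3],
            u[1] * ez[2] - u[2] * ez[1])
  s <- sqrt(sum(axis^2))
  ang <- atan2(s, sum(u * ez))
  if (s < 1e-12) {
    if (sum(u * ez) > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # upside down: flip about x
  }
  rotvec_to_matrix(axis / s * ang)
}

#' ESKF configuration
#'
#' All tunables of the zero-velocity-aided error-state Kalman filter, with
#' defaults.  Process noise is diagonal with per-axis blocks
#' `(gyro_noise_sd^2 dt^2, accel_noise_sd^2 dt^2, 0)` for the attitude,
#' velocity and position errors; the measurement noise of the
#' zero-velocity pseudo-measurement is `zupt_noise_sd^2 I`.
#'
#' @param zupt_window,zupt_gyro_threshold,zupt_accel_threshold,zupt_min_duration
#'   stance detector parameters, see [detect_zero_velocity()].
#' @param accel_noise_sd,gyro_noise_sd assumed sensor noise (m/s^2, rad/s).
#' @param zupt_noise_sd assumed zero-velocity measurement noise, m/s.
#' @param max_gap largest tolerated inter-sample interval, s; `NULL` means
#'   3.5 nominal sampling intervals (two consecutive lost samples pass,
#'   three abort).
#' @param bridge_gaps if `TRUE`, gaps of at most `bridge_max_missing`
#'   samples are filled by linear interpolation instead of aborting.
#' @param bridge_max_missing largest bridgeable gap, samples.
#' @param init_rest_min required initial stationary period, s.
#' @param zupt_enabled apply corrections (disable to expose open-loop drift).
#' @param check_psd track the minimum eigenvalue of P at every step.
#' @return list of class `eskf_config`.
#' @export
eskf_config <- function(zupt_window = 0.1, zupt_gyro_threshold = 0.6,
                        zupt_accel_threshold = 0.8, zupt_min_duration = 0.05,
                        accel_noise_sd = 0.02, gyro_noise_sd = 0.2 * pi / 180,
                        zupt_noise_sd = 0.01,
                        max_gap = NULL, bridge_gaps = FALSE,
                        bridge_max_missing = 3, init_rest_min = 0.5,
                        zupt_enabled = TRUE, check_psd = TRUE) {
  structure(as.list(environment()), class = "eskf_config")
}

# insert linearly interpolated samples on the nominal grid inside small gaps
bridge_small_gaps <- function(rec, max_missing) {
  dt0 <- nominal_dt(rec)
  dts <- diff(rec$t)
  idx <- which(dts > 1.5 * dt0)
  t_new <- rec$t
  f_new <- rec$f
  w_new <- rec$omega
  add_t <- numeric(0)
  for (i in idx) {
    k <- round(dts[i] / dt0) - 1
    if (k >= 1 && k <= max_missing)
      add_t <- c(add_t, rec$t[i] + seq_len(k) * dts[i] / (k + 1))
  }
  if (length(add_t)) {
    interp <- function(col, x) stats::approx(rec$t, col, xout = x)$y
    f_add <- sapply(seq_len(3), function(j) interp(rec$f[, j], add_t))
    w_add <- sapply(seq_len(3), function(j) interp(rec$omega[, j], add_t))
    ord <- order(c(rec$t, add_t))
    t_new <- c(rec$t, add_t)[ord]
    f_new <- rbind(rec$f, f_add)[ord, ]
    w_new <- rbind(rec$omega, w_add)[ord, ]
  }
  rec$t <- t_new
  rec$f <- f_new
  rec$omega <- w_new
  rec
}

#' Run the zero-velocity-aided error-state Kalman filter
#'
#' The full estimator: stance detection, attitude initialization from the
#' gravity direction during the initial standstill (yaw set to zero),
#' then per sample a strapdown step (attitude, velocity, displacement), a
#' covariance prediction, and -- on stationary samples -- a zero-velocity
#' correction.  Recordings with data gaps longer than `config$max_gap`
#' abort with an error listing the gap intervals rather than silently
#' integrating across missing data.
#'
#' @param rec an [imu_recording()] starting with at least
#'   `config$init_rest_min` seconds of standstill.
#' @param config an [eskf_config()].
#' @return An object of class `eskf_result`: `t`, `R` (3x3xn), `v`, `s`
#'   (n x 3), `a` (n x 3), `mask` (the [detect_zero_velocity()] result),
#'   and `diagnostics` (corrections applied, covariance health).
#' @export
run_eskf <- function(rec, config = eskf_config()) {
  stopifnot(inherits(config, "eskf_config"))
  max_gap <- if (is.null(config$max_gap)) 3.5 * nominal_dt(rec) else config$max_gap
  if (config$bridge_gaps)
    rec <- bridge_small_gaps(rec, config$bridge_max_missing)
  dts <- diff(rec$t)
  if (any(dts > max_gap)) {
    bad <- which(dts > max_gap)
    stop(sprintf(
      "data loss: %d gap(s) exceed max_gap = %.4f s (first at %.3f-%.3f s); %s",
      length(bad), max_gap, rec$t[bad[1]], rec$t[bad[1] + 1],
      "use bridge_gaps for isolated drops or re-record"))
  }
  mask <- detect_zero_velocity(rec, config$zupt_window,
                               config$zupt_gyro_threshold,
                               config$zupt_accel_threshold,
                               config$zupt_min_duration)
  stat <- mask$stationary
  n <- n_samples(rec)
  # initial standstill: the recording must open with a stationary run
  r <- rle(stat)
  if (!r$values[1])
    stop("no initial standstill detected; the filter needs a rest period to initialize")
  n0 <- r$lengths[1]
  if (rec$t[n0] - rec$t[1] < config$init_rest_min)
    stop(sprintf("initial standstill too short (%.2f s < %.2f s)",
                 rec$t[n0] - rec$t[1], config$init_rest_min))
  R0 <- attitude_from_gravity(colMeans(rec$f[seq_len(n0), , drop = FALSE]))

  Rh <- array(0, c(3, 3, n))
  vh <- matrix(0, n, 3)
  sh <- matrix(0, n, 3)
  ah <- matrix(0, n, 3)
  Rh[, , 1] <- R0
  state <- list(R = R0, v = c(0, 0, 0), s = c(0, 0, 0))
  P <- matrix(0, 9, 9)
  Sigma_v <- diag(config$zupt_noise_sd^2, 3)
  qdiag <- c(rep(config$gyro_noise_sd^2, 3), rep(config$accel_noise_sd^2, 3),
             rep(0, 3))
  n_corr <- 0L
  min_eig <- Inf
  for (i in seq_len(n)[-1]) {
    dt <- dts[i - 1]
    state <- strapdown_step(state, rec$f[i, ], rec$omega[i, ], dt)
    pred <- predict_covariance(P, state$R, rec$f[i, ], dt,
                               diag(qdiag * dt^2))
    P <- pred$P
    if (config$zupt_enabled && stat[i]) {
      cor <- zupt_correct(P, state, Sigma_v)
      P <- cor$P
      state <- cor$state
      n_corr <- n_corr + 1L
    }
    if (config$check_psd)
      min_eig <- min(min_eig, min(eigen(P, symmetric = TRUE,
                                        only.values = TRUE)$values))
    Rh[, , i] <- state$R
    vh[i, ] <- state$v
    sh[i, ] <- state$s
    ah[i, ] <- state$a
  }
  structure(list(
    t = rec$t, R = Rh, v = vh, s = sh, a = ah, mask = mask,
    diagnostics = list(n_corrections = n_corr, min_P_eigenvalue = min_eig,
                       n_stationary = sum(stat), P_final = P),
    config = config), class = "eskf_result")
}

#' @export
print.eskf_result <- function(x, ...) {
  cat(sprintf(
    "<eskf_result> %d samples, %d ZUPT corrections, final position (%.3f, %.3f, %.3f) m\n",
    length(x$t), x$diagnostics$n_corrections,
    x$s[nrow(x$s), 1], x$s[nrow(x$s), 2], x$s[nrow(x$s), 3]))
  invisible(x)
}
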