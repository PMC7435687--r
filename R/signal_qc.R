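#' Empirical sampling rates from adjacent timestamps
#'
#' For each adjacent timestamp pair the empirical rate is the inverse of
#' the interval, `1 / (t_i - t_{i-1})`.  Streamed recordings whose packets
#' are stamped on arrival show a wide spread around the configured rate,
#' including near-zero intervals; those non-positive intervals are counted
#' separately and excluded from the histogram.
#'
#' @param rec an [imu_recording()] with timestamps.
#' @param bin_width histogram bin width, Hz (1 Hz bins centred on integers).
#' @return list of class `sampling_rate_report`: `fs_values` (Hz, one per
#'   adjacent pair), `fs_configured`, `n_nonpositive`, and `histogram`
#'   (list with `breaks`, `counts`).
#' @export
empirical_sampling_rates <- function(rec, bin_width = 1) {
  if (rec$timestamp_mode == "absent")
    stop("recording has no native timestamps; empirical rates undefined")
  if (n_samples(rec) < 2) stop("need at least 2 samples")
  dt <- diff(rec$t)
  pos <- dt > 0
  fs_values <- ifelse(pos, 1 / dt, NA_real_)
  fv <- fs_values[pos]
  breaks <- seq(floor(min(c(fv, rec$fs_configured))) - bin_width / 2,
                ceiling(max(c(fv, rec$fs_configured))) + bin_width / 2,
                by = bin_width)
  h <- graphics::hist(fv, breaks = breaks, plot = FALSE)
  structure(list(fs_values = fs_values,
                 fs_configured = rec$fs_configured,
                 n_nonpositive = sum(!pos),
                 histogram = list(breaks = h$breaks, counts = h$counts)),
            class = "sampling_rate_report")
}

#' Stationary baseline summary
#'
#' Summary statistics of a bench (stationary) recording used to screen
#' sensor calibration: for a perfectly calibrated IMU at rest the
#' acceleration magnitude is exactly 1 g and the angular velocity is zero.
#' Statistics are computed over the first `n` samples (5000 by default).
#'
#' @param rec an [imu_recording()] of a stationary device.
#' @param n number of samples to summarize.
#' @param use_all if `TRUE`, recordings shorter than `n` are summarized in
#'   full instead of raising an error.
#' @return list of class `baseline_report`: per-axis quartile matrices and
#'   means for both sensors, plus `accel_magnitude_mean` and
#'   `gyro_magnitude_mean` (SI units), and `n_used`.
#' @export
baseline_summary <- function(rec, n = 5000, use_all = FALSE) {
  if (n_samples(rec) < n) {
    if (!use_all)
      stop(sprintf("recording has %d samples; %d required (use_all = TRUE to override)",
                   n_samples(rec), n))
    n <- n_samples(rec)
  }
  f <- rec$f[seq_len(n), , drop = FALSE]
  w <- rec$omega[seq_len(n), , drop = FALSE]
  qs <- function(m) apply(m, 2, stats::quantile, probs = c(0.25, 0.5, 0.75))
  structure(list(
    accel_quartiles = qs(f), accel_mean = colMeans(f),
    gyro_quartiles = qs(w), gyro_mean = colMeans(w),
    accel_magnitude_mean = mean(sqrt(rowSums(f^2))),
    gyro_magnitude_mean = mean(sqrt(rowSums(w^2))),
    n_used = n), class = "baseline_report")
}

#' Detect accelerometer saturation (range clipping)
#'
#' A sample's axis is flagged as clipped when its absolute value reaches
#' `tol` times the full-scale range.  The sub-unity tolerance allows for
#' quantization leaving values one LSB inside the rail.  Lowering `tol`
#' can only grow the flagged fractions.
#'
#' @param rec an [imu_recording()] with `accel_range` metadata (g units).
#' @param tol fraction of full scale treated as the rail.
#' @return list of class `clipping_report`: `clipped_fraction_per_axis`
#'   (length 3) and `limit_used` (m/s^2).
#' @export
detect_clipping <- function(rec, tol = 0.999) {
  if (is.null(rec$accel_range) || !isTRUE(rec$accel_range > 0))
    stop("accel_range metadata required to assess clipping")
  lim <- tol * rec$accel_range * GRAVITY
  frac <- colMeans(abs(rec$f) >= lim)
  structure(list(clipped_fraction_per_axis = frac,
                 limit_used = lim), class = "clipping_report")
}
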