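#' Construct an IMU recording
#'
#' Container for a time-stamped 6-axis inertial recording: specific force
#' `f` (accelerometer, m/s^2) and angular rate `omega` (gyroscope, rad/s) in
#' the sensor frame, plus sensor metadata.  All internal times are seconds
#' relative to the recording start; a Unix-epoch origin, when present in the
#' source file, is kept as metadata (`t_offset`).
#'
#' @param t numeric vector of sample times, seconds, strictly increasing.
#'   May be `NULL` when `timestamp_mode = "absent"`, in which case times are
#'   reconstructed as `(i - 1) / fs_configured`.
#' @param f n x 3 matrix of specific force, m/s^2 (columns x, y, z).
#' @param omega n x 3 matrix of angular rate, rad/s.
#' @param fs_configured configured sampling rate, Hz.
#' @param accel_range accelerometer full-scale range, g units (e.g. 8).
#' @param gyro_range gyroscope full-scale range, deg/s (e.g. 2000).
#' @param timestamp_mode one of `"relative"`, `"unix"`, `"absent"`.
#' @param device_label free-text device identifier.
#' @param t_offset epoch origin subtracted from Unix timestamps (seconds).
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(t, f, omega, fs_configured,
                          accel_range = 8, gyro_range = 2000,
                          timestamp_mode = c("relative", "unix", "absent"),
                          device_label = "synthetic", t_offset = 0) {
  timestamp_mode <- match.arg(timestamp_mode)
  f <- unname(as.matrix(f))
  omega <- unname(as.matrix(omega))
  n <- nrow(f)
  if (!identical(dim(f), dim(omega)) || ncol(f) != 3L)
    stop("f and omega must be n x 3 matrices of equal size")
  if (timestamp_mode == "absent" || is.null(t)) {
    t <- (seq_len(n) - 1) / fs_configured
    timestamp_mode <- "absent"
  }
  t <- as.numeric(t)
  if (length(t) != n) stop("length(t) must match nrow(f)")
  if (n > 0 && (any(!is.finite(t)) || any(!is.finite(f)) || any(!is.finite(omega))))
    stop("non-finite sample values")
  if (n > 1) {
    dt <- diff(t)
    if (any(dt < 0)) stop("sample times must not decrease")
    # ties are tolerated (streamed data stamped on packet arrival) so the
    # QC layer can count them; file readers collapse them instead
    if (any(dt == 0))
      warning("recording contains duplicated timestamps")
  }
  if (!isTRUE(accel_range > 0) || !isTRUE(gyro_range > 0))
    stop("sensor ranges must be positive")
  structure(list(
    t = t, f = f, omega = omega,
    fs_configured = fs_configured,
    accel_range = accel_range, gyro_range = gyro_range,
    timestamp_mode = timestamp_mode,
    device_label = device_label,
    t_offset = t_offset
  ), class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> %d samples, %.3f s, fs_configured = %g Hz (%s timestamps)\n",
    n_samples(x), if (n_samples(x) > 1) diff(range(x$t)) else 0,
    x$fs_configured, x$timestamp_mode))
  cat(sprintf("  ranges: +/-%g g accel, +/-%g deg/s gyro; device: %s\n",
              x$accel_range, x$gyro_range, x$device_label))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `imu_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) length(rec$t)

#' Nominal sampling interval of a recording
#' @param rec an `imu_recording`.
#' @return `1 / fs_configured`, seconds.
#' @export
nominal_dt <- function(rec) 1 / rec$fs_configured

#' Read a unified-format IMU CSV file
#'
#' The unified layout has a header `t,ax,ay,az,gx,gy,gz` (an optional
#' `unix_t` column may replace or accompany `t`).  Vendors exporting without
#' timestamps are supported: with `has_time = FALSE` (or neither time column
#' present) sample times are reconstructed from the configured rate.
#' Rows are sorted by time and duplicate timestamps are collapsed to the
#' first occurrence with a warning, since streamed data can stamp several
#' packets with one arrival time.
#'
#' @param path CSV file path.
#' @param fs_configured configured sampling rate, Hz.
#' @param accel_unit unit of the acceleration columns: `"m/s^2"` or `"g"`.
#' @param gyro_unit unit of the gyroscope columns: `"rad/s"` or `"deg/s"`.
#' @param accel_range,gyro_range sensor full-scale metadata (g, deg/s).
#' @param device_label free-text device identifier.
#' @return An [imu_recording()] with units normalized to m/s^2 and rad/s.
#' @export
read_unified_csv <- function(path, fs_configured,
                             accel_unit = "m/s^2", gyro_unit = "rad/s",
                             accel_range = 8, gyro_range = 2000,
                             device_label = basename(path)) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  need <- c("ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("unified CSV is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  for (cn in intersect(c("t", "unix_t", need), names(df))) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value in column '%s' at data row %d", cn, bad[1]))
      df[[cn]] <- num
    }
  }
  timestamp_mode <- "relative"
  t_offset <- 0
  if ("unix_t" %in% names(df) && !("t" %in% names(df))) {
    timestamp_mode <- "unix"
    t_offset <- df$unix_t[1]
    tvec <- df$unix_t - t_offset
  } else if ("t" %in% names(df)) {
    tvec <- df$t
    if ("unix_t" %in% names(df)) t_offset <- df$unix_t[1]
  } else {
    timestamp_mode <- "absent"
    tvec <- (seq_len(nrow(df)) - 1) / fs_configured
  }
  ord <- order(tvec)
  df <- df[ord, , drop = FALSE]
  tvec <- tvec[ord]
  dup <- duplicated(tvec)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate timestamp(s) to first occurrence",
                    sum(dup)))
    df <- df[!dup, , drop = FALSE]
    tvec <- tvec[!dup]
  }
  rec <- imu_recording(
    t = if (timestamp_mode == "absent") NULL else tvec,
    f = as.matrix(df[, c("ax", "ay", "az")]),
    omega = as.matrix(df[, c("gx", "gy", "gz")]),
    fs_configured = fs_configured,
    accel_range = accel_range, gyro_range = gyro_range,
    timestamp_mode = timestamp_mode,
    device_label = device_label, t_offset = t_offset)
  normalize_units(rec, accel_unit = accel_unit, gyro_unit = gyro_unit)
}

#' Normalize recording channels to SI units
#'
#' Converts accelerations to m/s^2 (1 g = 9.80665 m/s^2) and angular rates
#' to rad/s (pi/180 per deg/s).  Idempotent once units are SI.
#'
#' @param rec an `imu_recording`.
#' @param accel_unit unit the acceleration channels are currently in.
#' @param gyro_unit unit the gyroscope channels are currently in.
#' @return the recording in SI units.
#' @export
normalize_units <- function(rec, accel_unit = c("m/s^2", "g"),
                            gyro_unit = c("rad/s", "deg/s")) {
  accel_unit <- match.arg(accel_unit)
  gyro_unit <- match.arg(gyro_unit)
  if (accel_unit == "g") rec$f <- rec$f * GRAVITY
  if (gyro_unit == "deg/s") rec$omega <- rec$omega * pi / 180
  rec
}

#' Write a recording in the unified CSV layout
#'
#' Values are written with 17 significant digits ("%.17g") so that a
#' write/read round trip reproduces every sample bit-for-bit.  No
#' resampling is performed: gaps in the time base survive the round trip.
#'
#' @param rec an `imu_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_unified_csv <- function(rec, path) {
  cols <- list(
    t = rec$t,
    ax = rec$f[, 1], ay = rec$f[, 2], az = rec$f[, 3],
    gx = rec$omega[, 1], gy = rec$omega[, 2], gz = rec$omega[, 3])
  if (rec$timestamp_mode == "unix") cols$unix_t <- rec$t + rec$t_offset
  lines <- paste(names(cols), collapse = ",")
  if (n_samples(rec) > 0) {
    body <- do.call(paste, c(lapply(cols, function(v) sprintf("%.17g", v)),
                             sep = ","))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Detect sampling gaps and the retained-data fraction
#'
#' An interval between consecutive samples is a gap when it exceeds
#' `factor` times the nominal sampling interval.  The retained fraction is
#' the observed sample count over the count a gap-free recording of the
#' same duration would contain; streamed devices that lose packets (e.g.
#' Bluetooth transfer) show retained fractions well below 1.
#'
#' @param rec an `imu_recording` with at least 2 samples.
#' @param factor gap threshold as a multiple of `nominal_dt(rec)`.
#' @return A list of class `gap_report` with `gap_intervals` (two-column
#'   matrix of start/end times), `retained_fraction`, and `n_gaps`.
#' @export
detect_gaps <- function(rec, factor = 1.5) {
  if (n_samples(rec) < 2) stop("need at least 2 samples to detect gaps")
  dt <- diff(rec$t)
  thr <- factor * nominal_dt(rec)
  idx <- which(dt > thr)
  expected <- round(diff(range(rec$t)) * rec$fs_configured + 1)
  rf <- min(1, max(0, n_samples(rec) / expected))
  structure(list(
    gap_intervals = cbind(start_t = rec$t[idx], end_t = rec$t[idx + 1]),
    retained_fraction = rf,
    n_gaps = length(idx)
  ), class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> %d gap(s), retained fraction %.3f\n",
              x$n_gaps, x$retained_fraction))
  invisible(x)
}

#' Read a reference stride table
#'
#' Reference systems (e.g. a photoelectric walkway) export per-stride
#' initial-contact time, stride length and stride time.  Expected header:
#' `foot,ic_time,stride_length,stride_time`.
#'
#' @param path CSV file path.
#' @return data.frame with columns `foot` (character, "left"/"right"),
#'   `ic_time` (s), `stride_length` (m), `stride_time` (s).
#' @export
read_reference_strides <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("foot", "ic_time", "stride_length", "stride_time")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("reference stride CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) && (any(df$stride_length <= 0) || any(df$stride_time <= 0)))
    stop("stride lengths and times must be positive")
  df[, need]
}

#' Write a reference stride table
#' @param strides data.frame with columns `foot`, `ic_time`,
#'   `stride_length`, `stride_time` (extra columns are dropped).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference_strides <- function(strides, path) {
  need <- c("foot", "ic_time", "stride_length", "stride_time")
  utils::write.csv(strides[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
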