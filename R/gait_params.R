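# centred moving average, window w samples (odd), edges shrink
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  y <- as.numeric(y)
  # fill edges with the original samples
  na <- is.na(y)
  y[na] <- x[na]
  y
}

# indices of local maxima of x with height >= height, separated by >= min_sep
# samples; greedy from the highest peak down
find_peaks <- function(x, height, min_sep) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in cand) {
    if (!length(keep) || all(abs(keep - p) >= min_sep)) keep <- c(keep, p)
  }
  sort(keep)
}

#' Detect gait events from raw angular velocity
#'
#' Works directly on the gyroscope signal, as temporal gait events do not
#' require any integration.  The sagittal channel is chosen as the gyro
#' axis of maximal variance (mounting orientations differ between
#' devices), with its sign disambiguated so that midswing peaks are
#' positive (the dominant-polarity peaks are taken as midswing).  Midswing
#' events are peaks above `prominence` separated by at least
#' `min_stride_time`; initial contact is the minimum of the channel in the
#' window after each midswing peak, and foot off the minimum in the window
#' before it -- the touchdown and lift-off dips that flank the swing lobe.
#'
#' @param rec an [imu_recording()] of walking.
#' @param prominence minimum midswing peak height, rad/s.
#' @param min_stride_time minimum time between midswing peaks, s; also the
#'   search window for the flanking minima.
#' @param smooth_window moving-average window applied before peak picking, s.
#' @return list of class `gait_events`: `ic_times`, `fo_times`,
#'   `midswing_times` (s, snapped to sample times), `axis`, `sign`.
#' @export
detect_gait_events <- function(rec, prominence = 1.5, min_stride_time = 0.4,
                               smooth_window = 0.05) {
  fs <- rec$fs_configured
  v <- apply(rec$omega, 2, stats::var)
  axis <- which.max(v)
  x0 <- rec$omega[, axis]
  w <- max(1L, as.integer(round(smooth_window * fs)))
  if (w %% 2 == 0) w <- w + 1L
  x0 <- moving_average(x0, w)
  min_sep <- as.integer(round(min_stride_time * fs))
  # pick the polarity whose rectified peaks are taller
  p_pos <- find_peaks(x0, prominence, min_sep)
  p_neg <- find_peaks(-x0, prominence, min_sep)
  med <- function(p, x) if (length(p)) stats::median(x[p]) else -Inf
  sgn <- if (med(p_neg, -x0) > med(p_pos, x0)) -1 else 1
  x <- sgn * x0
  peaks <- if (sgn == 1) p_pos else p_neg
  if (!length(peaks)) stop("no gait detected: no angular-velocity peaks found")
  n <- length(x)
  ic <- integer(0)
  fo <- integer(0)
  ms <- integer(0)
  for (j in seq_along(peaks)) {
    p <- peaks[j]
    hi <- min(n, p + min_sep)
    if (j < length(peaks)) hi <- min(hi, peaks[j + 1] - 1L)
    lo <- max(1L, p - min_sep)
    if (j > 1) lo <- max(lo, peaks[j - 1] + 1L)
    if (hi <= p || lo >= p) next
    ici <- p + which.min(x[(p + 1):hi])
    foi <- lo + which.min(x[lo:(p - 1)]) - 1L
    ms <- c(ms, p)
    ic <- c(ic, ici)
    fo <- c(fo, foi)
  }
  structure(list(ic_times = rec$t[ic], fo_times = rec$t[fo],
                 midswing_times = rec$t[ms],
                 ic_idx = ic, fo_idx = fo, midswing_idx = ms,
                 axis = axis, sign = sgn),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d midswing peaks on gyro axis %d (sign %+d)\n",
              length(x$midswing_times), x$axis, x$sign))
  invisible(x)
}

#' Segment strides and compute spatio-temporal parameters
#'
#' One stride per consecutive pair of initial contacts of the same foot.
#' Stride length is the horizontal Euclidean displacement between the two
#' contacts; clearance is the peak elevation during swing above the
#' stride's own stance ground level (the median height over the stance),
#' which makes it robust to residual vertical drift; stance time runs from
#' initial contact to the following foot off, swing time from foot off to
#' the next initial contact.
#'
#' @param events a [detect_gait_events()] result.
#' @param result an `eskf_result` (or any list with `t` and `s` history).
#' @param foot foot label to attach.
#' @return data.frame of class `stride_table` with columns `foot`,
#'   `ic_time`, `fo_time`, `stride_length`, `stride_time`, `stance_time`,
#'   `swing_time`, `clearance`, `speed`, `is_turn`.
#' @export
segment_strides <- function(events, result, foot = "right") {
  if (length(events$ic_idx) < 2)
    stop("need at least 2 initial contacts to segment a stride")
  if (length(result$t) != nrow(result$s))
    stop("trajectory and time base lengths differ")
  s <- result$s
  t <- result$t
  n_str <- length(events$ic_idx) - 1
  out <- vector("list", n_str)
  for (k in seq_len(n_str)) {
    i0 <- events$ic_idx[k]
    i1 <- events$ic_idx[k + 1]
    # the foot-off event inside this stride
    fo_k <- events$fo_idx[events$fo_idx > i0 & events$fo_idx < i1]
    fo_k <- if (length(fo_k)) fo_k[1] else NA_integer_
    d <- s[i1, ] - s[i0, ]
    stride_time <- t[i1] - t[i0]
    ground <- if (!is.na(fo_k)) stats::median(s[i0:fo_k, 3]) else s[i0, 3]
    clearance <- max(s[i0:i1, 3]) - ground
    stance <- if (!is.na(fo_k)) t[fo_k] - t[i0] else NA_real_
    out[[k]] <- data.frame(
      foot = foot, ic_time = t[i0], fo_time = if (is.na(fo_k)) NA_real_ else t[fo_k],
      stride_length = sqrt(d[1]^2 + d[2]^2), stride_time = stride_time,
      stance_time = stance, swing_time = stride_time - stance,
      clearance = clearance,
      speed = sqrt(d[1]^2 + d[2]^2) / stride_time,
      is_turn = FALSE, stringsAsFactors = FALSE)
  }
  strides <- do.call(rbind, out)
  class(strides) <- c("stride_table", "data.frame")
  strides
}

#' Flag and exclude turning strides
#'
#' A stride is a turn when the heading (yaw of the estimated attitude)
#' changes by more than `heading_threshold` between its two initial
#' contacts.  Protocols with a straight capture volume exclude turning
#' strides from agreement analyses; optionally the strides adjacent to a
#' turn are dropped as well.
#'
#' @param strides a `stride_table` from [segment_strides()].
#' @param result the `eskf_result` the strides were cut from.
#' @param heading_threshold degrees.
#' @param drop_adjacent also drop the strides immediately before and after
#'   each turn.
#' @return the non-turn strides; the full table with `is_turn` filled in is
#'   attached as attribute `"all"`.
#' @export
exclude_turns <- function(strides, result, heading_threshold = 20,
                          drop_adjacent = FALSE) {
  idx0 <- match(round(strides$ic_time, 9), round(result$t, 9))
  idx1 <- match(round(strides$ic_time + strides$stride_time, 9),
                round(result$t, 9))
  dyaw <- vapply(seq_len(nrow(strides)), function(k) {
    y0 <- yaw_of(result$R[, , idx0[k]])
    y1 <- yaw_of(result$R[, , idx1[k]])
    d <- (y1 - y0 + pi) %% (2 * pi) - pi
    abs(d) * 180 / pi
  }, numeric(1))
  strides$is_turn <- dyaw >= heading_threshold
  drop <- strides$is_turn
  if (drop_adjacent && any(strides$is_turn)) {
    w <- which(strides$is_turn)
    drop[pmax(w - 1, 1)] <- TRUE
    drop[pmin(w + 1, nrow(strides))] <- TRUE
  }
  kept <- strides[!drop, , drop = FALSE]
  attr(kept, "all") <- strides
  kept
}

#' Cadence of a stride sequence
#'
#' Two steps per stride: `2 * 60 / mean(stride_time)`.
#'
#' @param strides a `stride_table` (or data.frame with `stride_time`).
#' @return steps per minute.
#' @export
cadence <- function(strides) {
  if (!nrow(strides)) stop("no strides")
  120 / mean(strides$stride_time)
}

#' Write a stride table to CSV
#' @param strides a `stride_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stride_table <- function(strides, path) {
  utils::write.csv(as.data.frame(strides), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stride table from CSV
#' @param path CSV written by [write_stride_table()].
#' @return a `stride_table` data.frame.
#' @export
read_stride_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("stride_table", "data.frame")
  df
}
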