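#' Multi-sensor kinematics recording
#'
#' @param time numeric vector of frame times (seconds), uniformly spaced.
#' @param pos numeric array frames x 3 x sensors (meters).
#' @param quat numeric array frames x 4 x sensors (scalar-first unit
#'   quaternions).
#' @param sensors character vector of sensor labels.
#' @param rate nominal sampling rate in Hz.
#' @return object of class `kinematics_recording`.
#' @export
kinematics_recording <- function(time, pos, quat, sensors, rate) {
  stopifnot(length(dim(pos)) == 3L, dim(pos)[2] == 3L,
            length(dim(quat)) == 3L, dim(quat)[2] == 4L,
            dim(pos)[1] == length(time), dim(quat)[1] == length(time),
            dim(pos)[3] == length(sensors), dim(quat)[3] == length(sensors))
  if (length(time) > 2L) {
    dt <- diff(time)
    if (max(abs(dt - 1 / rate)) > 0.25 / rate)
      stop("frame times are not uniformly sampled at the stated rate")
  }
  nrm <- sqrt(quat[, 1, , drop = FALSE]^2 + quat[, 2, , drop = FALSE]^2 +
                quat[, 3, , drop = FALSE]^2 + quat[, 4, , drop = FALSE]^2)
  if (any(abs(nrm - 1) > 1e-3)) stop("quaternions are far from unit norm")
  structure(list(time = as.numeric(time), pos = pos, quat = quat,
                 sensors = sensors, rate = rate),
            class = "kinematics_recording")
}

#' @export
print.kinematics_recording <- function(x, ...) {
  cat(sprintf("<kinematics_recording> %d frames @ %g Hz, %d sensors\n",
              length(x$time), x$rate, length(x$sensors)))
  invisible(x)
}

#' Single-channel ECG recording
#'
#' @param time sample times (seconds).
#' @param mv voltage in millivolts.
#' @param rate sampling rate in Hz (nominally 256).
#' @param filtered has a band-pass been applied?
#' @param filter_spec optional list describing the applied filter.
#' @return object of class `ecg_recording`.
#' @export
ecg_recording <- function(time, mv, rate, filtered = FALSE,
                          filter_spec = NULL) {
  stopifnot(length(time) == length(mv))
  structure(list(time = as.numeric(time), mv = as.numeric(mv), rate = rate,
                 filtered = filtered, filter_spec = filter_spec),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> %d samples @ %g Hz%s\n",
              length(x$mv), x$rate,
              if (isTRUE(x$filtered)) " (band-passed)" else ""))
  invisible(x)
}

#' Resample a kinematics recording by piecewise cubic splines
#'
#' Every position channel is interpolated with a cubic spline onto a uniform
#' grid at `target_rate` spanning the same time range (no extrapolation), so
#' the output length is `round(N * target / source)` within one sample.
#' Quaternions are made sign-continuous, interpolated componentwise and
#' renormalized.
#'
#' @param rec a [kinematics_recording()].
#' @param target_rate new rate in Hz (e.g. 256 to align with the ECG).
#' @return a [kinematics_recording()] at `target_rate`.
#' @export
resample_kinematics <- function(rec, target_rate) {
  stopifnot(inherits(rec, "kinematics_recording"), target_rate > 0)
  n <- length(rec$time)
  if (n < 4L) stop("insufficient data: need at least 4 samples to spline")
  t0 <- rec$time[1L]
  t1 <- rec$time[n]
  new_time <- t0 + seq(0L, floor((t1 - t0) * target_rate)) / target_rate
  m <- length(new_time)
  S <- length(rec$sensors)
  pos <- array(NA_real_, c(m, 3L, S))
  quat <- array(NA_real_, c(m, 4L, S))
  for (s in seq_len(S)) {
    for (k in 1:3)
      pos[, k, s] <- stats::spline(rec$time, rec$pos[, k, s],
                                   xout = new_time, method = "fmm")$y
    q <- quat_sign_continuity(rec$quat[, , s])
    for (k in 1:4)
      quat[, k, s] <- stats::spline(rec$time, q[, k],
                                    xout = new_time, method = "fmm")$y
    quat[, , s] <- quat_normalize(quat[, , s])
  }
  kinematics_recording(new_time, pos, quat, rec$sensors, target_rate)
}

#' Band-pass filter an ECG recording (zero-phase Butterworth)
#'
#' Butterworth IIR band-pass of the stated order, applied forward and
#' backward (`signal::filtfilt`) so the filter delay does not bias
#' lead/lag estimates.
#'
#' @param ecg an [ecg_recording()].
#' @param low,high band edges in Hz (defaults 5 and 30).
#' @param order filter order (default 2).
#' @return filtered [ecg_recording()] with the `filtered` flag set.
#' @export
bandpass_ecg <- function(ecg, low = 5, high = 30, order = 2L) {
  stopifnot(inherits(ecg, "ecg_recording"))
  nyq <- ecg$rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < rate/2")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  y <- signal::filtfilt(bf, ecg$mv)
  ecg_recording(ecg$time, y, ecg$rate, filtered = TRUE,
                filter_spec = list(type = "butterworth_bandpass",
                                   low_hz = low, high_hz = high,
                                   order = order, zero_phase = TRUE))
}

#' Segment pointing trials into forward and backward intervals
#'
#' Within each trial window the forward reach runs from the last
#' near-zero-speed frame before the speed rises toward the target to the
#' first near-zero-speed frame at the target (where the distance to the
#' target is minimal); the backward retraction runs from where speed rises
#' away from zero at the target to the next near-zero rest.  "Near zero"
#' means below `speed_threshold_frac` of the trial's peak speed.  Intervals
#' are half-open `[start, end)` in 1-based frames.
#'
#' @param speed end-effector linear speed (numeric vector).
#' @param distance distance of the end effector to the active trial target
#'   (numeric vector, NA outside trial windows).
#' @param trial_windows data.frame with `trial`, `start`, `end` (1-based
#'   half-open frame indices) — the task schedule.
#' @param rate sampling rate of `speed` in Hz (stored on the result).
#' @param speed_threshold_frac near-zero threshold as a fraction of the
#'   per-trial peak speed (default 0.05).
#' @param touch_tol distance (m) within which the target counts as touched.
#' @return data.frame of class `trial_segmentation` with columns `trial`,
#'   `fwd_start`, `fwd_end`, `bwd_start`, `bwd_end`, `window_start`,
#'   `window_end`, `valid`, `reason`; attribute `rate`.
#' @export
segment_trials <- function(speed, distance, trial_windows, rate,
                           speed_threshold_frac = 0.05, touch_tol = 0.05) {
  speed <- as.numeric(speed)
  distance <- as.numeric(distance)
  if (length(speed) != length(distance)) stop("series must be aligned")
  out <- lapply(seq_len(nrow(trial_windows)), function(i) {
    w0 <- trial_windows$start[i]
    w1 <- trial_windows$end[i] - 1L
    idx <- w0:w1
    sp <- speed[idx]
    di <- distance[idx]
    row <- data.frame(trial = trial_windows$trial[i],
                      fwd_start = NA_integer_, fwd_end = NA_integer_,
                      bwd_start = NA_integer_, bwd_end = NA_integer_,
                      window_start = w0, window_end = w1 + 1L,
                      valid = FALSE, reason = "no_touch")
    if (all(is.na(di)) || min(di, na.rm = TRUE) > touch_tol) return(row)
    thr <- speed_threshold_frac * max(sp)
    i_touch <- which.min(di)
    i_pk1 <- which.max(sp[1:i_touch])
    below <- sp < thr
    pre <- which(below[1:i_pk1])
    fwd_start <- if (length(pre)) max(pre) else 1L
    post <- which(below) ; post <- post[post >= i_pk1]
    if (!length(post)) { row$reason <- "no_segment"; return(row) }
    fwd_end <- min(post)
    if (fwd_end >= length(sp) - 2L) { row$reason <- "no_segment"; return(row) }
    rest <- fwd_end:length(sp)
    i_pk2 <- rest[which.max(sp[rest])]
    pre2 <- which(below[1:i_pk2]) ; pre2 <- pre2[pre2 >= fwd_end]
    bwd_start <- if (length(pre2)) max(pre2) else fwd_end
    post2 <- which(below) ; post2 <- post2[post2 >= i_pk2]
    if (!length(post2)) { row$reason <- "no_segment"; return(row) }
    bwd_end <- min(post2)
    row$fwd_start <- w0 + fwd_start - 1L
    row$fwd_end <- w0 + fwd_end - 1L
    row$bwd_start <- w0 + bwd_start - 1L
    row$bwd_end <- w0 + bwd_end - 1L
    row$valid <- TRUE
    row$reason <- "none"
    row
  })
  seg <- do.call(rbind, out)
  attr(seg, "rate") <- rate
  class(seg) <- c("trial_segmentation", "data.frame")
  seg
}

# intervals of one segment type from a segmentation, as a data.frame with
# start, end (half-open), valid
segment_intervals <- function(segmentation, segment) {
  if (segment == "forward") {
    data.frame(trial = segmentation$trial, start = segmentation$fwd_start,
               end = segmentation$fwd_end, valid = segmentation$valid)
  } else {
    data.frame(trial = segmentation$trial, start = segmentation$bwd_start,
               end = segmentation$bwd_end, valid = segmentation$valid)
  }
}

#' Flag trials containing single-frame sensor jumps
#'
#' Any trial whose window contains a frame-to-frame position displacement
#' larger than `max_pos_jump` on any sensor is marked invalid with reason
#' `"sensor_noise"`.
#'
#' @param rec a [kinematics_recording()].
#' @param seg a [segment_trials()] result.
#' @param max_pos_jump jump threshold in meters (default 0.10).
#' @return the segmentation with noisy trials invalidated.
#' @export
flag_noisy_trials <- function(rec, seg, max_pos_jump = 0.10) {
  stopifnot(inherits(rec, "kinematics_recording"))
  n <- length(rec$time)
  S <- length(rec$sensors)
  jump <- matrix(0, n - 1L, S)
  for (s in seq_len(S)) {
    d <- diff(rec$pos[, , s])
    jump[, s] <- sqrt(rowSums(d^2))
  }
  bad_frame <- which(apply(jump, 1L, max) > max_pos_jump)  # jump between f and f+1
  for (i in seq_len(nrow(seg))) {
    hit <- any(bad_frame >= seg$window_start[i] &
                 bad_frame < seg$window_end[i] - 1L)
    if (hit) {
      seg$valid[i] <- FALSE
      seg$reason[i] <- "sensor_noise"
    }
  }
  seg
}

#' Distance of one sensor to per-trial targets
#'
#' Builds a full-length distance series: within each trial window the
#' Euclidean distance of the sensor to that trial's target; NA elsewhere.
#'
#' @param rec a [kinematics_recording()].
#' @param sensor sensor label (typically the end effector).
#' @param trial_windows data.frame with `trial`, `start`, `end` and target
#'   coordinates `target_x`, `target_y`, `target_z`.
#' @return numeric vector, length = frames.
#' @export
distance_to_target <- function(rec, sensor, trial_windows) {
  s <- match(sensor, rec$sensors)
  if (is.na(s)) stop("unknown sensor: ", sensor)
  out <- rep(NA_real_, length(rec$time))
  for (i in seq_len(nrow(trial_windows))) {
    idx <- trial_windows$start[i]:(trial_windows$end[i] - 1L)
    tg <- c(trial_windows$target_x[i], trial_windows$target_y[i],
            trial_windows$target_z[i])
    d <- sweep(rec$pos[idx, , s, drop = TRUE], 2L, tg, "-")
    out[idx] <- sqrt(rowSums(d^2))
  }
  out
}

#' Export a trial segmentation as JSON
#'
#' Frame indices are written 0-based, half-open, matching the on-disk
#' session schema.
#'
#' @param seg a [segment_trials()] result.
#' @param path output file.
#' @export
write_segmentation_json <- function(seg, path) {
  recs <- lapply(seq_len(nrow(seg)), function(i) {
    list(trial_id = seg$trial[i],
         forward = c(seg$fwd_start[i] - 1L, seg$fwd_end[i] - 1L),
         backward = c(seg$bwd_start[i] - 1L, seg$bwd_end[i] - 1L),
         valid = seg$valid[i], reason = seg$reason[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
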