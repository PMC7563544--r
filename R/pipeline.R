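#' Map sensors to performing / non-performing / midline sides
#'
#' The performing set is the dominant-side scapula, upper arm, forearm and
#' hand-or-finger; the non-performing set is the mirror set; forehead and T7
#' are midline and excluded from side contrasts.
#'
#' @param body_parts character vector of sensor labels (with `_left` /
#'   `_right` suffixes) or a data.frame with a `sensor` column.
#' @param handedness `"right"` or `"left"`.
#' @return named character vector: side per sensor.
#' @export
assign_sides <- function(body_parts, handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  labels <- if (is.data.frame(body_parts)) body_parts$sensor else
    as.character(body_parts)
  suffix <- ifelse(grepl("_right$", labels), "right",
                   ifelse(grepl("_left$", labels), "left", "midline"))
  side <- ifelse(suffix == "midline", "midline",
                 ifelse(suffix == handedness, "performing", "nonperforming"))
  names(side) <- labels
  side
}

#' Run the full analysis pipeline on one session
#'
#' Derives linear speed and angular acceleration per sensor, segments trials
#' by the speed/distance criteria, flags noisy trials, extracts MMS per
#' (sensor, segment) and per (pair, segment), fits Gamma laws (NSR), builds
#' cross-correlation adjacency matrices and clustering coefficients per
#' segment, and computes heart-body connectivity (cross-correlation, lag,
#' EMD) on the band-passed ECG.
#'
#' @param session an `intent_session` (from [generate_session()] or
#'   [read_session()]).
#' @param min_spike_count minimum pooled spikes per Gamma fit (default 100).
#' @param max_lag cross-correlation lag window, seconds.
#' @param speed_threshold_frac segmentation near-zero threshold fraction.
#' @param max_pos_jump noisy-trial single-frame jump threshold, meters.
#' @param ecg_band band edges (Hz) for the ECG Butterworth filter.
#' @param filter_ecg set `FALSE` to run the heart analyses on the raw ECG.
#' @return object of class `intent_metrics`; see Details.
#' @details The result bundles `segmentation`, `nsr_nodes` (per sensor and
#'   segment), `nsr_pairs` (per sensor pair and segment), `adjacency` and
#'   `clustering` (per segment), `heart` (per sensor and segment:
#'   cross-correlation, signed lag with positive = ECG leads, EMD between
#'   MMS histograms), the side map and spike pools.
#' @export
analyze_session <- function(session, min_spike_count = 100L, max_lag = 1,
                            speed_threshold_frac = 0.05,
                            max_pos_jump = 0.10,
                            ecg_band = c(5, 30), filter_ecg = TRUE) {
  stopifnot(inherits(session, "intent_session"))
  kin <- session$kinematics
  rate <- kin$rate
  parts <- kin$sensors
  S <- length(parts)
  sides <- assign_sides(parts, session$config$handedness)
  ee <- parts[session$config$body_parts$role == "end_effector"]

  # --- derived kinematic series -------------------------------------------
  speeds <- vapply(seq_len(S), function(s)
    as.numeric(linear_speed(kin$pos[, , s], rate)), numeric(length(kin$time)))
  colnames(speeds) <- parts
  accel <- vapply(seq_len(S), function(s) {
    w <- angular_speed_from_quaternions(kin$quat[, , s], rate)
    abs(as.numeric(angular_acceleration(w, rate)))
  }, numeric(length(kin$time)))
  colnames(accel) <- parts

  # --- segmentation --------------------------------------------------------
  dist <- distance_to_target(kin, ee, session$schedule)
  seg <- segment_trials(speeds[, ee], dist, session$schedule, rate,
                        speed_threshold_frac = speed_threshold_frac)
  seg <- flag_noisy_trials(kin, seg, max_pos_jump = max_pos_jump)

  # --- MMS pools and Gamma fits -------------------------------------------
  pool_windows <- function(series, iv) {
    amps <- lapply(seq_len(nrow(iv)), function(i) {
      idx <- iv$start[i]:(iv$end[i] - 1L)
      if (length(idx) < 5L) return(numeric(0))
      standardize_peaks(series[idx])$amplitudes
    })
    unlist(amps)
  }
  segs <- c("forward", "backward")
  node_pool <- list()
  nsr_nodes <- list()
  for (sg in segs) {
    iv <- segment_intervals(seg, sg)
    iv <- iv[iv$valid, , drop = FALSE]
    for (s in seq_len(S)) {
      amps <- pool_windows(accel[, s], iv)
      node_pool[[paste(parts[s], sg, sep = ".")]] <- amps
      fit <- tryCatch(fit_gamma_mle(amps, min_count = min_spike_count),
                      error = function(e) NULL)
      nsr_nodes[[length(nsr_nodes) + 1L]] <- data.frame(
        sensor = parts[s], segment = sg, side = unname(sides[parts[s]]),
        shape = if (is.null(fit)) NA_real_ else fit$shape,
        nsr = if (is.null(fit)) NA_real_ else fit$nsr,
        n_spikes = length(amps))
    }
  }
  nsr_nodes <- do.call(rbind, nsr_nodes)

  pair_idx <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
  nsr_pairs <- list()
  for (sg in segs) {
    iv <- segment_intervals(seg, sg)
    iv <- iv[iv$valid, , drop = FALSE]
    for (p in seq_len(nrow(pair_idx))) {
      i <- pair_idx[p, 1L]; j <- pair_idx[p, 2L]
      amps <- pool_windows(pairwise_absdiff(accel[, i], accel[, j]), iv)
      fit <- tryCatch(fit_gamma_mle(amps, min_count = min_spike_count),
                      error = function(e) NULL)
      si <- sides[parts[i]]; sj <- sides[parts[j]]
      pside <- if (si == sj) unname(si) else "mixed"
      nsr_pairs[[length(nsr_pairs) + 1L]] <- data.frame(
        sensor_i = parts[i], sensor_j = parts[j], segment = sg,
        pair_side = pside,
        nsr = if (is.null(fit)) NA_real_ else fit$nsr,
        n_spikes = length(amps))
    }
  }
  nsr_pairs <- do.call(rbind, nsr_pairs)

  # --- body-body network ---------------------------------------------------
  adjacency <- lapply(segs, function(sg)
    build_adjacency(speeds, rate, seg, sg, max_lag = max_lag))
  names(adjacency) <- segs
  clustering <- do.call(rbind, lapply(segs, function(sg) {
    cc <- clustering_coefficients(adjacency[[sg]])
    cc$segment <- sg
    cc$side <- unname(sides[cc$node])
    cc
  }))

  # --- heart-body network --------------------------------------------------
  ecg_f <- if (filter_ecg)
    bandpass_ecg(session$ecg, ecg_band[1], ecg_band[2]) else session$ecg
  if (!filter_ecg) ecg_f$filtered <- TRUE  # sensitivity re-analysis path
  kin256 <- resample_kinematics(kin, ecg_f$rate)
  speeds256 <- vapply(seq_len(S), function(s)
    as.numeric(linear_speed(kin256$pos[, , s], kin256$rate)),
    numeric(length(kin256$time)))
  colnames(speeds256) <- parts
  ecg_abs <- abs(ecg_f$mv)
  heart <- list()
  for (sg in segs) {
    iv <- segment_intervals(seg, sg)
    iv <- iv[iv$valid, , drop = FALSE]
    iv256 <- data.frame(trial = iv$trial,
                        start = round((iv$start - 1L) / rate * ecg_f$rate) + 1L,
                        end = round((iv$end - 1L) / rate * ecg_f$rate) + 1L,
                        valid = TRUE)
    ecg_amps <- unlist(lapply(seq_len(nrow(iv256)), function(i) {
      idx <- iv256$start[i]:min(iv256$end[i] - 1L, length(ecg_abs))
      if (length(idx) < 5L) return(numeric(0))
      standardize_peaks(ecg_abs[idx])$amplitudes
    }))
    body_amps <- node_pool[paste(parts, sg, sep = ".")]
    names(body_amps) <- parts
    hb <- heart_body_connectivity(ecg_f, speeds256, kin256$rate, seg, sg,
                                  max_lag = max_lag,
                                  body_mms = body_amps, ecg_mms = ecg_amps,
                                  min_count = min_spike_count)
    hb$segment <- sg
    hb$side <- unname(sides[hb$sensor])
    heart[[sg]] <- hb
  }
  heart <- do.call(rbind, heart)

  structure(list(segmentation = seg, nsr_nodes = nsr_nodes,
                 nsr_pairs = nsr_pairs, adjacency = adjacency,
                 clustering = clustering, heart = heart, sides = sides,
                 end_effector = ee,
                 n_valid_trials = sum(seg$valid),
                 spike_pool = node_pool),
            class = "intent_metrics")
}

#' @export
print.intent_metrics <- function(x, ...) {
  cat(sprintf("<intent_metrics> %d valid trials; median NSR fwd %.4g / bwd %.4g\n",
              x$n_valid_trials,
              stats::median(x$nsr_nodes$nsr[x$nsr_nodes$segment == "forward"],
                            na.rm = TRUE),
              stats::median(x$nsr_nodes$nsr[x$nsr_nodes$segment == "backward"],
                            na.rm = TRUE)))
  invisible(x)
}
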