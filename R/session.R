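#' Generate a full synthetic session
#'
#' Concatenates `n_trials` pointing trials (with inter-trial rest built into
#' each fragment), composes the orientation chain so quaternions are
#' continuous across trial boundaries, and generates a matching ECG.  The
#' returned ground truth records the injected forward/backward intervals,
#' Gamma laws and heart leads.
#'
#' @param config a [session_config()].
#' @return object of class `intent_session`: list with `kinematics`
#'   ([kinematics_recording()]), `ecg` (raw [ecg_recording()]),
#'   `ground_truth` (data.frame of per-trial intervals, 1-based half-open
#'   frames, plus injected parameters as attributes), `schedule`
#'   (data.frame of trial windows and targets — what the experimenter would
#'   know), and `config`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  rate <- config$frame_rate_kin
  parts <- config$body_parts
  S <- nrow(parts)
  nt <- config$n_trials

  frags <- lapply(seq_len(nt) - 1L, function(i)
    generate_trial_kinematics(config, i))
  n_fr <- frags[[1L]]$n_frames
  total <- n_fr * nt
  pos <- array(NA_real_, c(total, 3L, S))
  quat <- array(NA_real_, c(total, 4L, S))
  gt <- vector("list", nt)
  sched <- vector("list", nt)
  q_carry <- matrix(rep(c(1, 0, 0, 0), S), nrow = S, byrow = TRUE)
  for (i in seq_len(nt)) {
    off <- (i - 1L) * n_fr
    idx <- off + seq_len(n_fr)
    pos[idx, , ] <- frags[[i]]$pos
    for (s in seq_len(S)) {
      qf <- quat_multiply(matrix(q_carry[s, ], n_fr, 4L, byrow = TRUE),
                          frags[[i]]$quat[, , s])
      quat[idx, , s] <- qf
      q_carry[s, ] <- qf[n_fr, ]
    }
    g <- frags[[i]]$gt
    gt[[i]] <- data.frame(trial = i,
                          fwd_start = off + g$forward[1],
                          fwd_end = off + g$forward[2],
                          bwd_start = off + g$backward[1],
                          bwd_end = off + g$backward[2])
    sched[[i]] <- data.frame(trial = i, start = off + 1L,
                             end = off + n_fr + 1L,
                             target_x = frags[[i]]$target[1],
                             target_y = frags[[i]]$target[2],
                             target_z = frags[[i]]$target[3])
  }
  gt <- do.call(rbind, gt)
  sched <- do.call(rbind, sched)
  time <- (0:(total - 1L)) / rate
  kin <- kinematics_recording(time, pos, quat, parts$sensor, rate)

  offset <- config$clock_offset_s
  if (identical(offset, "random")) {
    set.seed(trial_seed(config$seed, -3L, stream = 29L))
    offset <- stats::runif(1, -1, 1)
  }
  bounds <- data.frame(fwd_onset = (gt$fwd_start - 1L) / rate,
                       fwd_dur = (gt$fwd_end - gt$fwd_start) / rate,
                       bwd_onset = (gt$bwd_start - 1L) / rate,
                       bwd_dur = (gt$bwd_end - gt$bwd_start) / rate)
  ecg <- generate_ecg(config, bounds, total / rate, clock_offset_s = offset)

  attr(gt, "gamma_params") <- config$gamma_params
  attr(gt, "heart_lead_ms") <- config$heart_lead_ms
  attr(gt, "clock_offset_s") <- offset
  structure(list(kinematics = kin, ecg = ecg, ground_truth = gt,
                 schedule = sched, config = config),
            class = "intent_session")
}

#' @export
print.intent_session <- function(x, ...) {
  cat(sprintf("<intent_session> %d trials, %d frames kinematics, %d ECG samples\n",
              x$config$n_trials, length(x$kinematics$time), length(x$ecg$mv)))
  invisible(x)
}

#' Write / read a session in the on-disk CSV schema
#'
#' `kinematics.csv` holds one row per (frame, sensor): `time_s, sensor_id,
#' x_m, y_m, z_m, qw, qx, qy, qz`.  `ecg.csv` holds `time_s, mv`.
#' `schedule.csv` holds the trial windows and targets (0-based half-open
#' frames on disk), `ground_truth.json` the injected intervals, and
#' `config.yaml` the generating configuration.
#'
#' @param session an [generate_session()] result.
#' @param dir output directory (created if missing).
#' @return `read_session(dir)` returns an `intent_session` (ground truth and
#'   config included when present).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kin <- session$kinematics
  S <- length(kin$sensors)
  n <- length(kin$time)
  kd <- data.frame(
    time_s = rep(kin$time, S),
    sensor_id = rep(kin$sensors, each = n),
    x_m = as.vector(kin$pos[, 1, ]), y_m = as.vector(kin$pos[, 2, ]),
    z_m = as.vector(kin$pos[, 3, ]),
    qw = as.vector(kin$quat[, 1, ]), qx = as.vector(kin$quat[, 2, ]),
    qy = as.vector(kin$quat[, 3, ]), qz = as.vector(kin$quat[, 4, ]))
  utils::write.csv(kd, file.path(dir, "kinematics.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = session$ecg$time, mv = session$ecg$mv),
                   file.path(dir, "ecg.csv"), row.names = FALSE)
  sched <- session$schedule
  sched$start <- sched$start - 1L
  sched$end <- sched$end - 1L
  utils::write.csv(sched, file.path(dir, "schedule.csv"), row.names = FALSE)
  gt <- session$ground_truth
  jsonlite::write_json(
    list(trials = lapply(seq_len(nrow(gt)), function(i)
      list(trial_id = gt$trial[i],
           forward = c(gt$fwd_start[i] - 1L, gt$fwd_end[i] - 1L),
           backward = c(gt$bwd_start[i] - 1L, gt$bwd_end[i] - 1L))),
      heart_lead_ms = as.list(attr(gt, "heart_lead_ms")),
      clock_offset_s = attr(gt, "clock_offset_s")),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  write_session_config(session$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  cfg <- read_session_config(file.path(dir, "config.yaml"))
  kd <- utils::read.csv(file.path(dir, "kinematics.csv"))
  sensors <- unique(kd$sensor_id)
  n <- sum(kd$sensor_id == sensors[1])
  S <- length(sensors)
  pos <- array(NA_real_, c(n, 3L, S))
  quat <- array(NA_real_, c(n, 4L, S))
  for (s in seq_len(S)) {
    rows <- kd[kd$sensor_id == sensors[s], ]
    pos[, , s] <- as.matrix(rows[, c("x_m", "y_m", "z_m")])
    quat[, , s] <- as.matrix(rows[, c("qw", "qx", "qy", "qz")])
  }
  kin <- kinematics_recording(kd$time_s[kd$sensor_id == sensors[1]],
                              pos, quat, sensors, cfg$frame_rate_kin)
  ed <- utils::read.csv(file.path(dir, "ecg.csv"))
  ecg <- ecg_recording(ed$time_s, ed$mv, cfg$frame_rate_ecg)
  sched <- utils::read.csv(file.path(dir, "schedule.csv"))
  sched$start <- sched$start + 1L
  sched$end <- sched$end + 1L
  gt <- NULL
  gtp <- file.path(dir, "ground_truth.json")
  if (file.exists(gtp)) {
    gj <- jsonlite::read_json(gtp, simplifyVector = TRUE)
    gt <- data.frame(trial = gj$trials$trial_id,
                     fwd_start = sapply(gj$trials$forward, `[`, 1) + 1L,
                     fwd_end = sapply(gj$trials$forward, `[`, 2) + 1L,
                     bwd_start = sapply(gj$trials$backward, `[`, 1) + 1L,
                     bwd_end = sapply(gj$trials$backward, `[`, 2) + 1L)
    attr(gt, "heart_lead_ms") <- unlist(gj$heart_lead_ms)
    attr(gt, "clock_offset_s") <- gj$clock_offset_s
  }
  structure(list(kinematics = kin, ecg = ecg, ground_truth = gt,
                 schedule = sched, config = cfg),
            class = "intent_session")
}
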