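#' Default upper-body sensor layout
#'
#' Ten labeled sensors: forehead and T7 on the midline, scapula / upper arm /
#' forearm on both sides, the non-performing hand and the performing hand's
#' index finger (the end effector).  Labels carry a `_left` / `_right`
#' suffix except for the midline pair.
#'
#' @param handedness `"right"` or `"left"` (the performing side).
#' @return data.frame with `sensor`, `side` (performing / nonperforming /
#'   midline), `role`, `attenuation` (fraction of the reach displacement the
#'   sensor carries in the synthetic generator).
#' @export
default_body_parts <- function(handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  dom <- handedness
  off <- setdiff(c("left", "right"), dom)
  parts <- data.frame(
    sensor = c("forehead", "t7",
               paste0("scapula_", dom), paste0("scapula_", off),
               paste0("upper_arm_", dom), paste0("upper_arm_", off),
               paste0("forearm_", dom), paste0("forearm_", off),
               paste0("index_", dom), paste0("hand_", off)),
    side = c("midline", "midline",
             "performing", "nonperforming",
             "performing", "nonperforming",
             "performing", "nonperforming",
             "performing", "nonperforming"),
    role = c("head", "trunk", "scapula", "scapula", "upper_arm", "upper_arm",
             "forearm", "forearm", "end_effector", "hand"),
    attenuation = c(0.12, 0.10, 0.25, 0.25, 0.45, 0.45, 0.70, 0.70,
                    1.00, 0.85)
  )
  parts
}

#' Configuration of a synthetic pointing session
#'
#' Defines the recording conditions the generator emulates: 180 pointing
#' trials,
#' kinematics at 240 Hz from 10 upper-body sensors, lead-II ECG at 256 Hz.
#' Each trial holds a deliberate forward reach (bell-shaped speed, monotone
#' decreasing distance to the target) and a spontaneous backward retraction
#' with larger speed fluctuations.  Micro-movement spike amplitudes of the
#' angular-acceleration waveform follow configurable Gamma laws per
#' (segment, side); the ECG carries an in-band oscillatory modulation
#' time-locked to each movement segment and offset by a configurable
#' per-segment heart lead.
#'
#' @param n_trials number of pointing trials (default 180).
#' @param frame_rate_kin kinematics rate, Hz (default 240).
#' @param frame_rate_ecg ECG rate, Hz (default 256).
#' @param handedness performing side, `"right"` or `"left"`.
#' @param body_parts sensor table, see [default_body_parts()].
#' @param gamma_params data.frame (segment, side, shape, scale): target
#'   Gamma law of the MMS amplitudes of angular acceleration per cell.
#'   Defaults encode higher noise-to-signal ratio (scale) for forward
#'   segments and for the performing side.
#' @param heart_rate beats per minute (default 70).
#' @param heart_lead_ms named vector (forward, backward): signed offset of
#'   the ECG modulation relative to movement onset; positive = heart
#'   precedes movement.  Defaults: heart leads forward reaches, lags
#'   backward retractions.
#' @param coupling named vector (forward, backward) in \[0, 1\]: strength of
#'   the common drive shared across body parts per segment.
#' @param side_coupling named vector (performing, midline, nonperforming):
#'   per-side multiplier on the common drive.
#' @param follower_delay_ms named vector (performing, midline,
#'   nonperforming): signed delay of each side's coupled motion relative to
#'   the end effector; negative values are anticipatory (supporting body
#'   parts adjust posture before the reach, so their kinematics lead).
#' @param speed_jitter named vector (forward, backward): sd of the smooth
#'   multiplicative fluctuation on the segment speed profile (backward
#'   larger: retractions are more variable).
#' @param noise_sd sd of the band-limited position measurement noise,
#'   meters.
#' @param mod_depth amplitude of the movement-locked in-band ECG modulation
#'   (mV).
#' @param mod_freq_hz carrier frequency of that modulation (inside the
#'   5-30 Hz analysis band).
#' @param ecg_noise_sd sd of additive ECG noise, mV.
#' @param clock_offset_s offset of the ECG time base relative to the
#'   kinematics: a number in (-1, 1), or `"random"` to draw one uniformly
#'   from (-1, 1) per session.
#' @param accel_floor valley level of the angular-acceleration oscillation,
#'   deg/s^2.
#' @param spike_half_period_frames half-width in frames of one
#'   angular-acceleration arc (default 8 at 240 Hz).
#' @param spike_shelf_frames frames of valley shelf separating consecutive
#'   arcs (default 7); must exceed the reach of the discrete-derivative
#'   kernel so each recovered spike depends only on its own arc.
#' @param durations named vector of within-trial phase durations in seconds
#'   (pre, forward, dwell, backward, post).
#' @param reach_distance nominal reach amplitude, meters.
#' @param target_jitter half-range of the per-trial target displacement, m.
#' @param seed integer seed; the whole session is a deterministic function
#'   of the configuration.
#' @return validated list of class `session_config`.
#' @export
session_config <- function(n_trials = 180L,
                           frame_rate_kin = 240,
                           frame_rate_ecg = 256,
                           handedness = c("right", "left"),
                           body_parts = NULL,
                           gamma_params = NULL,
                           heart_rate = 70,
                           heart_lead_ms = c(forward = 150, backward = -90),
                           coupling = c(forward = 0.9, backward = 0.55),
                           side_coupling = c(performing = 1, midline = 0.7,
                                             nonperforming = 0.45),
                           follower_delay_ms = c(performing = 0,
                                                 midline = -120,
                                                 nonperforming = -250),
                           speed_jitter = c(forward = 0.05, backward = 0.12),
                           noise_sd = 5e-4,
                           mod_depth = 0.8,
                           mod_freq_hz = 18,
                           ecg_noise_sd = 0.005,
                           clock_offset_s = 0,
                           accel_floor = 100,
                           spike_half_period_frames = 8L,
                           spike_shelf_frames = 7L,
                           durations = c(pre = 0.4, forward = 0.7,
                                         dwell = 0.3, backward = 0.6,
                                         post = 0.5),
                           reach_distance = 0.45,
                           target_jitter = 0.07,
                           seed = 1L) {
  handedness <- match.arg(handedness)
  if (is.null(body_parts)) body_parts <- default_body_parts(handedness)
  if (is.null(gamma_params)) gamma_params <- default_gamma_params()
  cfg <- list(n_trials = as.integer(n_trials),
              frame_rate_kin = frame_rate_kin,
              frame_rate_ecg = frame_rate_ecg,
              handedness = handedness, body_parts = body_parts,
              gamma_params = gamma_params, heart_rate = heart_rate,
              heart_lead_ms = heart_lead_ms, coupling = coupling,
              side_coupling = side_coupling,
              follower_delay_ms = follower_delay_ms,
              speed_jitter = speed_jitter, noise_sd = noise_sd,
              mod_depth = mod_depth, mod_freq_hz = mod_freq_hz,
              ecg_noise_sd = ecg_noise_sd, clock_offset_s = clock_offset_s,
              accel_floor = accel_floor,
              spike_half_period_frames = as.integer(spike_half_period_frames),
              spike_shelf_frames = as.integer(spike_shelf_frames),
              durations = durations, reach_distance = reach_distance,
              target_jitter = target_jitter, seed = as.integer(seed))
  validate_session_config(cfg)
  structure(cfg, class = "session_config")
}

#' Default Gamma laws for synthetic MMS amplitudes
#'
#' Standardized spike amplitudes are bounded below by 1/2 (a peak always
#' exceeds the mean of its flanking valleys), so the laws concentrate in
#' (0.5, 1).  Cell-specific means and shapes encode the injected ordering:
#' scale (NSR = mean / shape) is higher for forward segments than backward
#' and higher on the performing side than the non-performing one, with the
#' performing side also more dispersed (lower shape) so that
#' pairwise-difference waveforms inherit the side contrast.
#'
#' @return data.frame with `segment`, `side`, `shape`, `scale`.
#' @export
default_gamma_params <- function() {
  means <- c(forward.performing = 0.70, forward.midline = 0.66,
             forward.nonperforming = 0.64, backward.performing = 0.62,
             backward.midline = 0.58, backward.nonperforming = 0.56)
  shapes <- c(forward.performing = 260, forward.midline = 400,
              forward.nonperforming = 640, backward.performing = 260,
              backward.midline = 400, backward.nonperforming = 640)
  cells <- do.call(rbind, strsplit(names(means), ".", fixed = TRUE))
  data.frame(segment = cells[, 1], side = cells[, 2],
             shape = unname(shapes),
             scale = unname(means) / unname(shapes))
}

validate_session_config <- function(cfg) {
  stopifnot(cfg$n_trials >= 1L,
            cfg$frame_rate_kin > 0, cfg$frame_rate_ecg > 0,
            cfg$heart_rate > 0,
            all(cfg$gamma_params$shape > 0),
            all(cfg$gamma_params$scale > 0),
            all(cfg$coupling >= 0), all(cfg$coupling <= 1),
            cfg$noise_sd >= 0, cfg$accel_floor > 0,
            cfg$spike_half_period_frames >= 4L,
            cfg$spike_shelf_frames >= 3L,
            all(cfg$durations > 0))
  if (!identical(cfg$clock_offset_s, "random") &&
      abs(as.numeric(cfg$clock_offset_s)) >= 1)
    stop("clock_offset_s must lie in (-1, 1) or be \"random\"")
  ee <- cfg$body_parts$role == "end_effector"
  if (sum(ee) != 1L || cfg$body_parts$side[ee] != "performing")
    stop("exactly one end-effector sensor on the performing side is required")
  mean_amp <- cfg$gamma_params$shape * cfg$gamma_params$scale
  if (any(mean_amp <= 0.5) || any(mean_amp >= 1))
    stop("gamma_params must place the MMS amplitude mean inside (0.5, 1)")
  invisible(cfg)
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(paste0("<session_config> %d trials, kin %g Hz / ecg %g Hz, ",
                     "%s-handed, seed %d\n"),
              x$n_trials, x$frame_rate_kin, x$frame_rate_ecg, x$handedness,
              x$seed))
  invisible(x)
}

#' Read / write a session configuration as YAML
#'
#' @param cfg a [session_config()].
#' @param path file path.
#' @return `read_session_config` returns a [session_config()].
#' @export
write_session_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$body_parts <- as.list(lst$body_parts)
  lst$gamma_params <- as.list(lst$gamma_params)
  # named vectors must be written as YAML maps to keep their names
  for (nm in c("heart_lead_ms", "coupling", "side_coupling",
               "follower_delay_ms", "speed_jitter", "durations"))
    lst[[nm]] <- as.list(lst[[nm]])
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_session_config
#' @export
read_session_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$body_parts <- as.data.frame(lst$body_parts)
  lst$gamma_params <- as.data.frame(lst$gamma_params)
  for (nm in c("heart_lead_ms", "coupling", "side_coupling",
               "follower_delay_ms", "speed_jitter", "durations"))
    lst[[nm]] <- unlist(lst[[nm]])
  do.call(session_config, lst)
}
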