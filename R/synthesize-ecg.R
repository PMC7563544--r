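#' Generate a synthetic single-lead ECG for a session
#'
#' A template QRS train (Gaussian R bump with a small S dip) at the
#' configured heart rate, plus a movement-locked modulation: around every
#' segment onset an in-band (default 18 Hz) oscillatory burst whose
#' amplitude profile spans the segment duration, shifted in time by the
#' configured per-segment heart lead.  A positive lead places the burst
#' before the movement, so the ECG envelope precedes the kinematics.
#'
#' @param config a [session_config()].
#' @param trial_boundaries data.frame with `fwd_onset`, `fwd_dur`,
#'   `bwd_onset`, `bwd_dur` in seconds (kinematics clock); rows sorted and
#'   non-overlapping.
#' @param total_dur total duration in seconds.
#' @param clock_offset_s offset of the ECG clock relative to the kinematics
#'   clock (events at kinematics time t appear at ECG index t + offset).
#' @return an [ecg_recording()] at `frame_rate_ecg`.
#' @export
generate_ecg <- function(config, trial_boundaries, total_dur,
                         clock_offset_s = 0) {
  stopifnot(inherits(config, "session_config"))
  if (config$heart_rate <= 20 || config$heart_rate >= 250)
    stop("heart_rate must lie in (20, 250) bpm")
  ons <- c(trial_boundaries$fwd_onset, trial_boundaries$bwd_onset)
  if (is.unsorted(trial_boundaries$fwd_onset) ||
      any(trial_boundaries$bwd_onset < trial_boundaries$fwd_onset))
    stop("trial boundaries must be sorted and non-overlapping")
  rate <- config$frame_rate_ecg
  n <- floor(total_dur * rate) + 1L
  tt <- (0:(n - 1L)) / rate
  set.seed(trial_seed(config$seed, -2L, stream = 13L))

  # movement-locked modulation envelope (ECG clock)
  env <- numeric(n)
  add_bump <- function(env, onset, dur, lead_s) {
    a <- onset - lead_s + clock_offset_s
    i0 <- max(1L, floor(a * rate) + 1L)
    i1 <- min(n, ceiling((a + dur) * rate) + 1L)
    if (i1 <= i0) return(env)
    tau <- (tt[i0:i1] - a) / dur
    tau <- pmin(pmax(tau, 0), 1)
    # same bell shape as a minimum-jerk speed profile, so the burst mirrors
    # the movement it is locked to (peak normalized to 1)
    env[i0:i1] <- env[i0:i1] + 16 * tau^2 * (1 - tau)^2
    env
  }
  lead <- config$heart_lead_ms / 1000
  for (i in seq_len(nrow(trial_boundaries))) {
    env <- add_bump(env, trial_boundaries$fwd_onset[i],
                    trial_boundaries$fwd_dur[i], lead["forward"])
    env <- add_bump(env, trial_boundaries$bwd_onset[i],
                    trial_boundaries$bwd_dur[i], lead["backward"])
  }

  # QRS train
  ibi <- 60 / config$heart_rate
  beats <- seq(0.3, total_dur, by = ibi)
  mv <- numeric(n)
  half <- round(0.08 * rate)
  for (b in beats) {
    ic <- round(b * rate) + 1L
    i0 <- max(1L, ic - half)
    i1 <- min(n, ic + half)
    ts <- tt[i0:i1] - b
    amp <- 1 + 0.3 * env[min(n, max(1L, ic))]
    mv[i0:i1] <- mv[i0:i1] + amp * (exp(-ts^2 / (2 * 0.012^2)) -
                                      0.2 * exp(-(ts - 0.035)^2 / (2 * 0.015^2)))
  }

  mv <- mv + config$mod_depth * env * sin(2 * pi * config$mod_freq_hz * tt)
  if (config$ecg_noise_sd > 0)
    mv <- mv + stats::rnorm(n, 0, config$ecg_noise_sd)
  ecg_recording(tt, mv, rate)
}
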