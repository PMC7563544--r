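test_that("trial and session generation are bitwise deterministic", {
  cfg <- session_config(n_trials = 3, seed = 99)
  f1 <- generate_trial_kinematics(cfg, 1L)
  f2 <- generate_trial_kinematics(cfg, 1L)
  expect_identical(f1, f2)
  f3 <- generate_trial_kinematics(cfg, 2L)
  expect_false(identical(f1$pos, f3$pos))
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$kinematics$pos, s2$kinematics$pos)
  expect_identical(s1$ecg$mv, s2$ecg$mv)
  expect_error(generate_trial_kinematics(cfg, 3L), "out of range")
})

test_that("session counts and ground-truth structure", {
  cfg <- session_config(n_trials = 5, seed = 17)
  ses <- generate_session(cfg)
  gt <- ses$ground_truth
  expect_equal(nrow(gt), 5L)
  # one forward and one backward interval per trial, in order, non-overlap
  expect_true(all(gt$fwd_start < gt$fwd_end))
  expect_true(all(gt$fwd_end <= gt$bwd_start))
  expect_true(all(gt$bwd_start < gt$bwd_end))
  expect_true(all(diff(gt$fwd_start) > 0))
  # single-trial session
  ses1 <- generate_session(session_config(n_trials = 1, seed = 17))
  expect_equal(nrow(ses1$ground_truth), 1L)
  # 10 sensors with exactly one end effector on the performing side
  expect_length(ses$kinematics$sensors, 10L)
  expect_equal(sum(cfg$body_parts$role == "end_effector"), 1L)
})

test_that("config validation catches bad inputs", {
  expect_error(session_config(n_trials = 0), "n_trials")
  expect_error(session_config(clock_offset_s = 1.5), "clock_offset")
  gp <- default_gamma_params()
  gp$scale <- -gp$scale
  expect_error(session_config(gamma_params = gp))
  gp2 <- default_gamma_params()
  gp2$scale <- 2 / gp2$shape  # mean 2: not a standardized amplitude
  expect_error(session_config(gamma_params = gp2), "inside \\(0.5, 1\\)")
})

test_that("forward profile is unimodal with monotone target approach", {
  cfg <- session_config(n_trials = 3, seed = 7, noise_sd = 0,
                        speed_jitter = c(forward = 0, backward = 0))
  ses <- generate_session(cfg)
  kin <- ses$kinematics
  ee <- which(kin$sensors == "index_right")
  sp <- as.numeric(linear_speed(kin$pos[, , ee], kin$rate))
  di <- distance_to_target(kin, "index_right", ses$schedule)
  gt <- ses$ground_truth
  for (i in 1:3) {
    idx <- gt$fwd_start[i]:(gt$fwd_end[i] - 1L)
    ext <- find_peaks_valleys(sp[idx])
    expect_lte(length(ext$maxima), 1)          # unimodal bell
    expect_true(all(diff(di[idx]) < 1e-9))     # distance decreases to contact
  }
  # with default multiplicative jitter the approach is still monotone
  cfg2 <- session_config(n_trials = 2, seed = 7, noise_sd = 0)
  ses2 <- generate_session(cfg2)
  di2 <- distance_to_target(ses2$kinematics, "index_right", ses2$schedule)
  gt2 <- ses2$ground_truth
  idx <- gt2$fwd_start[1]:(gt2$fwd_end[1] - 1L)
  expect_true(all(diff(di2[idx]) < 1e-9))
})

test_that("backward speed fluctuations exceed forward when configured 2x", {
  cfg <- session_config(n_trials = 100, seed = 13, noise_sd = 0,
                        speed_jitter = c(forward = 0.06, backward = 0.12))
  rate <- cfg$frame_rate_kin
  wins <- vapply(0:99, function(i) {
    fr <- generate_trial_kinematics(cfg, i)
    ee <- which(cfg$body_parts$role == "end_effector")
    sp <- as.numeric(linear_speed(fr$pos[, , ee], rate))
    resid_var <- function(bounds) {
      idx <- bounds[1]:(bounds[2] - 1L)
      y <- sp[idx]
      fit <- stats::smooth.spline(seq_along(y), y, df = 5)
      r <- y - stats::fitted(fit)
      stats::var(r / max(y))  # relative fluctuation about the smooth bell
    }
    resid_var(fr$gt$backward) > resid_var(fr$gt$forward)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("zero coupling decorrelates the contralateral hand", {
  cfg <- session_config(n_trials = 100, seed = 23,
                        coupling = c(forward = 0, backward = 0))
  ses <- generate_session(cfg)
  kin <- ses$kinematics
  sp_ee <- as.numeric(linear_speed(kin$pos[, , which(kin$sensors == "index_right")],
                                   kin$rate))
  sp_hand <- as.numeric(linear_speed(kin$pos[, , which(kin$sensors == "hand_left")],
                                     kin$rate))
  r <- max_xcorr(sp_ee, sp_hand, kin$rate, max_lag = 1)
  expect_lte(r$coefficient, 0.2)
})

test_that("ECG beat train is strictly periodic without modulation", {
  cfg <- session_config(n_trials = 2, seed = 3, mod_depth = 0,
                        ecg_noise_sd = 0, heart_rate = 72)
  ses <- generate_session(cfg)
  pk <- find_peaks_valleys(ses$ecg$mv)$maxima
  pk <- pk[ses$ecg$mv[pk] > 0.5]  # R peaks
  ibi <- diff(pk) / ses$ecg$rate
  expect_lte(max(abs(ibi - 60 / 72)), 1 / ses$ecg$rate)
  expect_error(generate_ecg(session_config(heart_rate = 10),
                            data.frame(), 10), "heart_rate")
})

test_that("injected heart lead appears in the modulation envelope timing", {
  cfg <- session_config(n_trials = 10, seed = 29, ecg_noise_sd = 0,
                        heart_lead_ms = c(forward = 150, backward = -150))
  ses <- generate_session(cfg)
  gt <- ses$ground_truth
  rate <- 256
  # oracle: rebuild the modulation bump train from ground truth, without lead
  tt <- ses$ecg$time
  bump <- function(onsets, durs) {
    env <- numeric(length(tt))
    for (i in seq_along(onsets)) {
      sel <- tt >= onsets[i] & tt <= onsets[i] + durs[i]
      tau <- (tt[sel] - onsets[i]) / durs[i]
      env[sel] <- env[sel] + 0.5 * (1 - cos(2 * pi * tau))
    }
    env
  }
  fwd_env <- bump((gt$fwd_start - 1) / 240, (gt$fwd_end - gt$fwd_start) / 240)
  # isolate the generated modulation by regenerating without it
  cfg0 <- session_config(n_trials = 10, seed = 29, ecg_noise_sd = 0,
                         mod_depth = 0,
                         heart_lead_ms = c(forward = 150, backward = -150))
  ses0 <- generate_session(cfg0)
  carrier_env <- ecg_envelope(abs(ses$ecg$mv - ses0$ecg$mv), rate = rate,
                              smooth_s = 0.1)
  r <- max_xcorr(carrier_env, fwd_env, rate, max_lag = 0.6)
  expect_lt(abs(r$lag - 0.150), 2 / 256)
})

test_that("MMS Gamma law is recovered from generated orientation data", {
  cfg <- session_config(n_trials = 130, seed = 37)
  ses <- generate_session(cfg)
  kin <- ses$kinematics
  gt <- ses$ground_truth
  sides <- assign_sides(kin$sensors, cfg$handedness)
  amps <- c()
  for (s in which(sides == "performing")) {
    w <- angular_speed_from_quaternions(kin$quat[, , s], kin$rate)
    a <- abs(as.numeric(angular_acceleration(w, kin$rate)))
    for (i in seq_len(nrow(gt)))
      amps <- c(amps,
                standardize_peaks(a[gt$fwd_start[i]:(gt$fwd_end[i] - 1L)])$amplitudes)
  }
  expect_gte(length(amps), 2500)
  f <- fit_gamma_mle(amps)
  gp <- cfg$gamma_params
  row <- gp[gp$segment == "forward" & gp$side == "performing", ]
  expect_true(f$ci95_shape[1] < row$shape && row$shape < f$ci95_shape[2])
  expect_true(f$ci95_scale[1] < row$scale && row$scale < f$ci95_scale[2])
})

test_that("session round-trips through the CSV schema", {
  cfg <- session_config(n_trials = 2, seed = 43)
  ses <- generate_session(cfg)
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  expect_true(all(file.exists(file.path(dir,
    c("kinematics.csv", "ecg.csv", "schedule.csv", "ground_truth.json",
      "config.yaml")))))
  back <- read_session(dir)
  expect_equal(back$kinematics$pos, ses$kinematics$pos, tolerance = 1e-9)
  expect_equal(back$ecg$mv, ses$ecg$mv, tolerance = 1e-9)
  expect_equal(back$ground_truth$fwd_start, ses$ground_truth$fwd_start)
  expect_equal(back$config$seed, cfg$seed)
})
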