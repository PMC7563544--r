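make_kin <- function(pos_fun, n = 2400, rate = 240, S = 1) {
  tt <- (0:(n - 1)) / rate
  pos <- array(0, c(n, 3, S))
  quat <- array(0, c(n, 4, S))
  for (s in seq_len(S)) {
    pf <- pos_fun(tt)
    if (NROW(pf) == 1L) pf <- matrix(pf, n, 3, byrow = TRUE)
    pos[, , s] <- pf
    quat[, 1, s] <- 1
  }
  kinematics_recording(tt, pos, quat, paste0("s", seq_len(S)), rate)
}

test_that("spline resampling matches analytic signals", {
  # constant channel stays constant
  rec <- make_kin(function(tt) cbind(0.25, -0.1, 0.4))
  out <- resample_kinematics(rec, 256)
  expect_equal(out$rate, 256)
  expect_equal(as.vector(out$pos[, 1, 1]), rep(0.25, length(out$time)))
  # 5 Hz sine, 10 s at 240 Hz -> 256 Hz within 1e-3 of the analytic sine
  rec <- make_kin(function(tt) cbind(sin(2 * pi * 5 * tt), 0, 0))
  out <- resample_kinematics(rec, 256)
  interior <- 10:(length(out$time) - 10)
  err <- abs(out$pos[interior, 1, 1] - sin(2 * pi * 5 * out$time[interior]))
  expect_lt(max(err), 1e-3)
  # band-limited mean preserved to high accuracy
  expect_lt(abs(mean(out$pos[interior, 1, 1]) -
                  mean(sin(2 * pi * 5 * out$time[interior]))), 1e-6)
})

test_that("resampled length follows the rate ratio within one sample", {
  rec <- make_kin(function(tt) cbind(tt, 0, 0), n = 240)
  out <- resample_kinematics(rec, 256)
  expect_lte(abs(length(out$time) - round(240 * 256 / 240)), 1)
  expect_error(resample_kinematics(make_kin(function(tt) cbind(tt, 0, 0),
                                            n = 3), 256),
               "insufficient")
})

test_that("resampling renormalizes quaternions", {
  n <- 1000; rate <- 240
  tt <- (0:(n - 1)) / rate
  th <- 2 * pi * 0.5 * tt
  quat <- array(0, c(n, 4, 1))
  quat[, , 1] <- intentnet:::quat_from_axis_angle(c(0, 0, 1), th)
  pos <- array(0, c(n, 3, 1))
  rec <- kinematics_recording(tt, pos, quat, "s1", rate)
  out <- resample_kinematics(rec, 256)
  nrm <- sqrt(rowSums(out$quat[, , 1]^2))
  expect_equal(nrm, rep(1, length(nrm)), tolerance = 1e-9)
})

test_that("Butterworth band-pass matches its transfer-function oracle", {
  rate <- 256
  tt <- (0:(20 * rate - 1)) / rate
  mk <- function(f) ecg_recording(tt, sin(2 * pi * f * tt), rate)
  # zero in, zero out
  out0 <- bandpass_ecg(ecg_recording(tt, rep(0, length(tt)), rate))
  expect_equal(out0$mv, rep(0, length(tt)))
  expect_true(out0$filtered)
  # 15 Hz sine passes within 5%
  mid <- (5 * rate):(15 * rate)
  amp15 <- max(bandpass_ecg(mk(15))$mv[mid])
  expect_lt(abs(amp15 - 1), 0.05)
  # 1 Hz sine attenuated by the squared (zero-phase) magnitude response,
  # evaluated directly from the digital transfer function
  bf <- signal::butter(2, c(5, 30) / (rate / 2), type = "pass")
  H <- function(f) {
    z <- exp(-1i * 2 * pi * f / rate * (seq_along(bf$b) - 1))
    za <- exp(-1i * 2 * pi * f / rate * (seq_along(bf$a) - 1))
    abs(sum(bf$b * z) / sum(bf$a * za))^2
  }
  amp1 <- max(abs(bandpass_ecg(mk(1))$mv[mid]))
  expect_equal(amp1 / amp15, H(1) / H(15), tolerance = 0.1 * H(1) / H(15))
  expect_error(bandpass_ecg(mk(1), low = 5, high = 200), "rate/2")
})

test_that("zero-phase filtering does not delay a QRS-like train", {
  rate <- 256
  tt <- (0:(10 * rate - 1)) / rate
  mv <- numeric(length(tt))
  for (b in seq(0.5, 9.5, by = 0.857))
    mv <- mv + exp(-(tt - b)^2 / (2 * 0.012^2))
  ecg <- ecg_recording(tt, mv, rate)
  out <- bandpass_ecg(ecg)
  r <- max_xcorr(mv, out$mv, rate, max_lag = 0.2)
  expect_equal(r$lag, 0)
})

test_that("segmentation recovers synthetic ground truth within 3 frames", {
  cfg <- session_config(n_trials = 12, seed = 21)
  ses <- generate_session(cfg)
  kin <- ses$kinematics
  ee <- kin$sensors[cfg$body_parts$role == "end_effector"]
  sp <- as.numeric(linear_speed(kin$pos[, , which(kin$sensors == ee)],
                                kin$rate))
  di <- distance_to_target(kin, ee, ses$schedule)
  seg <- segment_trials(sp, di, ses$schedule, kin$rate)
  gt <- ses$ground_truth
  expect_true(all(seg$valid))
  err <- c(seg$fwd_start - gt$fwd_start, seg$fwd_end - gt$fwd_end,
           seg$bwd_start - gt$bwd_start, seg$bwd_end - gt$bwd_end)
  expect_lte(max(abs(err)), 3)
  # forward precedes backward, half-open sanity
  expect_true(all(seg$fwd_end <= seg$bwd_start))
})

test_that("a target never approached marks the trial invalid", {
  n <- 600
  sp <- c(rep(0, 100), abs(sin(seq(0, pi, length.out = 400))), rep(0, 100))
  di <- seq(0.2, 0.8, length.out = n)  # monotone increasing distance
  tw <- data.frame(trial = 1, start = 1, end = n + 1)
  seg <- segment_trials(sp, di, tw, 240)
  expect_false(seg$valid)
  expect_equal(seg$reason, "no_touch")
})

test_that("noisy-trial flagging hits exactly the corrupted trials", {
  cfg <- session_config(n_trials = 8, seed = 31)
  ses <- generate_session(cfg)
  kin <- ses$kinematics
  ee <- kin$sensors[cfg$body_parts$role == "end_effector"]
  sp <- as.numeric(linear_speed(kin$pos[, , which(kin$sensors == ee)],
                                kin$rate))
  di <- distance_to_target(kin, ee, ses$schedule)
  seg <- segment_trials(sp, di, ses$schedule, kin$rate)
  # clean session: nothing flagged
  seg1 <- flag_noisy_trials(kin, seg)
  expect_true(all(seg1$valid))
  # inject a 0.15 m single-frame spike into trial 4, sensor 3
  corrupt <- c(4L, 6L)
  kin2 <- kin
  for (tr in corrupt) {
    f <- ses$schedule$start[tr] + 250L
    kin2$pos[f, 1, 3] <- kin2$pos[f, 1, 3] + 0.15
  }
  seg2 <- flag_noisy_trials(kin2, seg)
  expect_equal(which(!seg2$valid), corrupt)
  expect_true(all(seg2$reason[corrupt] == "sensor_noise"))
  # infinite threshold flags nothing
  seg3 <- flag_noisy_trials(kin2, seg, max_pos_jump = Inf)
  expect_true(all(seg3$valid))
})

test_that("segmentation JSON export is 0-based half-open", {
  cfg <- session_config(n_trials = 2, seed = 41)
  ses <- generate_session(cfg)
  kin <- ses$kinematics
  ee <- kin$sensors[cfg$body_parts$role == "end_effector"]
  sp <- as.numeric(linear_speed(kin$pos[, , which(kin$sensors == ee)],
                                kin$rate))
  di <- distance_to_target(kin, ee, ses$schedule)
  seg <- segment_trials(sp, di, ses$schedule, kin$rate)
  path <- withr::local_tempfile(fileext = ".json")
  write_segmentation_json(seg, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$forward[[1]][1], seg$fwd_start[1] - 1L)
  expect_equal(nrow(j), 2L)
})
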