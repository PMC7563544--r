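# Synthetic pointing-session generator.
#
# The end effector performs a minimum-jerk reach to a per-trial target and a
# minimum-jerk retraction with larger multiplicative speed fluctuations.
# Other sensors carry a delayed, attenuated copy of the end-effector
# displacement (strength set by segment coupling and side) plus independent
# smooth noise.  Orientation dynamics are built backwards from the target
# statistics: each segment's angular-acceleration magnitude is a chain of
# cosine arcs whose peak/valley ratios realize the configured Gamma law of
# standardized spike amplitudes, so the analysis pipeline recovers the
# injected noise-to-signal ratios.

# deterministic per-trial seed below 2^31
trial_seed <- function(seed, trial_index, stream = 0L) {
  (as.double(seed) * 48271 + as.double(trial_index) * 7919 +
     stream * 104729) %% 2147483629 + 1
}

# minimum-jerk speed profile over n frames covering distance A in time T
min_jerk_speed <- function(n, A, T) {
  tau <- seq(0, 1, length.out = n)
  30 * A / T * tau^2 * (1 - tau)^2
}

# smooth noise: cubic spline through iid normal knots every `knot_dt` s;
# the knot grid covers the whole range (no spline extrapolation) and the
# edge knots are pinned to zero so per-trial fragments concatenate without
# boundary jumps
smooth_noise <- function(n, rate, sd, knot_dt = 0.05) {
  if (sd <= 0) return(numeric(n))
  dur <- (n - 1) / rate
  nk <- max(4L, ceiling(dur / knot_dt) + 1L)
  kt <- seq(0, dur, length.out = nk)
  kv <- stats::rnorm(nk, 0, sd)
  kv[c(1L, nk)] <- 0
  stats::spline(kt, kv, xout = (0:(n - 1)) / rate, method = "fmm")$y
}

# The analysis recovers angular acceleration through two central-difference
# stages, whose composition is a short linear smoothing kernel.  Each spike
# arc is therefore isolated between flat valley shelves (longer than the
# kernel reach), so the recovered peak is an exact linear function of the
# injected peak: p_hat = floor + kappa * (p - floor).  `kappa` is measured
# once per configuration by pushing a single isolated arc through the exact
# discrete operators the pipeline applies.
arc_shape <- function(hp) (1 - cos(pi * (0:(2L * hp)) / hp)) / 2

# shallow triangular dip carved into a valley stretch so that each
# inter-peak flank has a single clean minimum (flat stretches would sprout
# spurious extrema from numerical noise); endpoints stay at the floor
dip_shape <- function(L) {
  if (L < 3L) return(numeric(L))
  c_mid <- (L + 1) / 2
  pmax(0, 1 - abs(seq_len(L) - c_mid) / (c_mid - 1))
}

DIP_FRAC <- 0.005

# Push one isolated arc (with dipped shelves) through the exact discrete
# operators of the analysis; returns the linear peak response p_hat =
# floor + kappa * (p - floor) and the recovered valley level m_hat.
calibrate_arc_gain <- function(hp, shelf, floor_, rate) {
  pad <- 24L
  n <- 2L * pad + 2L * shelf + 2L * hp + 1L
  alpha <- rep(floor_, n)
  i_sh1 <- pad + 1L
  i_arc <- i_sh1 + shelf
  i_sh2 <- i_arc + 2L * hp + 1L
  alpha[i_sh1:(i_arc - 1L)] <- floor_ * (1 - DIP_FRAC * dip_shape(shelf))
  alpha[i_sh2:(i_sh2 + shelf - 1L)] <-
    floor_ * (1 - DIP_FRAC * dip_shape(shelf))
  p <- 2 * floor_
  alpha[i_arc + 0:(2L * hp)] <- floor_ + (p - floor_) * arc_shape(hp)
  omega <- cumsum(alpha) / rate
  theta <- cumsum(omega) / rate
  omega_hat <- c(0, (theta[3:n] - theta[1:(n - 2L)]) * rate / 2, 0)
  alpha_hat <- central_diff(omega_hat, 1 / rate)
  core <- alpha_hat[(i_sh1 + 1L):(i_sh2 + shelf - 2L)]
  list(kappa = (max(core) - floor_) / (p - floor_), m_hat = min(core))
}

# draw spike amplitudes from the target Gamma law, truncated to the
# representable interval (a standardized peak with equal flanking valleys
# always lies in (1/2, 1))
draw_spike_amplitudes <- function(npk, shape, scale) {
  lo <- 0.505
  hi <- 0.985
  s <- stats::rgamma(npk, shape = shape, scale = scale)
  bad <- which(s <= lo | s >= hi)
  guard <- 0L
  while (length(bad) && guard < 50L) {
    s[bad] <- stats::rgamma(length(bad), shape = shape, scale = scale)
    bad <- bad[s[bad] <= lo | s[bad] >= hi]
    guard <- guard + 1L
  }
  s[s <= lo] <- lo + 1e-4
  s[s >= hi] <- hi - 1e-4
  s
}

# angular-acceleration chain over `len` frames: isolated cosine arcs
# separated by dipped valley shelves, peak heights chosen so the analysis
# recovers exactly the drawn standardized amplitudes.  A random phase
# desynchronizes the arc grid across sensors (consumes the caller's RNG
# stream), so pairwise-difference waveforms see each sensor's peaks against
# the other's valley floor.
chain_segment <- function(len, hp, shelf, floor_, shape, scale, cal) {
  period <- 2L * hp + shelf
  phase <- sample.int(period, 1L) - 1L
  lead_len <- shelf + phase
  npk <- max(0L, (len - lead_len - 1L) %/% period)
  low <- floor_ * (1 - DIP_FRAC)
  alpha <- rep(floor_, len)
  if (npk < 1L) {
    alpha[] <- seq(low, floor_, length.out = len)
    return(list(alpha = alpha, amplitudes = numeric(0)))
  }
  s <- draw_spike_amplitudes(npk, shape, scale)
  p_hat <- cal$m_hat * s / (1 - s)
  p <- floor_ + (p_hat - floor_) / cal$kappa
  arc <- arc_shape(hp)
  dip <- floor_ * (1 - DIP_FRAC * dip_shape(shelf))
  alpha[1:lead_len] <-
    seq(low, floor_, length.out = lead_len + 1L)[-(lead_len + 1L)]
  for (k in seq_len(npk)) {
    i0 <- lead_len + (k - 1L) * period + 1L
    alpha[i0:(i0 + 2L * hp)] <- floor_ + (p[k] - floor_) * arc
    if (k < npk)
      alpha[(i0 + 2L * hp + 1L):(i0 + 2L * hp + shelf)] <- dip
  }
  # monotone tail after the last arc: no interior extrema at the window edge
  u <- lead_len + (npk - 1L) * period + 2L * hp + 2L
  if (u <= len) alpha[u:len] <- seq(floor_, low, length.out = len - u + 1L)
  list(alpha = alpha, amplitudes = s)
}

# threshold crossings of a clean speed profile, replicating the segmentation
# rule: last below-threshold frame before the segment peak and first
# below-threshold frame after it (1-based, relative to the trial)
crossing_bounds <- function(speed, lo, hi, thr) {
  idx <- lo:hi
  pk <- idx[which.max(speed[idx])]
  below <- speed < thr
  pre <- which(below[lo:pk])
  start <- if (length(pre)) lo + max(pre) - 1L else lo
  post <- which(below[pk:hi])
  end <- if (length(post)) pk + min(post) - 1L else hi
  c(start, end)
}

#' Generate one synthetic pointing trial (kinematics fragment)
#'
#' Deterministic in (config, trial_index): the same pair always produces a
#' bitwise-identical fragment.  Frames are relative to the trial start.
#'
#' @param config a [session_config()].
#' @param trial_index 0-based trial number (must be `< n_trials`).
#' @return list with `pos` (frames x 3 x sensors), `quat`, `n_frames`,
#'   `target` (xyz), ground-truth `gt` (forward / backward frame bounds,
#'   1-based half-open) and the spike amplitudes injected per sensor and
#'   segment.
#' @export
generate_trial_kinematics <- function(config, trial_index) {
  stopifnot(inherits(config, "session_config"))
  if (trial_index < 0L || trial_index >= config$n_trials)
    stop("trial_index out of range [0, n_trials)")
  rate <- config$frame_rate_kin
  du <- config$durations
  n_fr <- round(sum(du) * rate)
  parts <- config$body_parts
  S <- nrow(parts)
  hp <- config$spike_half_period_frames
  shelf <- config$spike_shelf_frames
  cal <- calibrate_arc_gain(hp, shelf, config$accel_floor, rate)

  layout <- sensor_layout(config)
  set.seed(trial_seed(config$seed, trial_index))

  # ---- end-effector translation -------------------------------------------
  p0 <- layout$rest[, parts$role == "end_effector"]
  dx <- stats::runif(2, -config$target_jitter, config$target_jitter)
  target <- p0 + c(dx[1], config$reach_distance, 0.10 + 0.5 * dx[2])
  A <- sqrt(sum((target - p0)^2))
  dir <- (target - p0) / A

  i_f0 <- round(du["pre"] * rate) + 1L
  i_f1 <- round((du["pre"] + du["forward"]) * rate)
  i_b0 <- round((du["pre"] + du["forward"] + du["dwell"]) * rate) + 1L
  i_b1 <- round((du["pre"] + du["forward"] + du["dwell"] + du["backward"]) *
                  rate)

  v <- numeric(n_fr)
  nf <- i_f1 - i_f0 + 1L
  nb <- i_b1 - i_b0 + 1L
  jitter_dt <- 0.03  # fluctuation timescale, physiological tremor band
  vf <- min_jerk_speed(nf, A, du["forward"]) *
    pmax(0.02, 1 + smooth_noise(nf, rate, config$speed_jitter["forward"],
                                knot_dt = jitter_dt))
  vf <- vf * (A / (sum(vf) / rate))
  vb <- min_jerk_speed(nb, A, du["backward"]) *
    pmax(0.02, 1 + smooth_noise(nb, rate, config$speed_jitter["backward"],
                                knot_dt = jitter_dt))
  vb <- vb * (A / (sum(vb) / rate))
  v[i_f0:i_f1] <- vf
  v[i_b0:i_b1] <- vb

  thr <- 0.05 * max(v)
  fwd_gt <- crossing_bounds(v, i_f0, i_f1, thr)
  bwd_gt <- crossing_bounds(v, i_b0, i_b1, thr)

  s_net <- cumsum(ifelse(seq_len(n_fr) <= i_f1, v,
                         ifelse(seq_len(n_fr) >= i_b0, -v, 0))) / rate
  s_net[s_net < 0] <- 0
  s_net[(i_f1 + 1L):(i_b0 - 1L)] <- s_net[i_f1]  # hold at the target
  s_net[i_b1:n_fr] <- 0
  # forward-only and backward-only displacement components (each 0 -> A)
  s_fwd <- cumsum(ifelse(seq_len(n_fr) <= i_f1, v, 0)) / rate
  s_bwd <- cumsum(ifelse(seq_len(n_fr) >= i_b0, v, 0)) / rate
  # slow compensation drift with zero speed at the trial edges; spreads the
  # net coupled displacement (cf - cb) * A over the whole trial so follower
  # trajectories close without a transient in any analysis window
  tau_tr <- seq(0, 1, length.out = n_fr)
  W_slow <- tau_tr - sin(2 * pi * tau_tr) / (2 * pi)  # 0 -> 1, edges flat

  # ---- per-sensor translation ---------------------------------------------
  cf <- config$coupling["forward"]
  cb <- config$coupling["backward"]
  pos <- array(0, c(n_fr, 3L, S))
  for (s in seq_len(S)) {
    side <- parts$side[s]
    a_i <- parts$attenuation[s]
    move_dir <- if (parts$role[s] == "end_effector") dir else layout$dir[, s]
    if (parts$role[s] == "end_effector") {
      disp <- s_net
    } else {
      delay <- round(config$follower_delay_ms[side] / 1000 * rate)
      cs <- config$side_coupling[side]
      disp <- a_i * cs * (cf * shift_series(s_fwd, delay) -
                            cb * shift_series(s_bwd, delay) -
                            (cf - cb) * A * W_slow)
      nv <- smooth_noise_3d(n_fr, rate, 1, knot_dt = 0.15)
      cpl <- coupling_profile(n_fr, i_f1 + delay, i_b0 + delay, cf, cb)
      namp <- a_i * (1 - cpl * cs) * 0.012
      pos[, , s] <- pos[, , s] + nv * namp
    }
    pos[, , s] <- pos[, , s] +
      matrix(layout$rest[, s], n_fr, 3L, byrow = TRUE) +
      outer(disp, move_dir)
  }
  # measurement noise on every sensor
  for (s in seq_len(S))
    pos[, , s] <- pos[, , s] +
      smooth_noise_3d(n_fr, rate, config$noise_sd, knot_dt = 0.125)

  # ---- orientation dynamics -----------------------------------------------
  quat <- array(0, c(n_fr, 4L, S))
  spikes <- list()
  gp <- config$gamma_params
  for (s in seq_len(S)) {
    side <- parts$side[s]
    b_i <- config$accel_floor * layout$floor_mult[s]
    cal_i <- list(kappa = cal$kappa,
                  m_hat = cal$m_hat * layout$floor_mult[s])
    alpha <- numeric(n_fr)
    amps <- list()
    for (seg in c("forward", "backward")) {
      bounds <- if (seg == "forward") fwd_gt else bwd_gt
      row <- gp[gp$segment == seg & gp$side == side, ]
      ch <- chain_segment(bounds[2] - bounds[1] + 1L, hp, shelf,
                          b_i, row$shape, row$scale, cal_i)
      alpha[bounds[1]:bounds[2]] <- ch$alpha
      amps[[seg]] <- ch$amplitudes
      # ramps into and out of the chain
      ramp <- (1 - cos(pi * seq_len(hp) / (hp + 1L))) / 2 * b_i
      lo <- max(1L, bounds[1] - hp)
      if (bounds[1] > lo)
        alpha[lo:(bounds[1] - 1L)] <- ramp[seq_len(bounds[1] - lo)]
      hi <- min(n_fr, bounds[2] + hp)
      if (hi > bounds[2])
        alpha[(bounds[2] + 1L):hi] <- rev(ramp)[seq_len(hi - bounds[2])]
    }
    omega <- cumsum(alpha) / rate  # deg/s, nonnegative
    # wind down to zero during the post-rest so trials concatenate smoothly
    spin_start <- bwd_gt[2] + hp + 8L
    if (spin_start < n_fr - 8L) {
      nd <- n_fr - 8L - spin_start
      wend <- omega[spin_start]
      down <- wend * (1 + cos(pi * seq_len(nd) / nd)) / 2
      omega[(spin_start + 1L):(spin_start + nd)] <- down
      omega[(spin_start + nd):n_fr] <- 0
    }
    theta <- cumsum(omega) / rate * pi / 180
    quat[, , s] <- quat_from_axis_angle(layout$axis[, s], theta)
    spikes[[parts$sensor[s]]] <- amps
  }

  list(pos = pos, quat = quat, n_frames = n_fr, target = target,
       gt = list(forward = c(fwd_gt[1], fwd_gt[2] + 1L),
                 backward = c(bwd_gt[1], bwd_gt[2] + 1L)),
       injected_spikes = spikes)
}

# segment-dependent coupling profile: cf during the forward phase, cb during
# the backward phase, smooth morph while the (shifted) displacement dwells
coupling_profile <- function(n, morph_start, morph_end, cf, cb) {
  morph_start <- max(1L, min(n, morph_start))
  morph_end <- max(morph_start + 1L, min(n, morph_end))
  out <- numeric(n)
  out[seq_len(morph_start)] <- cf
  tau <- seq(0, 1, length.out = morph_end - morph_start + 1L)
  out[morph_start:morph_end] <- cf + (cb - cf) * (tau^2 * (3 - 2 * tau))
  if (morph_end < n) out[(morph_end + 1L):n] <- cb
  out
}

# shift a series by `k` samples (positive = later), padded with the edge
# value so displacement plateaus are preserved
shift_series <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  if (k > 0L) c(rep(x[1L], min(k, n)), x)[seq_len(n)]
  else c(x[min(-k + 1L, n):n], rep(x[n], min(-k, n)))[seq_len(n)]
}

smooth_noise_3d <- function(n, rate, sd, knot_dt = 0.125) {
  cbind(smooth_noise(n, rate, sd, knot_dt),
        smooth_noise(n, rate, sd, knot_dt),
        smooth_noise(n, rate, sd, knot_dt))
}

# per-sensor rest positions, motion directions and rotation axes; all a
# deterministic function of the session seed
sensor_layout <- function(config) {
  parts <- config$body_parts
  S <- nrow(parts)
  sgn <- ifelse(grepl("_right$", parts$sensor), 1,
                ifelse(grepl("_left$", parts$sensor), -1, 0))
  rest <- rbind(
    x = sgn * c(head = 0, trunk = 0, scapula = 0.10, upper_arm = 0.18,
                forearm = 0.22, end_effector = 0.20, hand = 0.20)[parts$role],
    y = c(head = 0.05, trunk = -0.05, scapula = -0.02, upper_arm = 0.02,
          forearm = 0.15, end_effector = 0.25, hand = 0.25)[parts$role],
    z = c(head = 0.55, trunk = 0.30, scapula = 0.42, upper_arm = 0.30,
          forearm = 0.12, end_effector = 0.05, hand = 0.05)[parts$role])
  colnames(rest) <- parts$sensor
  set.seed(trial_seed(config$seed, -1L, stream = 7L))
  axis <- matrix(stats::rnorm(3L * S), 3L, S)
  axis <- sweep(axis, 2L, sqrt(colSums(axis^2)), "/")
  dirp <- matrix(stats::rnorm(3L * S, sd = 0.15), 3L, S)
  base <- c(0, 1, 0.2)
  dir <- sweep(dirp, 1L, base, "+")
  dir <- sweep(dir, 2L, sqrt(colSums(dir^2)), "/")
  # per-sensor acceleration floors: widely spread on the performing side,
  # nearly equal on the non-performing side, so pairwise-difference
  # waveforms are more dispersed (higher NSR) among performing pairs
  spread <- c(performing = 0.38, midline = 0.20,
              nonperforming = 0.05)[parts$side]
  floor_mult <- 1 + stats::runif(S, -1, 1) * spread
  list(rest = rest, dir = dir, axis = axis, floor_mult = floor_mult)
}
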