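# Cross-correlation machinery shared by max_xcorr and the batched adjacency
# builder.  The coefficient at lag L is the Pearson correlation over the
# overlapping stretch (means and variances recomputed per lag), so window
# edges do not bias the location of the maximum.  Product sums come from one
# FFT per series; per-lag means and variances from cumulative sums.

# per-series precomputation for a padded FFT length nf
xcorr_prep <- function(x, nf) {
  n <- length(x)
  list(X = stats::fft(c(x, numeric(nf - n))),
       c1 = c(0, cumsum(x)), c2 = c(0, cumsum(x^2)), n = n)
}

# overlap-Pearson correlations for all lags -(n-1)..(n-1); positive lag
# means x leads y
xcorr_pearson <- function(px, py, nf) {
  n <- px$n
  cc <- Re(stats::fft(Conj(px$X) * py$X, inverse = TRUE)) / nf
  lags <- c(0:(n - 1L), -(1:(n - 1L)))
  sxy <- c(cc[1:n], cc[nf - (1:(n - 1L)) + 1L])
  m <- n - abs(lags)
  pos <- lags >= 0
  L <- abs(lags)
  sx <- sy <- sxx <- syy <- numeric(length(lags))
  # lag >= 0: x[1..n-L] against y[(1+L)..n]
  sx[pos] <- px$c1[n - L[pos] + 1L]
  sxx[pos] <- px$c2[n - L[pos] + 1L]
  sy[pos] <- py$c1[n + 1L] - py$c1[L[pos] + 1L]
  syy[pos] <- py$c2[n + 1L] - py$c2[L[pos] + 1L]
  # lag < 0: x[(1+L)..n] against y[1..n-L]
  sx[!pos] <- px$c1[n + 1L] - px$c1[L[!pos] + 1L]
  sxx[!pos] <- px$c2[n + 1L] - px$c2[L[!pos] + 1L]
  sy[!pos] <- py$c1[n - L[!pos] + 1L]
  syy[!pos] <- py$c2[n - L[!pos] + 1L]
  vx <- sxx - sx^2 / m
  vy <- syy - sy^2 / m
  den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  r <- ifelse(den > 1e-12 * m, (sxy - sx * sy / m) / den, NA_real_)
  list(lag = lags, r = r)
}

# usable lag range: requested window, capped so the overlap keeps at least
# half the samples (never fewer than 16)
lag_cap <- function(n, max_lag_samples) {
  max(0L, min(as.integer(max_lag_samples), n - max(16L, n %/% 2L)))
}

# pick max |r| within the lag window; ties broken toward the smallest |lag|
# (then toward the positive lag) for determinism
pick_max_lag <- function(lags, r, max_lag_samples) {
  keep <- abs(lags) <= max_lag_samples & !is.na(r)
  lags <- lags[keep]; r <- r[keep]
  if (!length(r)) return(list(coefficient = NA_real_, lag_samples = 0L,
                              sign = 0))
  o <- order(-abs(r), abs(lags), -sign(lags))
  list(coefficient = abs(r[o[1L]]), lag_samples = lags[o[1L]],
       sign = sign(r[o[1L]]))
}

#' Maximal normalized cross-correlation and its lag
#'
#' Series are mean-centered and unit-scaled per lag over the overlapping
#' stretch (an overlap-Pearson correlation), so window edges do not bias
#' the lag of the maximum.  The scan covers lags |L| <= `max_lag`, further
#' capped so that at least half the samples overlap.  The maximum absolute
#' coefficient is reported as an unsigned magnitude together with its
#' signed lag; positive lag means `x` leads `y`.  Ties go to the smallest
#' |lag|.
#'
#' @param x,y numeric vectors of equal length sampled at `rate`.
#' @param rate sampling rate in Hz.
#' @param max_lag lag window half-width in seconds (default 1).
#' @return list with `coefficient` (unsigned max |r|), `lag` (seconds,
#'   positive = x leads y), `sign` of the correlation at that lag.
#' @export
max_xcorr <- function(x, y, rate, max_lag = 1) {
  if (length(x) != length(y)) stop("series must have equal length")
  n <- length(x)
  if (n < 4L) stop("series too short")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("zero-variance input: constant signal has no correlation structure")
  nf <- stats::nextn(2L * n - 1L, 2L)
  cc <- xcorr_pearson(xcorr_prep(as.numeric(x), nf),
                      xcorr_prep(as.numeric(y), nf), nf)
  best <- pick_max_lag(cc$lag, cc$r, lag_cap(n, round(max_lag * rate)))
  list(coefficient = best$coefficient, lag = best$lag_samples / rate,
       sign = best$sign)
}

#' Cross-correlation adjacency matrix across body parts
#'
#' For each valid trial the requested segment's interval is cut from every
#' sensor's linear-speed series; pairwise maximal cross-correlations are
#' computed per trial and the per-pair median across trials forms the edge
#' weight.  Lags are medians of the signed per-trial lags and stored
#' antisymmetrically.
#'
#' @param speeds numeric matrix, frames x sensors (columns named), linear
#'   speed at `rate` Hz.
#' @param rate sampling rate of `speeds` in Hz.
#' @param segmentation a [segment_trials()] result.
#' @param segment `"forward"` or `"backward"`.
#' @param max_lag lag window in seconds (default 1).
#' @param min_len minimum usable interval length in samples.
#' @return object of class `adjacency_matrix`: list with `labels`,
#'   symmetric `weights` (zero diagonal), antisymmetric `lags` (seconds),
#'   `n_trials` used.
#' @export
build_adjacency <- function(speeds, rate, segmentation,
                            segment = c("forward", "backward"),
                            max_lag = 1, min_len = 16L) {
  segment <- match.arg(segment)
  speeds <- as.matrix(speeds)
  labels <- colnames(speeds)
  if (is.null(labels)) labels <- paste0("s", seq_len(ncol(speeds)))
  iv <- segment_intervals(segmentation, segment)
  iv <- iv[iv$valid & (iv$end - iv$start) >= min_len, , drop = FALSE]
  if (nrow(iv) < 5L) stop("insufficient data: fewer than 5 valid trials")
  S <- ncol(speeds)
  pairs <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
  wacc <- matrix(NA_real_, nrow(iv), nrow(pairs))
  lacc <- matrix(NA_real_, nrow(iv), nrow(pairs))
  for (tr in seq_len(nrow(iv))) {
    idx <- iv$start[tr]:(iv$end[tr] - 1L)
    n <- length(idx)
    win <- speeds[idx, , drop = FALSE]
    sds <- sqrt(pmax(0, colMeans(win^2) - colMeans(win)^2))
    ok <- sds > 1e-12
    nf <- stats::nextn(2L * n - 1L, 2L)
    preps <- lapply(seq_len(S), function(s)
      if (ok[s]) xcorr_prep(win[, s], nf) else NULL)
    max_s <- lag_cap(n, round(max_lag * rate))
    for (pidx in seq_len(nrow(pairs))) {
      i <- pairs[pidx, 1L]; j <- pairs[pidx, 2L]
      if (!ok[i] || !ok[j]) next
      cc <- xcorr_pearson(preps[[i]], preps[[j]], nf)
      best <- pick_max_lag(cc$lag, cc$r, max_s)
      wacc[tr, pidx] <- best$coefficient
      lacc[tr, pidx] <- best$lag_samples / rate
    }
  }
  W <- matrix(0, S, S, dimnames = list(labels, labels))
  L <- matrix(0, S, S, dimnames = list(labels, labels))
  for (pidx in seq_len(nrow(pairs))) {
    i <- pairs[pidx, 1L]; j <- pairs[pidx, 2L]
    w <- stats::median(wacc[, pidx], na.rm = TRUE)
    l <- stats::median(lacc[, pidx], na.rm = TRUE)
    if (is.na(w)) w <- 0
    if (is.na(l)) l <- 0
    W[i, j] <- W[j, i] <- w
    L[i, j] <- l
    L[j, i] <- -l
  }
  structure(list(labels = labels, weights = W, lags = L, n_trials = nrow(iv),
                 segment = segment),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("<adjacency_matrix> %d nodes, %d trials (%s), median weight %.3f\n",
              length(x$labels), x$n_trials, x$segment %||% "?",
              stats::median(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

#' Weighted clustering coefficients (geometric-mean triangle intensity)
#'
#' Edge weights are normalized by the largest weight; the triangle intensity
#' of node i is the sum over neighbor pairs (j, h) of
#' (w_ij * w_ih * w_jh)^(1/3), and the clustering coefficient divides by the
#' number of possible neighbor pairs k_i (k_i - 1) / 2.  Degrees count
#' edges with positive weight.  Nodes with fewer than two links get C = 0.
#'
#' @param adj [build_adjacency()] result, or a symmetric nonnegative matrix.
#' @return data.frame with `node`, `degree`, `triangle_intensity`,
#'   `clustering`.
#' @export
clustering_coefficients <- function(adj) {
  W <- if (inherits(adj, "adjacency_matrix")) adj$weights else as.matrix(adj)
  if (!isSymmetric(unname(W), tol = 1e-8)) stop("weights must be symmetric")
  labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("s", seq_len(nrow(W)))
  S <- nrow(W)
  diag(W) <- 0
  mx <- max(W)
  k <- rowSums(W > 0)
  if (mx <= 0) {
    return(data.frame(node = labels, degree = k, triangle_intensity = 0,
                      clustering = 0))
  }
  W3 <- (W / mx)^(1 / 3)
  t_i <- diag(W3 %*% W3 %*% W3) / 2
  C <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  data.frame(node = labels, degree = k, triangle_intensity = t_i,
             clustering = C)
}

#' Amplitude envelope of a (filtered) ECG series
#'
#' Rectifies the voltage, applies a running median wide enough to suppress
#' individual QRS complexes (brief isolated transients) while preserving
#' slower movement-locked amplitude changes, then smooths with a centered
#' moving average.  Both stages are symmetric, so the envelope introduces
#' no timing shift.
#'
#' @param ecg an `ecg_recording` (see [bandpass_ecg()]) or numeric vector.
#' @param rate sampling rate, taken from the recording when available.
#' @param median_s running-median window in seconds (default 0.25, wider
#'   than a QRS complex, narrower than a movement segment).
#' @param smooth_s moving-average window in seconds (default 0.08).
#' @return numeric envelope, same length as the input.
#' @export
ecg_envelope <- function(ecg, rate = NULL, median_s = 0.25,
                         smooth_s = 0.08) {
  v <- if (inherits(ecg, "ecg_recording")) ecg$mv else as.numeric(ecg)
  if (is.null(rate)) rate <- if (inherits(ecg, "ecg_recording")) ecg$rate else
    stop("rate must be supplied")
  k <- max(3L, round(median_s * rate))
  if (k %% 2L == 0L) k <- k + 1L
  med <- stats::runmed(abs(v), k, endrule = "constant")
  w <- max(1L, round(smooth_s * rate))
  if (w %% 2L == 0L) w <- w + 1L
  kern <- rep(1 / w, w)
  sm <- as.numeric(stats::filter(med, kern, sides = 2L,
                                 method = "convolution"))
  # fill filter NAs at the edges with the nearest smoothed value
  first <- which(!is.na(sm))[1L]
  last <- max(which(!is.na(sm)))
  sm[seq_len(first - 1L)] <- sm[first]
  sm[seq(last + 1L, length.out = length(sm) - last)] <- sm[last]
  sm
}

#' Heart-body connectivity: per-sensor cross-correlation, lag and EMD
#'
#' For every valid trial the requested segment's window (padded on both
#' sides) is cut from the ECG amplitude envelope and from each body part's
#' linear speed at the ECG rate; the maximal cross-correlation and its
#' signed lag are extracted per trial and summarized by their medians.
#' Positive lag means the ECG leads the kinematics.  When MMS amplitude sets
#' are supplied, the earth mover's distance between each body part's MMS
#' histogram and the ECG MMS histogram is added.
#'
#' @param ecg_filtered band-passed `ecg_recording`.
#' @param speeds numeric matrix, frames x sensors, linear speed resampled to
#'   the ECG rate (columns named).
#' @param kin_rate sampling rate of `speeds`; must equal the ECG rate.
#' @param segmentation a [segment_trials()] result (frame indices at the
#'   original kinematics rate stored in its `rate` attribute).
#' @param segment `"forward"` or `"backward"`.
#' @param max_lag lag window in seconds (default 1).
#' @param window_pad seconds of context added on both sides of each segment
#'   window (default 0.3).
#' @param body_mms optional named list (per sensor) of MMS amplitude vectors
#'   for this segment.
#' @param ecg_mms optional numeric vector of ECG MMS amplitudes for this
#'   segment.
#' @param min_count histogram minimum sample size for the EMD part.
#' @return data.frame with one row per sensor: `sensor`, `xcorr`, `lag_s`,
#'   `emd` (NA when MMS not supplied), `n_trials`.
#' @export
heart_body_connectivity <- function(ecg_filtered, speeds, kin_rate,
                                    segmentation,
                                    segment = c("forward", "backward"),
                                    max_lag = 1, window_pad = 0.3,
                                    body_mms = NULL, ecg_mms = NULL,
                                    min_count = 100L) {
  segment <- match.arg(segment)
  stopifnot(inherits(ecg_filtered, "ecg_recording"))
  if (!isTRUE(ecg_filtered$filtered))
    warning("ECG does not appear to be band-pass filtered")
  if (abs(kin_rate - ecg_filtered$rate) > 1e-9)
    stop("rate mismatch: kinematics must be resampled to the ECG rate")
  speeds <- as.matrix(speeds)
  labels <- colnames(speeds)
  if (is.null(labels)) labels <- paste0("s", seq_len(ncol(speeds)))
  env <- ecg_envelope(ecg_filtered)
  seg_rate <- attr(segmentation, "rate")
  if (is.null(seg_rate)) stop("segmentation lacks a rate attribute")
  iv <- segment_intervals(segmentation, segment)
  iv <- iv[iv$valid, , drop = FALSE]
  if (nrow(iv) < 5L) stop("insufficient data: fewer than 5 valid trials")
  pad <- round(window_pad * kin_rate)
  nmax <- min(nrow(speeds), length(env))
  S <- ncol(speeds)
  xc <- matrix(NA_real_, nrow(iv), S)
  lg <- matrix(NA_real_, nrow(iv), S)
  for (tr in seq_len(nrow(iv))) {
    a <- max(1L, round((iv$start[tr] - 1L) / seg_rate * kin_rate) + 1L - pad)
    b <- min(nmax, round((iv$end[tr] - 1L) / seg_rate * kin_rate) + 1L + pad)
    if (b - a < 16L) next
    ewin <- env[a:b]
    for (s in seq_len(S)) {
      swin <- speeds[a:b, s]
      res <- tryCatch(max_xcorr(ewin, swin, kin_rate, max_lag),
                      error = function(e) NULL)
      if (!is.null(res)) {
        xc[tr, s] <- res$coefficient
        lg[tr, s] <- res$lag
      }
    }
  }
  emd_vals <- rep(NA_real_, S)
  if (!is.null(ecg_mms) && length(ecg_mms) < min_count) {
    warning("too few ECG spike amplitudes for EMD; reporting NA")
    ecg_mms <- NULL
  }
  if (!is.null(body_mms) && !is.null(ecg_mms)) {
    hq <- mms_histogram(ecg_mms, min_count = min_count)
    for (s in seq_len(S)) {
      amps <- body_mms[[labels[s]]]
      if (!is.null(amps) && length(amps) >= min_count)
        emd_vals[s] <- emd(mms_histogram(amps, min_count = min_count), hq)
    }
  }
  data.frame(sensor = labels,
             xcorr = apply(xc, 2L, stats::median, na.rm = TRUE),
             lag_s = apply(lg, 2L, stats::median, na.rm = TRUE),
             emd = emd_vals,
             n_trials = colSums(!is.na(xc)))
}
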