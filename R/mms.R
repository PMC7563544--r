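#' Locate alternating peaks and valleys of a scalar waveform
#'
#' Strict local maxima and minima of the series, with plateaus collapsed to
#' their midpoint sample.  Extrema alternate by construction (between two
#' retained minima lies exactly one maximum) and the first and last samples
#' are never reported as extrema.  A constant series yields no extrema.
#'
#' @param series finite numeric vector, length >= 3.
#' @return list with integer index vectors `maxima` and `minima` (1-based,
#'   strictly increasing).
#' @export
find_peaks_valleys <- function(series) {
  if (length(series) < 3L) stop("series must have at least 3 samples")
  if (!all(is.finite(series))) stop("series must be finite")
  r <- rle(as.numeric(series))
  m <- length(r$values)
  if (m < 3L) return(list(maxima = integer(0), minima = integer(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- starts + (r$lengths - 1L) %/% 2L  # plateau midpoint
  d <- diff(r$values)
  k <- 2:(m - 1L)
  is_max <- d[k - 1L] > 0 & d[k] < 0
  is_min <- d[k - 1L] < 0 & d[k] > 0
  list(maxima = mid[k[is_max]], minima = mid[k[is_min]])
}

#' Micro-movement spike train from a nonnegative waveform
#'
#' Each interior local maximum `p` is standardized by its flanking valley
#' values `m1`, `m2` as `p / (p + (m1 + m2) / 2)`, yielding a unitless
#' amplitude in \[0, 1\] recorded at the maximum's frame.  The flanking
#' valley on each side is the minimum of the series between this maximum and
#' the neighboring maximum (or the series boundary), so the first and last
#' peaks use the boundary stretch as their outer valley.  Peaks whose peak
#' and both valleys are all zero are dropped (0/0 undefined).
#'
#' @param series nonnegative finite numeric vector.
#' @param mode `"amplitude_only"` keeps only the spike amplitudes;
#'   `"frame_preserving"` additionally allows reconstruction of a
#'   zero-padded series of the source length via [mms_frame_series()].
#' @return object of class `mms_train`: list with `indices`, `amplitudes`,
#'   `n_source`, `mode`, `n_dropped`.
#' @export
standardize_peaks <- function(series,
                              mode = c("amplitude_only", "frame_preserving")) {
  mode <- match.arg(mode)
  x <- as.numeric(series)
  if (any(x < 0)) stop("series must be nonnegative")
  ext <- find_peaks_valleys(x)
  pk <- ext$maxima
  n <- length(x)
  if (length(pk) == 0L) {
    return(structure(list(indices = integer(0), amplitudes = numeric(0),
                          n_source = n, mode = mode, n_dropped = 0L),
                     class = "mms_train"))
  }
  # valley value on each flank: min over the stretch to the adjacent peak
  # (exclusive) or to the series boundary (inclusive)
  bounds <- c(0L, pk, n + 1L)
  nseg <- length(pk) + 1L
  seg_min <- vapply(seq_len(nseg), function(s) {
    lo <- bounds[s] + 1L
    hi <- bounds[s + 1L] - 1L
    if (lo > hi) Inf else min(x[lo:hi])
  }, numeric(1))
  m1 <- seg_min[seq_along(pk)]
  m2 <- seg_min[seq_along(pk) + 1L]
  p <- x[pk]
  denom <- p + (m1 + m2) / 2
  keep <- is.finite(denom) & denom > 0
  structure(list(indices = pk[keep], amplitudes = (p / denom)[keep],
                 n_source = n, mode = mode,
                 n_dropped = sum(!keep)),
            class = "mms_train")
}

#' @export
print.mms_train <- function(x, ...) {
  cat(sprintf("<mms_train> %d spikes from %d frames (%s)%s\n",
              length(x$amplitudes), x$n_source, x$mode,
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Frame-preserving view of a spike train
#'
#' Zero-padded series of the source length with spike amplitudes at their
#' original frames.
#'
#' @param train an [standardize_peaks()] result.
#' @return numeric vector of length `train$n_source`.
#' @export
mms_frame_series <- function(train) {
  stopifnot(inherits(train, "mms_train"))
  out <- numeric(train$n_source)
  out[train$indices] <- train$amplitudes
  out
}

#' Elementwise absolute difference of two aligned series
#'
#' The connectivity waveform for a pair of body parts: |a - b| per frame,
#' reflecting the change in separation between the two.  Feeds
#' [standardize_peaks()].
#'
#' @param series_a,series_b numeric vectors of equal length.
#' @return numeric vector |a - b|.
#' @export
pairwise_absdiff <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) stop("length mismatch")
  abs(as.numeric(series_a) - as.numeric(series_b))
}

#' Frequency histogram of MMS amplitudes (Freedman-Diaconis binning)
#'
#' Bin width 2 * IQR * n^(-1/3); bins cover \[min, max\] and weights are
#' normalized to sum to one.  When the IQR is zero the square-root rule is
#' used instead (with a warning); a fully degenerate sample falls into a
#' single bin.
#'
#' @param amplitudes numeric values (typically in \[0, 1\]).
#' @param min_count minimum sample size required (default 100).
#' @return object of class `mms_histogram`: list with strictly increasing
#'   `edges`, normalized `weights`, and derived `centers`.
#' @export
mms_histogram <- function(amplitudes, min_count = 100L) {
  x <- as.numeric(amplitudes)
  if (length(x) < min_count)
    stop(sprintf("need at least %d values, got %d", min_count, length(x)))
  if (!all(is.finite(x))) stop("amplitudes must be finite")
  n <- length(x)
  rng <- range(x)
  iqr <- stats::IQR(x)
  if (rng[1] == rng[2]) {
    eps <- max(abs(rng[1]), 1) * 1e-3
    edges <- c(rng[1] - eps, rng[1] + eps)
  } else if (iqr <= 0) {
    warning("zero IQR; falling back to square-root binning rule")
    nb <- max(1L, ceiling(sqrt(n)))
    edges <- seq(rng[1], rng[2], length.out = nb + 1L)
  } else {
    bw <- 2 * iqr * n^(-1 / 3)
    nb <- max(1L, ceiling((rng[2] - rng[1]) / bw))
    edges <- rng[1] + bw * 0:nb
  }
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(edges) - 1L)
  structure(list(edges = edges, weights = counts / n,
                 centers = (edges[-1L] + edges[-length(edges)]) / 2),
            class = "mms_histogram")
}

#' @export
print.mms_histogram <- function(x, ...) {
  cat(sprintf("<mms_histogram> %d bins on [%.4g, %.4g]\n",
              length(x$weights), x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}
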