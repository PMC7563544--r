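# Independent oracles used across the suite.

# Greedy transport on sorted 1-D point masses: exact optimum for a convex
# ground cost (moves mass left-to-right, always matching the lowest
# remaining supply with the lowest remaining demand).
emd_greedy <- function(p, q) {
  oi <- order(p$centers); oj <- order(q$centers)
  pc <- p$centers[oi]; pw <- p$weights[oi]
  qc <- q$centers[oj]; qw <- q$weights[oj]
  i <- 1L; j <- 1L; cost <- 0
  while (i <= length(pc) && j <= length(qc)) {
    f <- min(pw[i], qw[j])
    cost <- cost + f * abs(pc[i] - qc[j])
    pw[i] <- pw[i] - f
    qw[j] <- qw[j] - f
    if (pw[i] <= 1e-15) i <- i + 1L
    if (j <= length(qc) && qw[j] <= 1e-15) j <- j + 1L
  }
  cost
}

# Full linear-program transport under the textbook constraints
# (row sums <= supply, column sums <= demand, total mass = min of the two);
# returns NA when the solver fails to converge on a degenerate basis.
emd_lp <- function(p, q) {
  if (!requireNamespace("boot", quietly = TRUE)) return(NA_real_)
  m <- length(p$centers); n <- length(q$centers)
  d <- abs(outer(p$centers, q$centers, "-"))
  A1 <- matrix(0, m + n, m * n)
  for (i in 1:m) for (j in 1:n) {
    k <- (i - 1L) * n + j
    A1[i, k] <- 1
    A1[m + j, k] <- 1
  }
  b3 <- min(sum(p$weights), sum(q$weights))
  res <- tryCatch(
    boot::simplex(a = as.vector(t(d)), A1 = A1,
                  b1 = c(p$weights, q$weights),
                  A3 = matrix(1, 1, m * n), b3 = b3, maxi = FALSE),
    error = function(e) NULL)
  if (is.null(res) || res$solved != 1) return(NA_real_)
  unname(res$value) / b3
}

rand_hist <- function(nbins, rng = c(0, 1)) {
  centers <- sort(stats::runif(nbins, rng[1], rng[2]))
  w <- stats::runif(nbins)
  list(centers = centers, weights = w / sum(w))
}

# Exhaustive triangle enumeration for the weighted clustering coefficient:
# t_i = sum over unordered neighbor pairs (j, h) of the geometric mean of
# the three normalized weights; C_i = t_i / (k_i (k_i - 1) / 2).
clustering_brute <- function(W) {
  S <- nrow(W)
  diag(W) <- 0
  Wn <- if (max(W) > 0) W / max(W) else W
  k <- rowSums(W > 0)
  C <- numeric(S)
  t_i <- numeric(S)
  for (i in seq_len(S)) {
    acc <- 0
    for (j in seq_len(S)) for (h in seq_len(S)) {
      if (j >= h || j == i || h == i) next
      acc <- acc + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
    }
    t_i[i] <- acc
    C[i] <- if (k[i] >= 2) acc / (k[i] * (k[i] - 1) / 2) else 0
  }
  list(triangle_intensity = t_i, clustering = C)
}

# hand-rolled minimal segmentation container for direct network tests
make_segmentation <- function(fwd, bwd, rate = 240) {
  seg <- data.frame(trial = seq_len(nrow(fwd)),
                    fwd_start = fwd[, 1], fwd_end = fwd[, 2],
                    bwd_start = bwd[, 1], bwd_end = bwd[, 2],
                    window_start = fwd[, 1], window_end = bwd[, 2],
                    valid = TRUE, reason = "none")
  attr(seg, "rate") <- rate
  class(seg) <- c("trial_segmentation", "data.frame")
  seg
}

# segmentation taken directly from a generated session's ground truth
segment_trials_from_gt <- function(ses) {
  gt <- ses$ground_truth
  seg <- data.frame(trial = gt$trial,
                    fwd_start = gt$fwd_start, fwd_end = gt$fwd_end,
                    bwd_start = gt$bwd_start, bwd_end = gt$bwd_end,
                    window_start = ses$schedule$start,
                    window_end = ses$schedule$end,
                    valid = TRUE, reason = "none")
  attr(seg, "rate") <- ses$kinematics$rate
  class(seg) <- c("trial_segmentation", "data.frame")
  seg
}
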