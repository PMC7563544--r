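# Quaternion helpers.  Convention throughout the package: scalar-first
# (w, x, y, z), Hamilton product.  Rows of a quaternion matrix are frames.

quat_normalize <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  nrm <- sqrt(rowSums(q^2))
  if (any(nrm < 1e-12)) stop("zero-norm quaternion")
  q / nrm
}

quat_conjugate <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  q[, 2:4] <- -q[, 2:4]
  q
}

# Row-wise Hamilton product a * b
quat_multiply <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  cbind(cos(angle / 2), outer(sin(angle / 2), axis))
}

# Flip sign of quaternions so consecutive frames stay on the same cover
# (dot product of consecutive rows kept nonnegative).
quat_sign_continuity <- function(q) {
  if (nrow(q) < 2L) return(q)
  d <- rowSums(q[-nrow(q), , drop = FALSE] * q[-1L, , drop = FALSE])
  flip <- cumprod(c(1, ifelse(d < 0, -1, 1)))
  q * flip
}

# Rotation angle (radians) of the relative rotation between paired rows,
# mapped to the shortest arc.
quat_relative_angle <- function(qa, qb) {
  dq <- quat_multiply(quat_conjugate(qa), qb)
  vec <- sqrt(rowSums(dq[, 2:4, drop = FALSE]^2))
  2 * atan2(vec, abs(dq[, 1]))
}
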