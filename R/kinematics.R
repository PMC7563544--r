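#' Kinematic series with a unit tag
#'
#' Light container for a derived scalar waveform (linear speed, angular speed
#' or angular acceleration) sampled at a fixed rate.
#'
#' @param values numeric vector of samples.
#' @param unit one of `"m/s"`, `"deg/s"`, `"deg/s^2"`.
#' @param rate sampling rate in Hz.
#' @param sensor optional sensor label.
#' @param derivation how the series was obtained.
#' @return a numeric vector of class `kinematic_series` with attributes
#'   `unit`, `rate`, `sensor` and `derivation`.
#' @export
kinematic_series <- function(values, unit, rate, sensor = NA_character_,
                             derivation = NA_character_) {
  structure(as.numeric(values), class = "kinematic_series",
            unit = unit, rate = rate, sensor = sensor, derivation = derivation)
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %d samples @ %g Hz [%s]%s\n",
              length(x), attr(x, "rate"), attr(x, "unit"),
              if (is.na(attr(x, "sensor"))) "" else
                paste0(" sensor=", attr(x, "sensor"))))
  invisible(x)
}

# Central difference of a vector: second-order accurate in the interior,
# one-sided first-order at the two endpoints.  `h` is the sample spacing.
central_diff <- function(x, h) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  d <- numeric(n)
  if (n == 2L) {
    d[] <- (x[2L] - x[1L]) / h
    return(d)
  }
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * h)
  d[1L] <- (x[2L] - x[1L]) / h
  d[n] <- (x[n] - x[n - 1L]) / h
  d
}

#' Linear speed from a 3-D position series
#'
#' Velocity by central differences (one-sided at the endpoints), then the
#' Euclidean norm per frame.  Length is preserved.
#'
#' @param positions numeric matrix, frames x 3, in meters.
#' @param rate sampling rate in Hz.
#' @param sensor optional sensor label carried on the result.
#' @return [kinematic_series] in m/s.
#' @export
linear_speed <- function(positions, rate, sensor = NA_character_) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be a frames x 3 matrix")
  if (nrow(positions) < 2L) stop("need at least 2 frames")
  if (!all(is.finite(positions))) stop("non-finite positions")
  h <- 1 / rate
  v <- vapply(1:3, function(k) central_diff(positions[, k], h),
              numeric(nrow(positions)))
  kinematic_series(sqrt(rowSums(v^2)), "m/s", rate, sensor, "linear_speed")
}

#' Angular speed from a unit-quaternion orientation series
#'
#' Sign continuity is enforced first (q and -q encode the same rotation).
#' For interior frames the rotation angle between frames t-1 and t+1 is taken
#' over a 2-frame window (the analogue of a central difference); endpoints
#' use the single adjacent interval.  The magnitude of the rotation rate is
#' returned in deg/s.
#'
#' @param quats numeric matrix, frames x 4, scalar-first quaternions.
#' @param rate sampling rate in Hz.
#' @param sensor optional sensor label.
#' @return [kinematic_series] in deg/s, same length as the input.
#' @export
angular_speed_from_quaternions <- function(quats, rate,
                                           sensor = NA_character_) {
  quats <- as.matrix(quats)
  if (ncol(quats) != 4L) stop("quats must be a frames x 4 matrix")
  n <- nrow(quats)
  if (n < 2L) stop("need at least 2 frames")
  if (!all(is.finite(quats))) stop("non-finite quaternions")
  q <- quat_sign_continuity(quat_normalize(quats))
  h <- 1 / rate
  w <- numeric(n)
  if (n >= 3L) {
    ang <- quat_relative_angle(q[1:(n - 2L), , drop = FALSE],
                               q[3:n, , drop = FALSE])
    w[2:(n - 1L)] <- ang / (2 * h)
  }
  w[1L] <- quat_relative_angle(q[1L, , drop = FALSE],
                               q[2L, , drop = FALSE]) / h
  w[n] <- quat_relative_angle(q[n - 1L, , drop = FALSE],
                              q[n, , drop = FALSE]) / h
  kinematic_series(w * 180 / pi, "deg/s", rate, sensor, "angular_speed")
}

#' Angular acceleration as the rate of change of angular speed
#'
#' The scalar angular acceleration is taken as d|omega|/dt: the derivative of
#' the angular speed waveform (central differences interior, one-sided ends).
#' `mode = "magnitude"` returns its absolute value, which for a fixed-axis
#' rotation equals |d omega/dt|; spike extraction operates on the magnitude.
#'
#' @param ang_speed [kinematic_series] in deg/s (or numeric vector with
#'   `rate` supplied).
#' @param rate sampling rate in Hz; defaults to the series' own rate.
#' @param mode `"signed"` (default) or `"magnitude"`.
#' @return [kinematic_series] in deg/s^2.
#' @export
angular_acceleration <- function(ang_speed, rate = attr(ang_speed, "rate"),
                                 mode = c("signed", "magnitude")) {
  mode <- match.arg(mode)
  if (length(ang_speed) < 3L) stop("need at least 3 samples")
  if (is.null(rate)) stop("rate must be supplied")
  a <- central_diff(as.numeric(ang_speed), 1 / rate)
  if (mode == "magnitude") a <- abs(a)
  kinematic_series(a, "deg/s^2", rate, attr(ang_speed, "sensor") %||% NA_character_,
                   "angular_acceleration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
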