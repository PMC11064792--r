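#' Accelerometer bias + scale calibration
#'
#' @param bias 3-vector, g.
#' @param scale 3-vector of positive diagonal scale factors.
#' @return Object of class `accel_calibration`.
#' @export
accel_calibration <- function(bias, scale) {
  stopifnot(length(bias) == 3, length(scale) == 3)
  if (any(scale <= 0)) stop("scale components must be > 0")
  structure(list(bias = as.numeric(bias), scale = as.numeric(scale)),
            class = "accel_calibration")
}

#' Fit accelerometer bias and diagonal scale from static poses
#'
#' Classic six-pose least squares: each static pose contributes its mean
#' acceleration vector `a`, and the calibration (bias `b`, scale `s`) is the
#' axis-aligned ellipsoid fit `sum_i s_i^2 (a_i - b_i)^2 = 1`, solved as a
#' linear least-squares problem in the algebraic parameters. Requires at
#' least 6 poses in distinct orientations for identifiability.
#'
#' @param static_poses List of `imu_series`, each a static recording.
#' @return An [accel_calibration()].
#' @export
fit_accel_calibration <- function(static_poses) {
  if (length(static_poses) < 6)
    stop("need >= 6 static poses with distinct orientations; got ",
         length(static_poses))
  A <- t(vapply(static_poses, function(s) {
    stopifnot(inherits(s, "imu_series"))
    c(mean(s$ax), mean(s$ay), mean(s$az))
  }, numeric(3)))
  X <- cbind(A[, 1]^2, A[, 2]^2, A[, 3]^2, A[, 1], A[, 2], A[, 3])
  qrX <- qr(X)
  if (qrX$rank < 6)
    stop("degenerate pose set: orientations do not identify bias and scale")
  p <- qr.coef(qrX, rep(1, nrow(X)))
  alpha <- p[1:3]; beta <- p[4:6]
  if (any(alpha <= 0))
    stop("degenerate pose set: fitted quadric is not an ellipsoid")
  bias <- -beta / (2 * alpha)
  c0 <- 1 + sum(beta^2 / (4 * alpha))
  if (c0 <= 0) stop("degenerate pose set: non-positive ellipsoid constant")
  accel_calibration(bias = bias, scale = sqrt(alpha / c0))
}

#' Apply an accelerometer calibration to a series
#'
#' Corrects each accelerometer sample as `scale * (a - bias)`; gyro channels
#' are untouched.
#'
#' @param series An `imu_series`.
#' @param cal An `accel_calibration`.
#' @return Corrected `imu_series`.
#' @export
apply_accel_calibration <- function(series, cal) {
  stopifnot(inherits(series, "imu_series"), inherits(cal, "accel_calibration"))
  imu_series(series$t,
             ax = cal$scale[1] * (series$ax - cal$bias[1]),
             ay = cal$scale[2] * (series$ay - cal$bias[2]),
             az = cal$scale[3] * (series$az - cal$bias[3]),
             gx = series$gx, gy = series$gy, gz = series$gz,
             nominal_rate = series$nominal_rate)
}

#' Overlapping Allan deviation of a rate signal
#'
#' Characterises gyroscope noise: on a log-log plot of deviation versus
#' cluster time tau, white (angle random walk) noise shows slope -1/2 and
#' rate random walk slope +1/2. Cluster times are log-spaced from `2/rate`
#' up to one ninth of the record duration.
#'
#' @param x Numeric rate samples (e.g. a gyro channel, deg/s).
#' @param rate Sampling rate, Hz.
#' @param n_taus Number of cluster times.
#' @return Object of class `allan_curve` with `taus` (s) and `adev` (same
#'   units as `x`).
#' @export
allan_deviation <- function(x, rate, n_taus = 30) {
  n <- length(x)
  m_max <- floor(n / 9)
  if (m_max < 2)
    stop("series too short for Allan analysis: need >= 18 samples, got ", n)
  ms <- unique(round(exp(seq(log(2), log(m_max), length.out = n_taus))))
  cs <- c(0, cumsum(x))
  adev <- vapply(ms, function(m) {
    # overlapping cluster means
    ybar <- (cs[(m + 1):(n + 1)] - cs[1:(n - m + 1)]) / m
    d <- ybar[(m + 1):length(ybar)] - ybar[1:(length(ybar) - m)]
    sqrt(mean(d^2) / 2)
  }, numeric(1))
  structure(list(taus = ms / rate, adev = adev), class = "allan_curve")
}

#' @export
print.allan_curve <- function(x, ...) {
  cat(sprintf("<allan_curve> %d cluster times, tau %.3g-%.3g s\n",
              length(x$taus), min(x$taus), max(x$taus)))
  invisible(x)
}

#' Read / write a calibration JSON file
#'
#' Format: `{"bias": [..3..], "scale": [..3..]}`.
#'
#' @param cal An `accel_calibration`.
#' @param path File path.
#' @return `write_calibration` returns the path invisibly;
#'   `read_calibration` returns an `accel_calibration`.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "accel_calibration"))
  jsonlite::write_json(list(bias = cal$bias, scale = cal$scale), path,
                       digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  accel_calibration(j$bias, j$scale)
}
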