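#' Shape-preserving cubic interpolation onto a uniform grid
#'
#' Piecewise cubic Hermite (PCHIP) interpolation of every channel onto a
#' uniform grid at `rate` Hz spanning `[t[1], t[n]]`. Monotone segments stay
#' monotone (no overshoot) and knot values are reproduced exactly.
#'
#' @param series An `imu_series` with strictly increasing timestamps
#'   (see [clean_timestamps()]).
#' @param rate Target rate, Hz; defaults to the series' nominal rate.
#' @return An `imu_series` on the uniform grid.
#' @export
interpolate_pchip <- function(series, rate = series$nominal_rate) {
  stopifnot(inherits(series, "imu_series"))
  if (length(series$t) < 2)
    stop("need at least 2 samples to interpolate, got ", length(series$t))
  series <- clean_timestamps(series)
  t <- series$t
  grid <- t[1] + (seq_len(floor((t[length(t)] - t[1]) * rate + 1e-9) + 1) - 1) / rate
  q <- function(y) pracma::pchip(t, y, grid)
  imu_series(grid, q(series$ax), q(series$ay), q(series$az),
             q(series$gx), q(series$gy), q(series$gz), nominal_rate = rate)
}

.check_uniform <- function(t, rate) {
  if (length(t) > 1 && max(abs(diff(t) - 1 / rate)) > 1e-6)
    stop("series must be uniformly sampled at the nominal rate")
}

# zero-phase (forward-backward) IIR application with odd-reflect padding of
# one settling length at each end
.filtfilt_reflect <- function(b, a, x) {
  n <- length(x)
  npad <- min(n - 1, max(3 * (length(a) - 1), 30))
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  xp <- c(pre, x, post)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a digital Butterworth low-pass and applies it forward and backward
#' (zero phase; the squared magnitude response) to every channel, with
#' odd-reflection edge padding.
#'
#' @param series An `imu_series` on a uniform grid.
#' @param cutoff Cut-off frequency, Hz (0 < cutoff < rate/2).
#' @param order Filter order (default 2).
#' @return Filtered `imu_series`.
#' @export
butterworth_lowpass <- function(series, cutoff = 10, order = 2) {
  stopifnot(inherits(series, "imu_series"))
  rate <- series$nominal_rate
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("cutoff must satisfy 0 < cutoff < rate/2 = ", rate / 2, " Hz")
  .check_uniform(series$t, rate)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  f <- function(y) .filtfilt_reflect(bf$b, bf$a, y)
  imu_series(series$t, f(series$ax), f(series$ay), f(series$az),
             f(series$gx), f(series$gy), f(series$gz), nominal_rate = rate)
}

# scalar local-level (random walk state) Kalman filter; optional zero-phase
# RTS smoothing pass
.kalman1 <- function(z, q, r, smooth = TRUE) {
  n <- length(z)
  if (n == 0) return(z)
  xf <- numeric(n); Pf <- numeric(n)
  xf[1] <- z[1]; Pf[1] <- r
  for (k in seq_len(n - 1) + 1) {
    Pp <- Pf[k - 1] + q
    K <- Pp / (Pp + r)
    xf[k] <- xf[k - 1] + K * (z[k] - xf[k - 1])
    Pf[k] <- (1 - K) * Pp
  }
  if (!smooth) return(xf)
  xs <- xf
  for (k in (n - 1):1) {
    if (k < 1) break
    C <- Pf[k] / (Pf[k] + q)
    xs[k] <- xf[k] + C * (xs[k + 1] - xf[k])
  }
  xs
}

# measurement-noise sd estimated from second differences, which a smooth
# band-limited oscillation contributes little to (unlike first differences)
.noise_sd_est <- function(x) {
  if (length(x) < 3) return(0)
  stats::mad(diff(x, differences = 2)) / sqrt(6)
}

#' Scalar Kalman smoothing of each channel
#'
#' Per-channel local-level (random-walk state) Kalman filter with gain
#' `K = P/(P+r)`, followed by a fixed-interval (RTS) smoothing pass so the
#' result is zero-phase. With `q` large relative to `r` the filter trusts the
#' measurements and returns (approximately) the input.
#'
#' @param series An `imu_series` on a uniform grid.
#' @param q Process-noise variance; default `1e-2 * var(channel)`.
#' @param r Measurement-noise variance; default estimated per channel from
#'   the median absolute second difference.
#' @param smooth Apply the backward smoothing pass (default TRUE).
#' @return Smoothed `imu_series`.
#' @export
kalman_smooth <- function(series, q = NULL, r = NULL, smooth = TRUE) {
  stopifnot(inherits(series, "imu_series"))
  .check_uniform(series$t, series$nominal_rate)
  if (!is.null(q) && q <= 0) stop("q must be > 0")
  if (!is.null(r) && r <= 0) stop("r must be > 0")
  f <- function(y) {
    qe <- if (is.null(q)) max(1e-2 * stats::var(y), 1e-12) else q
    re <- if (is.null(r)) max(.noise_sd_est(y)^2, 1e-12) else r
    .kalman1(y, qe, re, smooth = smooth)
  }
  imu_series(series$t, f(series$ax), f(series$ay), f(series$az),
             f(series$gx), f(series$gy), f(series$gz),
             nominal_rate = series$nominal_rate)
}

#' Condition one raw block segment
#'
#' The full chain: PCHIP interpolation onto the uniform grid, zero-phase
#' second-order Butterworth low-pass (10 Hz default), scalar Kalman
#' smoothing. Provenance of applied steps is recorded on the result.
#'
#' @param raw An `imu_series` segment (from [segment_blocks()]).
#' @param cutoff_hz,order Butterworth parameters.
#' @param q,r Kalman parameters (NULL = per-channel defaults).
#' @param block_s Nominal block duration carried for metric extraction.
#' @return A `wrist_block_series`: an `imu_series` with attributes
#'   `provenance`, `block` and `block_s`.
#' @export
preprocess_block <- function(raw, cutoff_hz = 10, order = 2, q = NULL,
                             r = NULL, block_s = NULL) {
  stopifnot(inherits(raw, "imu_series"))
  if (length(raw$t) < 2)
    stop("segment too short to preprocess: ", length(raw$t), " samples")
  out <- interpolate_pchip(raw)
  out <- butterworth_lowpass(out, cutoff = cutoff_hz, order = order)
  out <- kalman_smooth(out, q = q, r = r)
  attr(out, "provenance") <- c("pchip",
                               sprintf("butterworth(%d,%gHz)", order, cutoff_hz),
                               "kalman")
  attr(out, "block") <- attr(raw, "block")
  attr(out, "block_s") <- if (is.null(block_s))
    series_span(out) else block_s
  class(out) <- c("wrist_block_series", class(out))
  out
}

#' @export
print.wrist_block_series <- function(x, ...) {
  cat(sprintf("<wrist_block_series> block %s, %d samples @ %g Hz [%s]\n",
              as.character(attr(x, "block") %||% NA), length(x$t),
              x$nominal_rate, paste(attr(x, "provenance"), collapse = " -> ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
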