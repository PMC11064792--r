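sine_series <- function(f, n = 1000, rate = 50, amp = 1) {
  t <- (seq_len(n) - 1) / rate
  y <- amp * sin(2 * pi * f * t)
  imu_series(t, y, y, y, y, y, y, nominal_rate = rate)
}

# amplitude of a sinusoid at frequency f via least squares on sin/cos basis
fit_amp <- function(t, y, f) {
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  sqrt(sum(qr.coef(qr(X), y)^2))
}

test_that("PCHIP reproduces grid input, linears and monotone shape", {
  s <- sine_series(2)
  out <- interpolate_pchip(s)
  expect_equal(out$gy, s$gy, tolerance = 1e-10)
  expect_equal(out$t, s$t, tolerance = 1e-12)
  # irregular sampling of a linear channel is reproduced exactly
  t <- sort(c(0, runif(60, 0, 2), 2))
  lin <- 3 * t - 1
  s2 <- imu_series(t, lin, lin, lin, lin, lin, lin, nominal_rate = 50)
  out2 <- interpolate_pchip(s2)
  expect_equal(out2$gy, 3 * out2$t - 1, tolerance = 1e-9)
  # monotone input stays monotone (no overshoot)
  t3 <- c(0, 0.1, 0.5, 0.6, 1.4, 2)
  mono <- c(0, 0.1, 0.2, 3, 3.1, 3.2)
  s3 <- imu_series(t3, mono, mono, mono, mono, mono, mono, nominal_rate = 50)
  out3 <- interpolate_pchip(s3)
  expect_true(all(diff(out3$gy) >= -1e-12))
  expect_error(interpolate_pchip(flat_series(1)), "at least 2")
})

test_that("zero-phase Butterworth passes 1 Hz, blocks 20 Hz, keeps DC", {
  s1 <- butterworth_lowpass(sine_series(1), cutoff = 10, order = 2)
  expect_equal(fit_amp(s1$t, s1$gy, 1), 1, tolerance = 0.01)
  s20 <- butterworth_lowpass(sine_series(20), cutoff = 10, order = 2)
  expect_lt(fit_amp(s20$t, s20$gy, 20), 0.1)
  dc <- butterworth_lowpass(flat_series(500, value = 2.5), cutoff = 10)
  expect_equal(dc$gy, rep(2.5, 500), tolerance = 1e-9)
  expect_error(butterworth_lowpass(sine_series(1), cutoff = 25), "Nyquist|cutoff")
})

test_that("repeating the Butterworth stage barely changes a filtered signal", {
  s <- butterworth_lowpass(sine_series(2), cutoff = 10)
  s2 <- butterworth_lowpass(s, cutoff = 10)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(s2$gy) - rms(s$gy)) / rms(s$gy), 0.01)
})

test_that("Kalman smoothing behaves at its limits", {
  # constant input passes through
  k1 <- kalman_smooth(flat_series(300, value = 4), q = 0.1, r = 0.1)
  expect_equal(k1$gy[150:300], rep(4, 151), tolerance = 1e-6)
  # white noise with matched r loses variance
  set.seed(8)
  n <- 2000; t <- (seq_len(n) - 1) / 50
  z <- rnorm(n)
  s <- imu_series(t, z, z, z, z, z, z, nominal_rate = 50)
  k2 <- kalman_smooth(s, q = 0.01, r = 1)
  expect_lt(var(k2$gy), var(z))
  # huge q trusts the measurements
  k3 <- kalman_smooth(s, q = 1e8, r = 1)
  expect_equal(k3$gy, z, tolerance = 1e-3)
  expect_error(kalman_smooth(s, q = -1), "q")
  expect_error(kalman_smooth(s, r = 0), "r")
})

test_that("the full chain preserves a noiseless rotation signal", {
  p <- sim_params(theta_amp = 45, freq = 2, sustain_s = 20, seed = 1)
  s <- simulate_session(p)
  seg <- segment_blocks(s$right)[[1]]
  blk <- preprocess_block(seg)
  expect_identical(attr(blk, "provenance"),
                   c("pchip", "butterworth(2,10Hz)", "kalman"))
  analytic <- 45 * 2 * pi * 2 * cos(2 * pi * 2 * blk$t)
  expect_gt(cor(blk$gy, analytic), 0.999)
  # zero-phase chain: the first velocity peak stays within one sample
  expect_lt(abs(blk$t[which.max(blk$gy)] - 0), 1 / 50 + 1e-9)
})

test_that("degenerate segments are refused", {
  expect_error(preprocess_block(flat_series(1)), "too short")
})
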