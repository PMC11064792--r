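sine_block <- function(amp = 45, f = 2, dur = 20, rate = 50) {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  make_block(t, amp * 2 * pi * f * cos(2 * pi * f * t), rate)
}

test_that("a 2 Hz sine yields two angle extrema per cycle at the right times", {
  ext <- detect_angle_extrema(sine_block())
  expect_equal(ext$n_extrema, 80)
  analytic <- 0.125 + 0.25 * (0:79)
  expect_lt(max(abs(ext$times - analytic)), 0.010 + 1e-9)
  expect_true(all(diff(ext$times) > 0))
})

test_that("flat and half-cycle signals give 0 and 2 extrema", {
  flat <- make_block((0:999) / 50, rnorm(1000, 0, 0.5))
  expect_equal(detect_angle_extrema(flat)$n_extrema, 0)
  # plateau - swing - plateau: one half-cycle of rotation
  t <- (0:199) / 50
  gy <- numeric(200)
  mid <- t >= 1 & t < 1.25                      # fall from +45 to -45 deg
  gy[mid] <- -45 * (2 * pi * 2) * sin(2 * pi * 2 * (t[mid] - 1))
  half <- make_block(t, gy)
  expect_equal(detect_angle_extrema(half)$n_extrema, 2)
})

test_that("rotation amplitude matches the per-half-cycle swing", {
  ext <- detect_angle_extrema(sine_block())
  expect_equal(as.numeric(compute_rotation_amplitude(ext)), 90,
               tolerance = 0.02)
  # single-interval arithmetic
  expect_equal(compute_rotation_amplitude(make_ext(c(0, 0.25), c(10, -20))), 30)
  expect_equal(compute_rotation_amplitude(make_ext(c(0, 0.25), c(5, 5))), 0)
  # undefined below 2 extrema: 0 with a flag
  r <- compute_rotation_amplitude(make_ext(0.1, 5))
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "insufficient"))
})

test_that("rotation frequency comes from extrema counts", {
  ext <- detect_angle_extrema(sine_block())
  expect_equal(compute_rotation_frequency(ext), 2, tolerance = 0.04)
  expect_equal(compute_rotation_frequency(make_ext(numeric(0), numeric(0))), 0)
  expect_equal(compute_rotation_frequency(make_ext(0.3, 10)), 0)
  expect_equal(compute_rotation_frequency(make_ext(c(0, 0.25, 0.5),
                                                   c(45, -45, 45))), 2)
})

test_that("total rotation time tracks the active envelope", {
  expect_equal(compute_total_rotation_time(sine_block()), 20, tolerance = 0.2)
  t <- (0:999) / 50
  gy <- ifelse(t < 10, 400 * cos(2 * pi * 2 * t), 0)
  expect_equal(compute_total_rotation_time(make_block(t, gy)), 10,
               tolerance = 0.3)
  expect_equal(compute_total_rotation_time(make_block(t, rep(0, 1000))), 0)
})

test_that("symmetry follows the weighted-difference formula", {
  st <- function(roa, rof) list(roa = roa, rof = rof)
  expect_equal(compute_symmetry(st(90, 2), st(90, 2)), 1)
  expect_equal(compute_symmetry(st(100, 2), st(0, 0)), 0)
  expect_equal(compute_symmetry(st(80, 2), st(100, 2)), (1 - 0.7 * 0.2)^2)
  # symmetric in its arguments
  expect_equal(compute_symmetry(st(80, 1.9), st(100, 2)),
               compute_symmetry(st(100, 2), st(80, 1.9)))
  # zero-motion ratio convention: both zero -> no penalty from that term
  expect_equal(compute_symmetry(st(0, 0), st(0, 0)), 1)
})

test_that("symmetry is non-increasing in the amplitude gap at fixed frequency", {
  st <- function(roa, rof) list(roa = roa, rof = rof)
  gaps <- seq(0, 100, by = 5)
  vals <- vapply(gaps, function(g)
    compute_symmetry(st(100 - g, 2), st(100, 2)), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("amplitude is invariant to gyro sign flip and constant bias", {
  blk <- sine_block()
  roa0 <- as.numeric(compute_rotation_amplitude(detect_angle_extrema(blk)))
  flip <- make_block(blk$t, -blk$gy)
  expect_equal(as.numeric(compute_rotation_amplitude(detect_angle_extrema(flip))),
               roa0, tolerance = 1e-9)
  biased <- make_block(blk$t, blk$gy + 25)
  expect_equal(as.numeric(compute_rotation_amplitude(detect_angle_extrema(biased))),
               roa0, tolerance = 0.02)
})

test_that("extrema-to-extrema angles equal direct integrals of the rate", {
  set.seed(2)
  blk <- make_block((0:999) / 50,
                    45 * 2 * pi * 2 * cos(2 * pi * 2 * (0:999) / 50) +
                      rnorm(1000, 0, 10))
  ext <- detect_angle_extrema(blk)
  gy0 <- blk$gy - mean(blk$gy)
  direct <- vapply(seq_len(ext$n_extrema - 1), function(i) {
    sel <- blk$t >= ext$times[i] & blk$t <= ext$times[i + 1]
    abs(pracma::trapz(blk$t[sel], gy0[sel]))
  }, numeric(1))
  expect_equal(mean(direct), as.numeric(compute_rotation_amplitude(ext)),
               tolerance = 1e-6)
})

test_that("metric recovery stays unbiased across the noise sweep", {
  for (sd in c(0, 10, 20)) {
    set.seed(100 + sd)
    t <- (0:999) / 50
    blk <- make_block(t, 45 * 2 * pi * 2 * cos(2 * pi * 2 * t) + rnorm(1000, 0, sd))
    ext <- detect_angle_extrema(blk)
    expect_lt(abs(as.numeric(compute_rotation_amplitude(ext)) - 90) / 90, 0.05)
    expect_lt(abs(compute_rotation_frequency(ext) - 2) / 2, 0.02)
  }
})

test_that("session features aggregate as the max over blocks", {
  p <- sim_params(theta_amp = 50, freq = 2, sustain_s = 15,
                  lr_amp_ratio = 0.8, lr_freq_ratio = 0.9, seed = 4)
  s <- simulate_session(p, group = "ASD", id = "F1", age_months = 50)
  f <- extract_features(s)
  expect_equal(f$trt, max(f$blocks$trt))
  expect_equal(f$roa, max(f$blocks$roa))
  expect_equal(f$symmetry, max(f$blocks$symmetry))
  expect_false(f$low_motion)
  # recovery of the generating parameters
  expect_equal(f$trt, 15, tolerance = 15 * 0.06)
  expect_equal(f$roa, 100, tolerance = 100 * 0.03)
  pred_sym <- (1 - 0.7 * 0.2 - 0.3 * 0.1)^2
  expect_equal(f$symmetry, pred_sym, tolerance = 0.03)
})

test_that("identical wrists give symmetry 1 in every block", {
  p <- sim_params(theta_amp = 45, freq = 2, sustain_s = 20, seed = 6)
  f <- extract_features(simulate_session(p, id = "SYM"))
  expect_equal(f$blocks$symmetry, rep(1, 3), tolerance = 1e-6)
})

test_that("a motionless session is flagged as low motion", {
  p <- sim_params(theta_amp = 45, freq = 2, sustain_s = 20,
                  gyro_noise_sd = 2, seed = 9)
  s <- simulate_session(p, id = "LOW")
  quiet <- function(x) imu_series(x$t, x$ax, x$ay, x$az, x$gx,
                                  rnorm(length(x$t), 0, 2), x$gz,
                                  nominal_rate = x$nominal_rate)
  s$left <- quiet(s$left); s$right <- quiet(s$right)
  f <- extract_features(s)
  expect_true(f$low_motion)
  expect_equal(c(f$trt, f$roa, f$symmetry), c(0, 0, 0))
})
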