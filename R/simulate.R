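#' Simulation parameters for one synthetic WRI session
#'
#' The simulated wrist angle during each imitation block is
#' `theta(t) = theta_amp * w(t) * sin(2*pi*freq*t)` (degrees), where the
#' envelope `w(t)` is 1 while the participant sustains the rotation
#' (`t < sustain_s`) and ramps to 0 over 1 s with a raised cosine. The gyro
#' y channel is the analytic derivative plus bias and Gaussian noise; the
#' accelerometer reports the gravity vector re-projected through the rotation
#' about the y axis plus noise. The non-dominant (left) wrist rotates with
#' amplitude `theta_amp * lr_amp_ratio` and frequency `freq * lr_freq_ratio`.
#'
#' @param theta_amp Peak rotation angle, degrees (> 0).
#' @param freq Rotation frequency, Hz (~2 in the protocol).
#' @param sustain_s Seconds of sustained rotation within a block
#'   (0 < sustain_s <= block duration).
#' @param lr_amp_ratio,lr_freq_ratio Left/right amplitude and frequency
#'   ratios, each in (0, 1].
#' @param gyro_noise_sd Gyro white-noise sd, deg/s.
#' @param accel_noise_sd Accelerometer white-noise sd, g.
#' @param gyro_bias Constant gyro bias, deg/s.
#' @param seed Optional integer seed; given a seed the session is fully
#'   deterministic.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(theta_amp = 45, freq = 2, sustain_s = 20,
                       lr_amp_ratio = 1, lr_freq_ratio = 1,
                       gyro_noise_sd = 0, accel_noise_sd = 0,
                       gyro_bias = 0, seed = NULL) {
  if (theta_amp <= 0) stop("theta_amp must be > 0")
  if (freq <= 0) stop("freq must be > 0")
  if (sustain_s <= 0) stop("sustain_s must be > 0")
  if (lr_amp_ratio <= 0 || lr_amp_ratio > 1 ||
      lr_freq_ratio <= 0 || lr_freq_ratio > 1)
    stop("lr ratios must lie in (0, 1]")
  if (gyro_noise_sd < 0 || accel_noise_sd < 0) stop("noise sds must be >= 0")
  structure(list(theta_amp = theta_amp, freq = freq, sustain_s = sustain_s,
                 lr_amp_ratio = lr_amp_ratio, lr_freq_ratio = lr_freq_ratio,
                 gyro_noise_sd = gyro_noise_sd, accel_noise_sd = accel_noise_sd,
                 gyro_bias = gyro_bias, seed = seed), class = "sim_params")
}

# run expr under a local RNG stream, restoring the caller's stream after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# envelope: 1 up to sustain, raised-cosine ramp to 0 over the next second
.envelope <- function(tau, sustain) {
  w <- numeric(length(tau))
  w[tau < sustain] <- 1
  ramp <- tau >= sustain & tau < sustain + 1
  w[ramp] <- 0.5 * (1 + cos(pi * (tau[ramp] - sustain)))
  w
}

.envelope_deriv <- function(tau, sustain) {
  dw <- numeric(length(tau))
  ramp <- tau >= sustain & tau < sustain + 1
  dw[ramp] <- -0.5 * pi * sin(pi * (tau[ramp] - sustain))
  dw
}

# analytic angle (deg) and angular velocity (deg/s) over a full session grid,
# zero during rest periods
.wrist_kinematics <- function(t, amp, freq, sustain, schedule) {
  theta <- numeric(length(t))
  omega <- numeric(length(t))
  cyc <- schedule$block_s + schedule$rest_s
  for (k in seq_len(schedule$n_blocks)) {
    start <- (k - 1) * cyc
    inb <- t >= start & t < start + schedule$block_s
    tau <- t[inb] - start
    w <- .envelope(tau, sustain)
    dw <- .envelope_deriv(tau, sustain)
    ph <- 2 * pi * freq * tau
    theta[inb] <- amp * w * sin(ph)
    omega[inb] <- amp * (dw * sin(ph) + w * 2 * pi * freq * cos(ph))
  }
  list(theta = theta, omega = omega)
}

#' Simulate one dual-wrist WRI session
#'
#' Deterministic given `params$seed`. Rest periods contain sensor noise only.
#'
#' @param params A [sim_params()] object.
#' @param schedule A [protocol_schedule()].
#' @param group `"TD"` or `"ASD"` label carried on the session.
#' @param id Participant id string.
#' @param age_months Age recorded in the sidecar metadata.
#' @return A [session_recording()].
#' @export
simulate_session <- function(params, schedule = protocol_schedule(),
                             group = "TD", id = "S001", age_months = 60) {
  stopifnot(inherits(params, "sim_params"))
  if (params$sustain_s > schedule$block_s)
    stop("sustain_s must not exceed the block duration")
  rate <- 50
  n <- round(protocol_span(schedule) * rate)
  t <- (seq_len(n) - 1) / rate
  with_seed(params$seed, {
    mk_wrist <- function(amp, freq) {
      kin <- .wrist_kinematics(t, amp, freq, params$sustain_s, schedule)
      th <- kin$theta * pi / 180
      gy <- kin$omega + params$gyro_bias +
        stats::rnorm(n, 0, params$gyro_noise_sd)
      noise3 <- function() stats::rnorm(n, 0, params$accel_noise_sd)
      imu_series(t,
                 ax = sin(th) + noise3(), ay = noise3(), az = cos(th) + noise3(),
                 gx = stats::rnorm(n, 0, params$gyro_noise_sd), gy = gy,
                 gz = stats::rnorm(n, 0, params$gyro_noise_sd),
                 nominal_rate = rate)
    }
    right <- mk_wrist(params$theta_amp, params$freq)
    left <- mk_wrist(params$theta_amp * params$lr_amp_ratio,
                     params$freq * params$lr_freq_ratio)
    session_recording(id, group, age_months, left = left, right = right,
                      schedule = schedule)
  })
}

#' Default group presets for the cohort simulator
#'
#' Mean kinematic parameters per group, with log-normal coefficients of
#' variation for between-participant spread. TD children sustain the full
#' block at large amplitude with near-symmetric wrists; ASD children sustain
#' about half the block at lower amplitude with weaker symmetry. Sustain
#' draws are capped at the block duration, so both groups' sustain CVs
#' jointly set the spread of total rotation time; they were calibrated so
#' that the simulated Cohen's d on total rotation time is about -1.6
#' (ASD - TD) under default sensor noise, and then fixed.
#'
#' @return Named list with `TD` and `ASD` preset lists.
#' @export
default_group_presets <- function() {
  list(
    TD = list(sustain = 20, sustain_cv = 0.45, theta = 60, theta_cv = 0.25,
              amp_ratio = 0.95, freq_ratio = 0.95, ratio_cv = 0.04,
              freq = 2, freq_cv = 0.05,
              gyro_noise_sd = 8, accel_noise_sd = 0.02, bias_sd = 1),
    ASD = list(sustain = 10, sustain_cv = 0.8, theta = 40, theta_cv = 0.25,
               amp_ratio = 0.75, freq_ratio = 0.75, ratio_cv = 0.12,
               freq = 2, freq_cv = 0.05,
               gyro_noise_sd = 8, accel_noise_sd = 0.02, bias_sd = 1)
  )
}

# log-normal draw parameterised by arithmetic mean and CV
rlnorm_mean <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# draw one participant's sim_params from a group preset
draw_params <- function(preset, block_s, seed) {
  with_seed(seed, {
    sim_params(
      theta_amp = .clip(rlnorm_mean(1, preset$theta, preset$theta_cv), 5, 170),
      freq = .clip(rlnorm_mean(1, preset$freq, preset$freq_cv), 0.5, 5),
      sustain_s = .clip(rlnorm_mean(1, preset$sustain, preset$sustain_cv),
                        0.5, block_s),
      lr_amp_ratio = .clip(rlnorm_mean(1, preset$amp_ratio, preset$ratio_cv),
                           0.05, 1),
      lr_freq_ratio = .clip(rlnorm_mean(1, preset$freq_ratio, preset$ratio_cv),
                            0.05, 1),
      gyro_noise_sd = preset$gyro_noise_sd,
      accel_noise_sd = preset$accel_noise_sd,
      gyro_bias = stats::rnorm(1, 0, preset$bias_sd),
      seed = seed + 1L
    )
  })
}

#' Simulate a 2 (group) x 3 (age band) cohort
#'
#' Per-participant parameters are drawn log-normally around the group preset
#' means; ages are uniform within each one-year band. Deterministic given
#' `seed`.
#'
#' @param n_per_cell Participants per group-by-age-band cell (6 cells).
#' @param presets As returned by [default_group_presets()].
#' @param schedule A [protocol_schedule()].
#' @param seed Integer master seed; every participant derives a sub-seed.
#' @return List with `sessions` (list of [session_recording()]) and `meta`
#'   (data.frame of participant_id, group, age_months, age_band).
#' @export
simulate_cohort <- function(n_per_cell = 18, presets = default_group_presets(),
                            schedule = protocol_schedule(), seed = 1) {
  bands <- list("3.5-4.5y" = c(42, 54), "4.5-5.5y" = c(54, 66),
                "5.5-6.5y" = c(66, 78))
  sessions <- list()
  meta <- list()
  idx <- 0L
  for (grp in c("ASD", "TD")) {
    for (b in names(bands)) {
      for (i in seq_len(n_per_cell)) {
        idx <- idx + 1L
        sub <- (as.integer(seed) + 7919L * idx) %% 2147483647L
        age <- with_seed(sub + 5L,
                         stats::runif(1, bands[[b]][1], bands[[b]][2]))
        p <- draw_params(presets[[grp]], schedule$block_s, sub)
        id <- sprintf("%s%03d", grp, idx)
        sessions[[idx]] <- simulate_session(p, schedule, group = grp, id = id,
                                            age_months = age)
        meta[[idx]] <- data.frame(participant_id = id, group = grp,
                                  age_months = age,
                                  age_band = b, stringsAsFactors = FALSE)
      }
    }
  }
  list(sessions = sessions, meta = do.call(rbind, meta))
}
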