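# shared fixtures built in code

# a wrist_block_series directly from t / gy, bypassing preprocessing
make_block <- function(t, gy, rate = 50) {
  n <- length(t)
  s <- imu_series(t, rep(0, n), rep(0, n), rep(1, n),
                  rep(0, n), gy, rep(0, n), nominal_rate = rate)
  attr(s, "block_s") <- diff(range(t)) + 1 / rate
  class(s) <- c("wrist_block_series", class(s))
  s
}

# an extrema_sequence with given times/angles (for arithmetic checks)
make_ext <- function(times, angles) {
  structure(list(times = times, angles = angles, n_extrema = length(times),
                 t = times, angle = angles), class = "extrema_sequence")
}

# a flat imu_series of n samples
flat_series <- function(n = 100, rate = 50, value = 0) {
  t <- (seq_len(n) - 1) / rate
  imu_series(t, rep(value, n), rep(0, n), rep(1, n),
             rep(0, n), rep(value, n), rep(0, n), nominal_rate = rate)
}

# static accelerometer pose with direction v, distorted by bias b / scale s
static_pose <- function(v, bias = c(0, 0, 0), scale = c(1, 1, 1), n = 50) {
  v <- v / sqrt(sum(v^2))
  a <- v / scale + bias
  t <- (seq_len(n) - 1) / 50
  imu_series(t, rep(a[1], n), rep(a[2], n), rep(a[3], n),
             rep(0, n), rep(0, n), rep(0, n), nominal_rate = 50)
}

six_poses <- function(bias = c(0, 0, 0), scale = c(1, 1, 1)) {
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1), c(1, 1, 1))
  lapply(dirs, static_pose, bias = bias, scale = scale)
}

# small balanced 2x3 factorial data set with optional group shift
factorial_data <- function(n_per_cell = 15, group_shift = 0, age_shift = 0) {
  d <- expand.grid(i = seq_len(n_per_cell), group = c("ASD", "TD"),
                   age_band = c("a", "b", "c"))
  d$y <- stats::rnorm(nrow(d)) +
    ifelse(d$group == "ASD", group_shift, 0) +
    age_shift * as.integer(factor(d$age_band))
  d
}

# linearly separable feature table for classifier tests
separable_features <- function(n = 20) {
  data.frame(
    participant_id = sprintf("P%03d", seq_len(2 * n)),
    group = rep(c("ASD", "TD"), each = n),
    trt_s = c(stats::rnorm(n, 5, 0.5), stats::rnorm(n, 18, 0.5)),
    roa_deg = c(stats::rnorm(n, 60, 3), stats::rnorm(n, 120, 3)),
    symmetry = c(stats::rnorm(n, 0.5, 0.03), stats::rnorm(n, 0.95, 0.02)),
    stringsAsFactors = FALSE)
}
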