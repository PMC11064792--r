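#' Six-channel inertial time series
#'
#' Container for one wrist sensor's recording: timestamps, three-axis linear
#' acceleration (in g) and three-axis angular velocity (in deg/s). The y gyro
#' axis (`gy`) is the wrist pronation/supination axis used by the rotation
#' metrics.
#'
#' @param t Numeric vector of timestamps in seconds, monotone non-decreasing.
#' @param ax,ay,az Linear acceleration channels in g.
#' @param gx,gy,gz Angular velocity channels in deg/s.
#' @param nominal_rate Nominal sampling rate in Hz (default 50).
#' @return An object of class `imu_series`.
#' @export
imu_series <- function(t, ax, ay, az, gx, gy, gz, nominal_rate = 50) {
  chans <- list(t = t, ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz)
  lens <- vapply(chans, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all channels must have equal length; got ",
         paste(names(lens), lens, sep = "=", collapse = ", "))
  for (nm in names(chans)) {
    if (!is.numeric(chans[[nm]]))
      stop("channel '", nm, "' must be numeric")
  }
  if (any(diff(t) < 0)) stop("timestamps must be monotone non-decreasing")
  if (!is.numeric(nominal_rate) || nominal_rate <= 0)
    stop("nominal_rate must be > 0")
  structure(c(chans, list(nominal_rate = nominal_rate)), class = "imu_series")
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> %d samples, %.2f-%.2f s, nominal %g Hz\n",
              length(x$t), if (length(x$t)) min(x$t) else NA,
              if (length(x$t)) max(x$t) else NA, x$nominal_rate))
  invisible(x)
}

#' Deduplicate timestamps (keep first occurrence)
#'
#' Interpolation requires strictly increasing time; duplicated stamps are
#' dropped keeping the first sample of each run.
#'
#' @param series An `imu_series`.
#' @return An `imu_series` with strictly increasing `t`.
#' @export
clean_timestamps <- function(series) {
  stopifnot(inherits(series, "imu_series"))
  keep <- !duplicated(series$t)
  if (all(keep)) return(series)
  imu_series(series$t[keep], series$ax[keep], series$ay[keep], series$az[keep],
             series$gx[keep], series$gy[keep], series$gz[keep],
             nominal_rate = series$nominal_rate)
}

#' Imitation protocol schedule
#'
#' The task structure: `n_blocks` imitation blocks of `block_s` seconds each,
#' separated by `rest_s` seconds of rest. Default is the three-block protocol
#' (20 s imitation, 10 s rest).
#'
#' @param n_blocks Number of imitation blocks (>= 1).
#' @param block_s Imitation block duration, seconds.
#' @param rest_s Rest duration between blocks, seconds.
#' @return An object of class `protocol_schedule`.
#' @export
protocol_schedule <- function(n_blocks = 3, block_s = 20, rest_s = 10) {
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (block_s <= 0 || rest_s <= 0) stop("durations must be > 0")
  structure(list(n_blocks = as.integer(n_blocks), block_s = block_s,
                 rest_s = rest_s), class = "protocol_schedule")
}

#' Total protocol span in seconds (first block onset to last block end)
#' @param schedule A `protocol_schedule`.
#' @return Seconds.
#' @export
protocol_span <- function(schedule) {
  with(schedule, n_blocks * block_s + (n_blocks - 1) * rest_s)
}

#' One participant's dual-wrist session
#'
#' @param participant_id Character id.
#' @param group `"ASD"` or `"TD"`.
#' @param age_months Chronological age in months. Ages outside the study range
#'   42-78 months (3.5-6.5 y) trigger a warning, not an error.
#' @param left,right `imu_series` for each wrist.
#' @param schedule A `protocol_schedule`.
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(participant_id, group, age_months, left, right,
                              schedule = protocol_schedule()) {
  group <- match.arg(group, c("ASD", "TD"))
  if (!inherits(left, "imu_series") || !inherits(right, "imu_series"))
    stop("both wrists must be imu_series objects")
  if (!inherits(schedule, "protocol_schedule"))
    stop("schedule must be a protocol_schedule")
  if (!is.numeric(age_months) || length(age_months) != 1L || age_months <= 0)
    stop("age_months must be a positive scalar")
  if (age_months < 42 || age_months > 78)
    warning("age_months ", age_months, " outside the study range [42, 78]")
  structure(list(participant_id = as.character(participant_id), group = group,
                 age_months = age_months, left = left, right = right,
                 schedule = schedule), class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %s (%s, %.1f mo): L %d / R %d samples, %d blocks\n",
              x$participant_id, x$group, x$age_months,
              length(x$left$t), length(x$right$t), x$schedule$n_blocks))
  invisible(x)
}

#' Age band for the 3.5-6.5 y cohort
#'
#' Deterministic mapping of age in months to the three one-year bands used in
#' the factorial design.
#'
#' @param age_months Numeric vector of ages in months.
#' @return Factor with levels `"3.5-4.5y"`, `"4.5-5.5y"`, `"5.5-6.5y"`.
#' @export
age_band <- function(age_months) {
  cut(age_months, breaks = c(-Inf, 54, 66, Inf),
      labels = c("3.5-4.5y", "4.5-5.5y", "5.5-6.5y"), right = FALSE)
}

# span of a series measured inclusive of one sample period, so that an
# "80 s" recording of 4000 samples at 50 Hz (stamps 0..79.98) counts as 80 s
series_span <- function(series) {
  diff(range(series$t)) + 1 / series$nominal_rate
}

#' Cut a wrist series into per-block segments
#'
#' Block k (1-based) covers the half-open window
#' `[(k-1)*(block_s+rest_s), (k-1)*(block_s+rest_s) + block_s)` seconds after
#' the first sample (the recording is assumed to start at block-1 onset).
#' Trailing samples beyond the last block are ignored. The series span is
#' measured inclusive of one nominal sample period.
#'
#' @param series An `imu_series`.
#' @param schedule A `protocol_schedule`.
#' @return List of `imu_series` segments, one per block, each carrying a
#'   `block` attribute and times re-zeroed to block onset.
#' @export
segment_blocks <- function(series, schedule = protocol_schedule()) {
  stopifnot(inherits(series, "imu_series"))
  need <- protocol_span(schedule)
  have <- series_span(series)
  if (have < need - 1e-9)
    stop(sprintf("series too short for schedule: spans %.2f s, needs %.2f s (%.2f s missing)",
                 have, need, need - have))
  t0 <- series$t[1]
  lapply(seq_len(schedule$n_blocks), function(k) {
    start <- (k - 1) * (schedule$block_s + schedule$rest_s)
    sel <- series$t - t0 >= start - 1e-9 &
           series$t - t0 < start + schedule$block_s - 1e-9
    seg <- imu_series(series$t[sel] - t0 - start,
                      series$ax[sel], series$ay[sel], series$az[sel],
                      series$gx[sel], series$gy[sel], series$gz[sel],
                      nominal_rate = series$nominal_rate)
    attr(seg, "block") <- k
    seg
  })
}

.wrist_cols <- c("participant_id", "wrist", "t_s", "ax_g", "ay_g", "az_g",
                 "gx_dps", "gy_dps", "gz_dps")

# lossless numeric formatting for the session CSV
.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a session to disk
#'
#' Produces `<base>.csv` (long format, both wrists) and a `<base>.json`
#' sidecar holding group, age and the protocol schedule.
#'
#' @param session A `session_recording`.
#' @param dir Output directory (created if missing).
#' @param base File base name; defaults to the participant id.
#' @return Invisibly, the CSV path.
#' @export
write_session <- function(session, dir, base = session$participant_id) {
  stopifnot(inherits(session, "session_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- do.call(rbind, lapply(c("left", "right"), function(w) {
    s <- session[[w]]
    data.frame(participant_id = session$participant_id, wrist = w,
               t_s = .fmt_num(s$t), ax_g = .fmt_num(s$ax), ay_g = .fmt_num(s$ay),
               az_g = .fmt_num(s$az), gx_dps = .fmt_num(s$gx),
               gy_dps = .fmt_num(s$gy), gz_dps = .fmt_num(s$gz),
               stringsAsFactors = FALSE)
  }))
  csv <- file.path(dir, paste0(base, ".csv"))
  utils::write.table(rows, csv, sep = ",", row.names = FALSE, quote = FALSE)
  sidecar <- list(participant_id = session$participant_id, group = session$group,
                  age_months = session$age_months,
                  schedule = list(n_blocks = session$schedule$n_blocks,
                                  block_s = session$schedule$block_s,
                                  rest_s = session$schedule$rest_s),
                  nominal_rate = session$left$nominal_rate)
  jsonlite::write_json(sidecar, file.path(dir, paste0(base, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}

.parse_num_col <- function(x, col, file) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & nzchar(x))
  if (length(bad))
    stop(sprintf("malformed value in column '%s' of %s at data row %d: '%s'",
                 col, basename(file), bad[1], x[bad[1]]))
  v
}

#' Read a session from disk
#'
#' @param path Path to the session CSV (or its base name without extension);
#'   the JSON sidecar is looked up next to it.
#' @return A validated `session_recording`.
#' @export
read_session <- function(path) {
  csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
  side <- sub("\\.csv$", ".json", csv)
  if (!file.exists(csv)) stop("session file not found: ", csv)
  if (!file.exists(side)) stop("sidecar not found: ", side)
  raw <- utils::read.csv(csv, colClasses = "character")
  missing_cols <- setdiff(.wrist_cols, names(raw))
  if (length(missing_cols))
    stop("session CSV missing columns: ", paste(missing_cols, collapse = ", "))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  rate <- if (!is.null(meta$nominal_rate)) meta$nominal_rate else 50
  mk <- function(w) {
    sub <- raw[raw$wrist == w, , drop = FALSE]
    if (!nrow(sub)) stop("incomplete recording: missing wrist '", w, "'")
    imu_series(.parse_num_col(sub$t_s, "t_s", csv),
               .parse_num_col(sub$ax_g, "ax_g", csv),
               .parse_num_col(sub$ay_g, "ay_g", csv),
               .parse_num_col(sub$az_g, "az_g", csv),
               .parse_num_col(sub$gx_dps, "gx_dps", csv),
               .parse_num_col(sub$gy_dps, "gy_dps", csv),
               .parse_num_col(sub$gz_dps, "gz_dps", csv),
               nominal_rate = rate)
  }
  sched <- protocol_schedule(meta$schedule$n_blocks, meta$schedule$block_s,
                             meta$schedule$rest_s)
  session_recording(participant_id = meta$participant_id, group = meta$group,
                    age_months = meta$age_months, left = mk("left"),
                    right = mk("right"), schedule = sched)
}

#' Validate a session file for format and protocol coverage
#'
#' @param path Path as in [read_session()].
#' @param schedule Expected schedule; defaults to the session's own sidecar.
#' @return TRUE invisibly on success; errors describe the failure.
#' @export
validate_session <- function(path, schedule = NULL) {
  s <- read_session(path)
  sched <- if (is.null(schedule)) s$schedule else schedule
  for (w in c("left", "right")) invisible(segment_blocks(s[[w]], sched))
  invisible(TRUE)
}
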