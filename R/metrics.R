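#' Detect extrema of the integrated rotation angle
#'
#' Integrates the y-axis angular velocity over time (trapezoid rule) to an
#' angle trace, removes the constant rate bias (block-mean angular velocity,
#' i.e. the linear trend of the angle), and returns the local extrema of the
#' angle trace. Extrema are the "peak points" between which per-half-cycle
#' rotation angles are measured; they coincide with zero crossings of the
#' angular velocity. Candidates are plateau-aware non-strict turning points,
#' kept when their topographic prominence reaches `prominence_deg` and
#' separated by at least `min_gap_s`.
#'
#' @param block A `wrist_block_series` (or any `imu_series` with uniform `t`).
#' @param prominence_deg Minimum prominence of an extremum, degrees.
#' @param min_gap_s Minimum spacing between retained extrema, seconds.
#' @return Object of class `extrema_sequence`: list with `times` (s),
#'   `angles` (deg, detrended angle at each extremum), `n_extrema`, and the
#'   full `angle` trace with its `t`.
#' @export
detect_angle_extrema <- function(block, prominence_deg = 10, min_gap_s = 0.15) {
  stopifnot(inherits(block, "imu_series"))
  t <- block$t
  gy0 <- block$gy - mean(block$gy)
  theta <- pracma::cumtrapz(t, gy0)[, 1]
  cand <- .turning_points(theta)
  keep <- .prominence(theta, cand$idx, cand$type) >= prominence_deg
  idx <- cand$idx[keep]; type <- cand$type[keep]
  sel <- .enforce_alternation(theta, idx, type)
  idx <- sel$idx; type <- sel$type
  # enforce minimum spacing: drop the less prominent of an offending pair
  while (length(idx) >= 2 && any(diff(t[idx]) < min_gap_s)) {
    j <- which(diff(t[idx]) < min_gap_s)[1]
    pr <- .prominence(theta, idx[c(j, j + 1)], type[c(j, j + 1)])
    drop <- if (pr[1] < pr[2]) j else j + 1
    idx <- idx[-drop]; type <- type[-drop]
    sel <- .enforce_alternation(theta, idx, type)
    idx <- sel$idx; type <- sel$type
  }
  structure(list(times = t[idx], angles = theta[idx],
                 n_extrema = length(idx), t = t, angle = theta),
            class = "extrema_sequence")
}

# plateau-aware non-strict turning points: sign changes of the first
# difference after collapsing zero-difference runs; an extremum on a plateau
# is placed at the plateau midpoint
.turning_points <- function(theta) {
  d <- diff(theta)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(idx = integer(0), type = integer(0)))
  sv <- s[nz]
  ch <- which(diff(sv) != 0)
  if (!length(ch)) return(list(idx = integer(0), type = integer(0)))
  idx <- vapply(ch, function(j) {
    lo <- nz[j] + 1L           # first index at the extremal value
    hi <- nz[j + 1]            # last index at the extremal value
    as.integer(floor((lo + hi) / 2))
  }, integer(1))
  list(idx = idx, type = as.integer(sv[ch]))  # +1 max, -1 min
}

# topographic prominence: height above the higher of the two bases, where a
# base is the lowest point between the extremum and the nearest higher
# terrain (or the signal boundary) on each side; minima are handled on -theta
.prominence <- function(theta, idx, type) {
  n <- length(theta)
  vapply(seq_along(idx), function(k) {
    i <- idx[k]
    x <- if (type[k] > 0) theta else -theta
    v <- x[i]
    hl <- if (i > 1) which(x[1:(i - 1)] > v) else integer(0)
    left_base <- if (length(hl)) min(x[(max(hl) + 1):i]) else min(x[1:i])
    hr <- if (i < n) which(x[(i + 1):n] > v) + i else integer(0)
    right_base <- if (length(hr)) min(x[i:(min(hr) - 1)]) else min(x[i:n])
    v - max(left_base, right_base)
  }, numeric(1))
}

# collapse consecutive extrema of the same type to the most extreme one
.enforce_alternation <- function(theta, idx, type) {
  if (length(idx) < 2) return(list(idx = idx, type = type))
  keep <- rep(TRUE, length(idx))
  # repeatedly merge adjacent same-type pairs, keeping the more extreme point
  repeat {
    ks <- which(keep)
    if (length(ks) < 2) break
    same <- which(type[ks[-length(ks)]] == type[ks[-1]])
    if (!length(same)) break
    a <- ks[same[1]]; b <- ks[same[1] + 1]
    va <- theta[idx[a]] * type[a]; vb <- theta[idx[b]] * type[b]
    keep[if (va >= vb) b else a] <- FALSE
  }
  list(idx = idx[keep], type = type[keep])
}

#' Rotation amplitude from an extrema sequence
#'
#' Mean absolute rotation angle between adjacent extrema (the per-half-cycle
#' swing): `RoA = 1/(N-1) * sum_i |angle[i+1] - angle[i]|`, each term being
#' the integral of the angular velocity between adjacent peak points.
#'
#' @param ext An `extrema_sequence`.
#' @return Degrees; 0 (with attribute `insufficient = TRUE`) when fewer than
#'   2 extrema were detected.
#' @export
compute_rotation_amplitude <- function(ext) {
  stopifnot(inherits(ext, "extrema_sequence"))
  if (ext$n_extrema < 2)
    return(structure(0, insufficient = TRUE))
  mean(abs(diff(ext$angles)))
}

#' Rotation frequency from an extrema sequence
#'
#' Adjacent extrema are half a cycle apart, so the full-cycle frequency is
#' `(N - 1) / (2 * (t_last - t_first))`; 0 when fewer than 2 extrema.
#'
#' @param ext An `extrema_sequence`.
#' @param duration Unused fallback span, seconds (kept for API symmetry).
#' @return Hz.
#' @export
compute_rotation_frequency <- function(ext, duration = NULL) {
  stopifnot(inherits(ext, "extrema_sequence"))
  if (ext$n_extrema < 2) return(0)
  span <- ext$times[ext$n_extrema] - ext$times[1]
  if (span <= 0) return(0)
  (ext$n_extrema - 1) / (2 * span)
}

#' Total rotation time of a block
#'
#' Time during which the rotation-activity envelope (moving RMS of the y-axis
#' angular velocity over `window_s`) exceeds the activity threshold
#' `max(15 deg/s, 0.2 * 95th percentile of the envelope)`. Inactive gaps
#' shorter than `gap_tol_s` are bridged.
#'
#' @param block A `wrist_block_series`.
#' @param window_s Moving-RMS window, seconds.
#' @param threshold Activity threshold in deg/s; NULL for the adaptive
#'   default above.
#' @param gap_tol_s Gaps shorter than this are counted as active, seconds.
#' @return Seconds of sustained rotation.
#' @export
compute_total_rotation_time <- function(block, window_s = 0.5,
                                        threshold = NULL, gap_tol_s = 0.5) {
  stopifnot(inherits(block, "imu_series"))
  n <- length(block$gy)
  if (n == 0) return(0)
  rate <- block$nominal_rate
  w <- max(1L, round(window_s * rate))
  cs <- c(0, cumsum(block$gy^2))
  lo <- pmax(seq_len(n) - floor(w / 2), 1L)
  hi <- pmin(seq_len(n) + floor(w / 2), n)
  rms <- sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
  if (is.null(threshold))
    threshold <- max(15, 0.2 * stats::quantile(rms, 0.95, names = FALSE))
  active <- rms >= threshold
  # bridge short inactive gaps between active stretches
  r <- rle(active)
  if (length(r$lengths) > 2) {
    inner <- 2:(length(r$lengths) - 1)
    bridge <- inner[!r$values[inner] & r$lengths[inner] < gap_tol_s * rate]
    r$values[bridge] <- TRUE
  }
  sum(inverse.rle(r)) / rate
}

#' Per-wrist per-block rotation statistics
#'
#' @param block A preprocessed `wrist_block_series`.
#' @param wrist `"left"` or `"right"` label.
#' @inheritParams detect_angle_extrema
#' @inheritParams compute_total_rotation_time
#' @return List with `roa` (deg), `rof` (Hz), `trt` (s), `n_extrema`, `wrist`.
#' @export
wrist_block_stats <- function(block, wrist = "right", prominence_deg = 10,
                              min_gap_s = 0.15, window_s = 0.5,
                              threshold = NULL, gap_tol_s = 0.5) {
  ext <- detect_angle_extrema(block, prominence_deg, min_gap_s)
  list(roa = as.numeric(compute_rotation_amplitude(ext)),
       rof = compute_rotation_frequency(ext),
       trt = compute_total_rotation_time(block, window_s, threshold, gap_tol_s),
       n_extrema = ext$n_extrema, wrist = wrist)
}

#' Left/right rotation symmetry
#'
#' `Symmetry = (1 - 0.7*|RoA_l - RoA_r|/max(RoA_l, RoA_r)
#'                - 0.3*|RoF_l - RoF_r|/max(RoF_l, RoF_r))^2`,
#' with a ratio defined as 0 when both of its arguments are 0; clipped to
#' [0, 1]. Symmetric in its two arguments.
#'
#' @param left,right Per-wrist stats (lists with `roa` and `rof`, e.g. from
#'   [wrist_block_stats()]).
#' @return Unitless value in [0, 1].
#' @export
compute_symmetry <- function(left, right) {
  rdiff <- function(a, b) {
    m <- max(a, b)
    if (m == 0) 0 else abs(a - b) / m
  }
  v <- (1 - 0.7 * rdiff(left$roa, right$roa) -
            0.3 * rdiff(left$rof, right$rof))^2
  min(max(v, 0), 1)
}

#' Extract the per-participant WRI feature triple
#'
#' Per block, both wrists are conditioned with [preprocess_block()]; total
#' rotation time and rotation amplitude are taken from the dominant (right)
#' wrist (all study participants were right-handed; set `wrist = "max"` to
#' use the better wrist instead), symmetry from both wrists. Each metric is
#' aggregated as the maximum over the blocks. If no block of the dominant
#' wrist shows at least two angle extrema the features are (0, 0, 0) with
#' `low_motion = TRUE`.
#'
#' @param session A `session_recording`.
#' @param wrist `"right"` (dominant) or `"max"` (better wrist per block).
#' @param cutoff_hz,order,q,r Preprocessing parameters ([preprocess_block()]).
#' @param prominence_deg,min_gap_s Peak-detection parameters.
#' @param window_s,threshold,gap_tol_s Activity-rule parameters.
#' @return Object of class `wri_features`: list with `trt` (s), `roa` (deg),
#'   `symmetry`, `low_motion`, and a per-block data.frame `blocks`.
#' @export
extract_features <- function(session, wrist = c("right", "max"),
                             cutoff_hz = 10, order = 2, q = NULL, r = NULL,
                             prominence_deg = 10, min_gap_s = 0.15,
                             window_s = 0.5, threshold = NULL,
                             gap_tol_s = 0.5) {
  stopifnot(inherits(session, "session_recording"))
  wrist <- match.arg(wrist)
  sched <- session$schedule
  segs <- lapply(c(left = "left", right = "right"), function(w)
    segment_blocks(clean_timestamps(session[[w]]), sched))
  per_block <- lapply(seq_len(sched$n_blocks), function(k) {
    st <- lapply(c(left = "left", right = "right"), function(w) {
      blk <- preprocess_block(segs[[w]][[k]], cutoff_hz = cutoff_hz,
                              order = order, q = q, r = r,
                              block_s = sched$block_s)
      wrist_block_stats(blk, wrist = w, prominence_deg = prominence_deg,
                        min_gap_s = min_gap_s, window_s = window_s,
                        threshold = threshold, gap_tol_s = gap_tol_s)
    })
    dom <- if (wrist == "right") st$right
           else st[[which.max(c(st$left$roa, st$right$roa))]]
    data.frame(block = k, trt = dom$trt, roa = dom$roa,
               symmetry = compute_symmetry(st$left, st$right),
               n_extrema_left = st$left$n_extrema,
               n_extrema_right = st$right$n_extrema)
  })
  pb <- do.call(rbind, per_block)
  dom_n <- if (wrist == "right") pb$n_extrema_right
           else pmax(pb$n_extrema_left, pb$n_extrema_right)
  low <- all(dom_n < 2)
  out <- if (low) list(trt = 0, roa = 0, symmetry = 0, low_motion = TRUE)
         else list(trt = max(pb$trt), roa = max(pb$roa),
                   symmetry = max(pb$symmetry), low_motion = FALSE)
  structure(c(out, list(blocks = pb, participant_id = session$participant_id)),
            class = "wri_features")
}

#' @export
print.wri_features <- function(x, ...) {
  cat(sprintf("<wri_features> %s: TRT %.2f s, RoA %.1f deg, Symmetry %.3f%s\n",
              x$participant_id, x$trt, x$roa, x$symmetry,
              if (x$low_motion) " [low motion]" else ""))
  invisible(x)
}

#' Build the cohort feature table from a list of sessions
#'
#' @param sessions List of `session_recording`s.
#' @param ... Passed to [extract_features()].
#' @return data.frame with participant_id, group, age_months, age_band,
#'   trt_s, roa_deg, symmetry, low_motion_flag.
#' @export
features_table <- function(sessions, ...) {
  rows <- lapply(sessions, function(s) {
    f <- extract_features(s, ...)
    data.frame(participant_id = s$participant_id, group = s$group,
               age_months = s$age_months,
               age_band = as.character(age_band(s$age_months)),
               trt_s = f$trt, roa_deg = f$roa, symmetry = f$symmetry,
               low_motion_flag = f$low_motion, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
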