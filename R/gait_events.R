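#' Detector parameters for gait segmentation
#'
#' Tunables of the quasi-static (GLRT) detector and of the gyroscope
#' peak-based foot event labeller.
#'
#' @param N sliding window size in samples (odd, centred). ~0.19 s at
#'   26 Hz with the default 5.
#' @param T_threshold GLRT threshold (dimensionless).
#' @param sigma_a accelerometer noise standard deviation, m/s^2.
#' @param sigma_w gyroscope noise standard deviation, rad/s.
#' @param w0 zero-rotation tolerance for foot-flat / heel-off, rad/s.
#' @param lpf_cutoff cutoff of the first-order low-pass applied to the
#'   gyroscope magnitude, Hz (applied forward-backward, zero phase).
#' @param min_stance,min_swing minimum phase durations, s; shorter runs
#'   of the quasi-static mask are merged into their neighbours.
#' @param min_peaks minimum number of gyroscope-magnitude peaks for a
#'   swing to count as a proper step.
#' @param peak_prominence minimum peak prominence, rad/s.
#' @param peak_separation minimum time between accepted peaks, s.
#' @param g gravitational acceleration, m/s^2.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(N = 5, T_threshold = 3e4,
                            sigma_a = default_noise()$sigma_a,
                            sigma_w = default_noise()$sigma_w,
                            w0 = 0.3, lpf_cutoff = 5,
                            min_stance = 0.2, min_swing = 0.2,
                            min_peaks = 2, peak_prominence = 0.5,
                            peak_separation = 0.1, g = GRAVITY) {
  stopifnot(N >= 2, T_threshold > 0, sigma_a > 0, sigma_w > 0,
            min_peaks >= 1, lpf_cutoff > 0)
  structure(list(N = as.integer(N), T_threshold = T_threshold,
                 sigma_a = sigma_a, sigma_w = sigma_w, w0 = w0,
                 lpf_cutoff = lpf_cutoff, min_stance = min_stance,
                 min_swing = min_swing, min_peaks = as.integer(min_peaks),
                 peak_prominence = peak_prominence,
                 peak_separation = peak_separation, g = g),
            class = "detector_params")
}

#' GLRT zero-motion statistic of one window
#'
#' Computes the generalized likelihood ratio test statistic
#' `S = (1/N) * sum_i [ |f_i - g fbar/|fbar||^2 / sigma_a^2
#'                      + |w_i|^2 / sigma_w^2 ]`
#' where `fbar` is the window-mean specific force. Small values indicate
#' a quasi-static (foot-flat) window.
#'
#' @param window_f N x 3 matrix of specific-force samples, m/s^2.
#' @param window_w N x 3 matrix of angular-rate samples, rad/s.
#' @param sigma_a,sigma_w sensor noise standard deviations.
#' @param g gravitational acceleration, m/s^2.
#' @return The non-negative scalar statistic.
#' @export
glrt_statistic <- function(window_f, window_w, sigma_a, sigma_w,
                           g = GRAVITY) {
  window_f <- as.matrix(window_f); window_w <- as.matrix(window_w)
  stopifnot(ncol(window_f) == 3, ncol(window_w) == 3,
            nrow(window_f) == nrow(window_w), sigma_a > 0, sigma_w > 0)
  N <- nrow(window_f)
  if (N < 2) abort("window must hold at least 2 samples",
                   class = "gaitkin_invalid_argument")
  fbar <- colMeans(window_f)
  nf <- sqrt(sum(fbar^2))
  if (nf == 0) {
    abort("window-mean specific force is zero; gravity direction undefined",
          class = "gaitkin_degenerate_window")
  }
  fres <- sweep(window_f, 2, g * fbar / nf)
  sum(fres^2 / sigma_a^2 + window_w^2 / sigma_w^2) / N
}

# sliding GLRT over a whole trace; centred windows, edge windows clamped
glrt_series <- function(f, w, N, sigma_a, sigma_w, g = GRAVITY) {
  n <- nrow(f)
  half <- N %/% 2
  S <- numeric(n)
  # cumulative sums give O(n) window means
  cf <- apply(rbind(0, f), 2, cumsum)
  for (k in seq_len(n)) {
    lo <- max(1, k - half); hi <- min(n, k + half)
    lo <- max(1, min(lo, hi - N + 1)); hi <- min(n, max(hi, lo + N - 1))
    fbar <- (cf[hi + 1, ] - cf[lo, ]) / (hi - lo + 1)
    nf <- sqrt(sum(fbar^2))
    if (nf == 0) {
      abort("window-mean specific force is zero",
            class = "gaitkin_degenerate_window")
    }
    idx <- lo:hi
    fres <- sweep(f[idx, , drop = FALSE], 2, g * fbar / nf)
    S[k] <- sum(fres^2 / sigma_a^2 +
                  w[idx, , drop = FALSE]^2 / sigma_w^2) / length(idx)
  }
  S
}

# merge mask runs shorter than the minimum durations into neighbours
merge_short_runs <- function(mask, times, min_static, min_moving) {
  repeat {
    r <- rle(mask)
    if (length(r$lengths) <= 1) return(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    dur <- times[ends] - times[starts]
    limit <- ifelse(r$values, min_static, min_moving)
    bad <- which(dur < limit)
    if (!length(bad)) return(mask)
    # flip the shortest offending run first; ties by position
    i <- bad[which.min(dur[bad])]
    mask[starts[i]:ends[i]] <- !r$values[i]
  }
}

#' Estimate constant gyro bias from an initial standstill
#'
#' Mean gyroscope output over the first `window` seconds of a trace,
#' assumed motionless. Used to initialise the orientation filter's bias
#' states and to pre-correct the GLRT input when the sensors carry large
#' turn-on biases.
#'
#' @param trace one-site tibble with columns `t, wx, wy, wz`.
#' @param window averaging window, s.
#' @return Numeric length-3 bias estimate, rad/s.
#' @export
estimate_gyro_bias <- function(trace, window = 1) {
  sel <- trace$t <= trace$t[1] + window
  colMeans(as.matrix(trace[sel, c("wx", "wy", "wz")]))
}

#' Quasi-static (foot-flat) detection by sliding GLRT
#'
#' Flags each sample of a foot trace as quasi-static when the centred
#' N-sample GLRT statistic falls below the threshold, then removes runs
#' shorter than the minimum stance/swing durations by merging them into
#' their neighbours.
#'
#' @param trace one-site tibble with columns `t, fx..fz, wx..wz`.
#' @param params a [detector_params()] object.
#' @param gyro_bias optional length-3 constant bias (rad/s) subtracted
#'   from the gyroscope before the statistic is formed; see
#'   [estimate_gyro_bias()].
#' @return Logical vector, one element per sample (`TRUE` = quasi-static).
#' @export
detect_quasi_static <- function(trace, params = detector_params(),
                                gyro_bias = c(0, 0, 0)) {
  n <- nrow(trace)
  if (n < params$N) {
    abort("trace is shorter than the detector window",
          class = "gaitkin_insufficient_data")
  }
  f <- as.matrix(trace[c("fx", "fy", "fz")])
  w <- sweep(as.matrix(trace[c("wx", "wy", "wz")]), 2, gyro_bias)
  S <- glrt_series(f, w, params$N, params$sigma_a, params$sigma_w, params$g)
  mask <- S < params$T_threshold
  merge_short_runs(mask, trace$t, params$min_stance, params$min_swing)
}

#' Segment a quasi-static mask into gait cycles
#'
#' Pairs each static run with the moving run that follows it: one gait
#' cycle is a stance phase plus the subsequent swing phase. The mask is
#' expected to begin and end in the static state; a leading moving run is
#' discarded with a warning.
#'
#' @param mask logical quasi-static mask from [detect_quasi_static()].
#' @param times sample timestamps, s.
#' @return A tibble with one row per cycle: `stance_start, stance_end,
#'   swing_start, swing_end` (times, s) and the corresponding sample
#'   index columns `i_stance_start, ..., i_swing_end`.
#' @export
segment_gait_cycles <- function(mask, times) {
  stopifnot(length(mask) == length(times))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  if (!r$values[1]) {
    warn("mask starts in motion; discarding leading moving run")
    starts <- starts[-1]; ends <- ends[-1]; r$values <- r$values[-1]
  }
  k <- length(r$values)
  cycles <- list()
  i <- 1
  while (i + 1 <= k) {
    if (r$values[i] && !r$values[i + 1]) {
      cycles[[length(cycles) + 1]] <- tibble(
        i_stance_start = starts[i], i_stance_end = ends[i],
        i_swing_start = starts[i + 1], i_swing_end = ends[i + 1])
    }
    i <- i + 1
  }
  if (!length(cycles)) {
    return(tibble(stance_start = numeric(), stance_end = numeric(),
                  swing_start = numeric(), swing_end = numeric(),
                  i_stance_start = integer(), i_stance_end = integer(),
                  i_swing_start = integer(), i_swing_end = integer()))
  }
  out <- bind_rows(cycles)
  mutate(out,
         stance_start = times[.data$i_stance_start],
         stance_end = times[.data$i_stance_end],
         swing_start = times[.data$i_swing_start],
         swing_end = times[.data$i_swing_end],
         .before = 1)
}

#' First-order low-pass filter
#'
#' `y_k = alpha y_{k-1} + (1 - alpha) x_k` with
#' `alpha = exp(-2 pi fc dt)`. With `zero_phase = TRUE` (default) the
#' filter is run forward and then backward so peak locations are not
#' delayed.
#'
#' @param x signal.
#' @param dt sample interval, s.
#' @param cutoff cutoff frequency, Hz.
#' @param zero_phase run forward-backward?
#' @return Filtered signal.
#' @export
lowpass1 <- function(x, dt, cutoff, zero_phase = TRUE) {
  alpha <- exp(-2 * pi * cutoff * dt)
  y <- stats::filter(x * (1 - alpha), alpha, method = "recursive",
                     init = x[1])
  y <- as.numeric(y)
  if (zero_phase) {
    y <- rev(as.numeric(stats::filter(rev(y) * (1 - alpha), alpha,
                                      method = "recursive", init = y[length(y)])))
  }
  y
}

#' Locate local maxima with a prominence and separation requirement
#'
#' Strict local maxima of `x`; the prominence of a peak is its height
#' above the higher of the two lowest points separating it from higher
#' terrain (or the signal edge). Peaks closer together than `min_sep`
#' are thinned, keeping the higher peak.
#'
#' @param x signal values.
#' @param t timestamps, same length.
#' @param prominence minimum prominence.
#' @param min_sep minimum time separation, s.
#' @return Integer indices of accepted peaks, in time order.
#' @export
find_peaks <- function(x, t, prominence = 0, min_sep = 0) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    h <- x[i]
    # walk left/right to the nearest strictly higher sample, tracking minima
    vl <- h; j <- i - 1
    while (j >= 1 && x[j] <= h) { vl <- min(vl, x[j]); j <- j - 1 }
    vr <- h; j <- i + 1
    while (j <= n && x[j] <= h) { vr <- min(vr, x[j]); j <- j + 1 }
    h - max(vl, vr)
  }, numeric(1))
  keep <- cand[prom >= prominence]
  if (min_sep > 0 && length(keep) > 1) {
    ord <- keep[order(x[keep], decreasing = TRUE)]
    sel <- integer()
    for (i in ord) {
      if (all(abs(t[i] - t[sel]) >= min_sep)) sel <- c(sel, i)
    }
    keep <- sort(sel)
  }
  keep
}

#' Detect foot gait events from a foot-mounted IMU trace
#'
#' Full per-foot gait event labelling: quasi-static segmentation by the
#' GLRT detector, pairing of stance and swing phases into gait cycles,
#' then per-cycle peak analysis of the low-pass filtered gyroscope
#' magnitude. A cycle whose swing shows at least `min_peaks` peaks is a
#' proper step: the first peak is marked toe-off and the last peak
#' heel-strike. Foot-flat is the contiguous run of samples below the
#' zero-rotation tolerance from the start of the stance phase, and
#' heel-off is the last sample at or above the tolerance scanning back
#' from the stance end. Cycles with fewer peaks are skipped.
#'
#' @param trace one-foot tibble with columns `t, fx..fz, wx..wz`.
#' @param params a [detector_params()] object.
#' @param calibrate_bias subtract the initial-standstill gyro bias
#'   estimate before detection (see [estimate_gyro_bias()])?
#' @param foot label ("left"/"right") recorded in the output.
#' @return An object of class `gait_events`: a list with
#'   * `events`: tibble `foot, event, t` (`toe_off`, `heel_strike`,
#'     `heel_off`), time-ordered;
#'   * `foot_flat`: tibble `foot, t_start, t_end`;
#'   * `cycles`: all cycles from [segment_gait_cycles()];
#'   * `valid`: logical, which cycles produced a step;
#'   * `mask`: the quasi-static mask.
#' @export
detect_foot_events <- function(trace, params = detector_params(),
                               calibrate_bias = TRUE, foot = "right") {
  bias <- if (calibrate_bias) estimate_gyro_bias(trace) else c(0, 0, 0)
  mask <- detect_quasi_static(trace, params, gyro_bias = bias)
  cycles <- segment_gait_cycles(mask, trace$t)
  w <- sweep(as.matrix(trace[c("wx", "wy", "wz")]), 2, bias)
  wmag <- sqrt(rowSums(w^2))
  dt <- stats::median(diff(trace$t))
  wf <- lowpass1(wmag, dt, params$lpf_cutoff)
  ev <- list(); ff <- list(); valid <- logical(nrow(cycles))
  for (ci in seq_len(nrow(cycles))) {
    cy <- cycles[ci, ]
    sw <- cy$i_swing_start:cy$i_swing_end
    pk <- find_peaks(wf[sw], trace$t[sw], params$peak_prominence,
                     params$peak_separation)
    if (length(pk) < params$min_peaks) next
    pk_t <- trace$t[sw[pk]]
    if (length(unique(pk_t)) < params$min_peaks) next  # degenerate ties
    valid[ci] <- TRUE
    st <- cy$i_stance_start:cy$i_stance_end
    flat <- wf[st] < params$w0
    n_flat <- if (flat[1]) which.min(c(flat, FALSE)) - 1 else 0
    heel_off <- {
      above <- which(wf[st] >= params$w0)
      if (length(above)) trace$t[st[max(above)]] else NA_real_
    }
    ev[[length(ev) + 1]] <- tibble(
      foot = foot,
      event = c("toe_off", "heel_strike",
                if (!is.na(heel_off)) "heel_off"),
      t = c(pk_t[1], pk_t[length(pk_t)],
            if (!is.na(heel_off)) heel_off))
    if (n_flat > 0) {
      ff[[length(ff) + 1]] <- tibble(foot = foot,
                                     t_start = trace$t[st[1]],
                                     t_end = trace$t[st[n_flat]])
    }
  }
  events <- if (length(ev)) arrange(bind_rows(ev), .data$t) else
    tibble(foot = character(), event = character(), t = numeric())
  foot_flat <- if (length(ff)) bind_rows(ff) else
    tibble(foot = character(), t_start = numeric(), t_end = numeric())
  structure(list(events = events, foot_flat = foot_flat, cycles = cycles,
                 valid = valid, mask = mask, foot = foot,
                 gyro_bias = bias),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> foot %s: %d cycles, %d valid steps\n",
              x$foot, nrow(x$cycles), sum(x$valid)))
  print(x$events, n = 6)
  invisible(x)
}

#' Detect gait events for both feet of a multi-sensor log
#'
#' @param log tidy IMU log with `site` column containing `foot_L` and/or
#'   `foot_R` samples.
#' @inheritParams detect_foot_events
#' @return A tibble binding the per-foot event tables, with the
#'   per-foot `gait_events` objects in attribute `per_foot`.
#' @export
detect_gait_events <- function(log, params = detector_params(),
                               calibrate_bias = TRUE) {
  feet <- intersect(c("foot_L", "foot_R"), unique(log$site))
  if (!length(feet)) {
    abort("log contains no foot sensor samples", class = "gaitkin_data_error")
  }
  per <- lapply(feet, function(s) {
    detect_foot_events(site_trace(log, s), params, calibrate_bias,
                       foot = if (s == "foot_L") "left" else "right")
  })
  names(per) <- feet
  out <- arrange(bind_rows(lapply(per, `[[`, "events")), .data$t)
  attr(out, "per_foot") <- per
  out
}
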