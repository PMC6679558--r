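#' Acceleration magnitude series
#'
#' Gravity-free acceleration magnitude per sample:
#' `a_i = ||f_i|| - g`, the input to the empirical step and stride
#' models.
#'
#' @param trace tibble with columns `fx, fy, fz` (m/s^2), one row per
#'   sample.
#' @param g gravitational acceleration, m/s^2.
#' @return Numeric vector, one value per sample.
#' @export
accel_magnitude_series <- function(trace, g = GRAVITY) {
  f <- as.matrix(trace[c("fx", "fy", "fz")])
  if (!nrow(f)) abort("empty trace", class = "gaitkin_invalid_argument")
  sqrt(rowSums(f^2)) - g
}

#' Weinberg step-length model
#'
#' Step length from the bounce of the hip:
#' `k * (a_max - a_min)^(1/4)` over one gait cycle of gravity-free
#' acceleration magnitudes (typically from the pelvis sensor, heel-strike
#' to heel-strike).
#'
#' @param a acceleration magnitudes over one gait cycle, m/s^2.
#' @param k dimensionless tuning parameter.
#' @return Step length, m.
#' @export
weinberg_step <- function(a, k) {
  if (length(a) < 2) {
    abort("a gait cycle needs at least two samples",
          class = "gaitkin_invalid_argument")
  }
  k * (max(a) - min(a))^(1 / 4)
}

#' Kim mean-acceleration stride model
#'
#' Stride length from the mean absolute gravity-free acceleration over
#' one stride cycle of the foot sensor: `k * (sum|a_i| / N)^(1/3)`. The
#' published default for `k` is 0.98; it is normally re-calibrated on
#' training data with [calibrate_k()].
#'
#' @param a acceleration magnitudes over one gait cycle, m/s^2.
#' @param k dimensionless tuning parameter.
#' @return Stride length, m.
#' @export
kim_stride <- function(a, k = 0.98) {
  if (!length(a)) abort("empty cycle", class = "gaitkin_invalid_argument")
  k * (mean(abs(a)))^(1 / 3)
}

#' Calibrate a step-model tuning parameter
#'
#' Least-squares slope through the origin between the model's raw values
#' (the `(a_max - a_min)^(1/4)` or cube-root terms, i.e. the model
#' evaluated with `k = 1`) and observed step/stride lengths:
#' `k = sum(raw * len) / sum(raw^2)`.
#'
#' @param observed_lengths reference lengths, m.
#' @param model_raw_values model raw values, same length.
#' @return The fitted `k`.
#' @export
calibrate_k <- function(observed_lengths, model_raw_values) {
  stopifnot(length(observed_lengths) == length(model_raw_values),
            length(observed_lengths) >= 1)
  if (all(model_raw_values == 0)) {
    abort("all model raw values are zero; k is unidentifiable",
          class = "gaitkin_degenerate_calibration")
  }
  sum(model_raw_values * observed_lengths) / sum(model_raw_values^2)
}

#' Step/stride estimates from the empirical acceleration models
#'
#' Applies the Weinberg step model (pelvis sensor, heel-strike to
#' heel-strike windows) or the Kim stride model (foot sensor, toe-off to
#' heel-strike of the same foot) over a full log.
#'
#' @param log tidy IMU log.
#' @param events events tibble from [detect_gait_events()].
#' @param method `"weinberg"` or `"kim"`.
#' @param k tuning parameter; `NULL` uses 0.98 for `"kim"` and 0.5 for
#'   `"weinberg"` (both normally replaced via [calibrate_k()]).
#' @param g gravitational acceleration, m/s^2.
#' @return A `gait_steps` tibble: `kind, side, value, t_toe_off,
#'   t_heel_strike, excluded` plus a `raw` column of the `k = 1` model
#'   values (for calibration).
#' @export
model_step_lengths <- function(log, events, method = c("weinberg", "kim"),
                               k = NULL, g = GRAVITY) {
  method <- match.arg(method)
  if (is.null(k)) k <- if (method == "kim") 0.98 else 0.5
  swings <- pair_swings(events)
  rows <- list()
  if (method == "weinberg") {
    tr <- site_trace(log, "pelvis")
    a <- accel_magnitude_series(tr, g)
    # heel-strike to heel-strike windows, any foot
    hs <- sort(swings$t_heel_strike)
    for (j in seq_len(length(hs) - 1)) {
      sel <- tr$t >= hs[j] & tr$t <= hs[j + 1]
      if (sum(sel) < 2) next
      raw <- (max(a[sel]) - min(a[sel]))^(1 / 4)
      rows[[length(rows) + 1]] <- tibble(
        kind = "step_length_feet", side = "n/a", value = k * raw,
        t_toe_off = hs[j], t_heel_strike = hs[j + 1], raw = raw)
    }
  } else {
    for (ft in unique(swings$foot)) {
      site <- if (ft == "left") "foot_L" else "foot_R"
      tr <- site_trace(log, site)
      a <- accel_magnitude_series(tr, g)
      sw <- swings[swings$foot == ft, ]
      for (j in seq_len(nrow(sw))) {
        sel <- tr$t >= sw$t_toe_off[j] & tr$t <= sw$t_heel_strike[j]
        if (!sum(sel)) next
        raw <- mean(abs(a[sel]))^(1 / 3)
        rows[[length(rows) + 1]] <- tibble(
          kind = "stride_length", side = ft, value = k * raw,
          t_toe_off = sw$t_toe_off[j], t_heel_strike = sw$t_heel_strike[j],
          raw = raw)
      }
    }
  }
  if (!length(rows)) {
    return(tibble(kind = character(), side = character(), value = numeric(),
                  t_toe_off = numeric(), t_heel_strike = numeric(),
                  raw = numeric(), excluded = logical()))
  }
  flag_boundary_steps(bind_rows(rows))
}
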