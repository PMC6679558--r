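#' Lower-limb orientation Kalman filter
#'
#' A linear Kalman filter tracks, for five body segments (pelvis, both
#' thighs, both shanks), the attitude angles, the attitude rates and the
#' gyroscope biases: a 45-element state (5 segments x 3 angles, 3 rates,
#' 3 biases) with its 45x45 covariance. The prediction integrates the
#' rate states into the angles and relaxes the biases as first-order
#' Gauss-Markov processes; measurement updates come from the gyroscope
#' (rate + bias), the accelerometer tilt, and - where a magnetometer is
#' mounted - the magnetic heading, which is the only observation that
#' constrains yaw.
#'
#' @name orientation_filter
NULL

seg_index <- function(segment) {
  i <- match(segment, SEGMENTS)
  if (is.na(i)) abort(sprintf("unknown segment '%s'", segment),
                      class = "gaitkin_invalid_argument")
  i
}

idx_angle <- function(i) (i - 1) * 3 + 1:3
idx_rate <- function(i) 15 + (i - 1) * 3 + 1:3
idx_bias <- function(i) 30 + (i - 1) * 3 + 1:3

#' Filter noise model for the orientation filter
#'
#' @param config optional [body_config()] whose noise block supplies the
#'   gyroscope measurement noise and bias-drift densities.
#' @param sw process-noise PSD of the attitude-rate states,
#'   (rad/s)^2/Hz; scalar or length-15 diagonal. This is a motion
#'   parameter, not a sensor parameter: it bounds how fast limb rates
#'   may slew between samples, and the default (3) allows the
#'   several-rad/s-per-tenth-of-a-second rate changes seen in walking.
#' @param sbw gyro bias drift PSD, (rad/s^2)^2 s; scalar or length 15.
#' @param beta inverse bias correlation time, 1/s; scalar or length 15.
#' @param v_phi,v_theta,v_psi measurement variances of the roll, pitch
#'   and yaw observations, rad^2.
#' @param v_w gyroscope measurement variance per axis, (rad/s)^2.
#' @param accel_gate accelerometer updates are skipped while
#'   `| ||f|| - g |` exceeds this bound (m/s^2), so that tilt
#'   observations corrupted by linear acceleration do not bias the
#'   attitude.
#' @param rate_gate tilt updates and zero-angular-rate updates are
#'   restricted to quasi-static samples with `||w - bias_est|| <` this
#'   bound (rad/s); a near-gravity specific-force magnitude alone does
#'   not rule out a tangential acceleration that tilts the apparent
#'   gravity direction.
#' @param v_zaru variance of the zero-angular-rate pseudo-measurement
#'   applied during quasi-static samples, (rad/s)^2. Re-anchoring the
#'   rate states at zero whenever the segment is still lets the filter
#'   re-separate the gyro bias from the rate, which keeps the
#'   unobservable yaw of magnetometer-less segments from drifting at
#'   the residual bias rate.
#' @param g gravitational acceleration, m/s^2.
#' @return An object of class `filter_noise`.
#' @export
filter_noise <- function(config = NULL,
                         sw = 3, sbw = NULL, beta = NULL,
                         v_phi = (2 * pi / 180)^2,
                         v_theta = (2 * pi / 180)^2,
                         v_psi = (5 * pi / 180)^2,
                         v_w = NULL, accel_gate = 0.2,
                         rate_gate = 0.3, v_zaru = 0.1^2, g = GRAVITY) {
  nz <- if (is.null(config)) default_noise() else config$noise
  if (is.null(sbw)) sbw <- nz$bias_psd
  if (is.null(beta)) beta <- 1 / nz$bias_tau
  if (is.null(v_w)) v_w <- nz$sigma_w^2
  expand <- function(x) if (length(x) == 1) rep(x, 15) else x
  out <- list(sw = expand(sw), sbw = expand(sbw), beta = expand(beta),
              v_phi = v_phi, v_theta = v_theta, v_psi = v_psi,
              v_w = v_w, accel_gate = accel_gate, rate_gate = rate_gate,
              v_zaru = v_zaru, g = g)
  if (any(unlist(out[c("sw", "sbw", "beta")]) <= 0) ||
      any(c(v_phi, v_theta, v_psi, v_w) <= 0)) {
    abort("all noise diagonals and variances must be positive",
          class = "gaitkin_validation_error")
  }
  structure(out, class = "filter_noise")
}

#' Construct a lower-limb filter state
#'
#' @param x 45-vector: angles (15), rates (15), biases (15) in segment
#'   order pelvis, thigh_L, thigh_R, shank_L, shank_R.
#' @param P 45x45 covariance.
#' @param t state epoch, s.
#' @return An object of class `limb_state`.
#' @export
limb_state <- function(x = numeric(45),
                       P = diag(c(rep((10 * pi / 180)^2, 15),
                                  rep(0.5^2, 15),
                                  rep(0.05^2, 15))),
                       t = 0) {
  stopifnot(length(x) == 45, all(dim(P) == c(45, 45)))
  structure(list(x = x, P = (P + t(P)) / 2, t = t), class = "limb_state")
}

#' @export
print.limb_state <- function(x, ...) {
  ang <- matrix(x$x[1:15], nrow = 3)
  colnames(ang) <- SEGMENTS; rownames(ang) <- c("roll", "pitch", "yaw")
  cat(sprintf("<limb_state> t = %.3f s; angles (deg):\n", x$t))
  print(round(ang * 180 / pi, 2))
  invisible(x)
}

#' Time-propagate the lower-limb filter state
#'
#' Applies the linear transition (angles advance by rate * dt, rates
#' persist, biases decay as Gauss-Markov) and adds the discretised
#' process noise: the angle/rate block integrates the gyro angular
#' random walk (`dt^3/3`, `dt^2/2`, `dt` blocks) and the bias block the
#' Gauss-Markov drift.
#'
#' @param state a [limb_state()].
#' @param dt time step, s (> 0).
#' @param noise a [filter_noise()].
#' @return The propagated `limb_state`.
#' @export
predict_orientation <- function(state, dt, noise) {
  if (!is.numeric(dt) || dt <= 0) {
    abort("dt must be positive", class = "gaitkin_invalid_argument")
  }
  I15 <- diag(15)
  Phi <- diag(45)
  Phi[1:15, 16:30] <- dt * I15
  Phi[31:45, 31:45] <- I15 - diag(noise$beta) * dt
  Q <- matrix(0, 45, 45)
  Q[1:15, 1:15] <- diag(dt^3 / 3 * noise$sw)
  Q[1:15, 16:30] <- diag(dt^2 / 2 * noise$sw)
  Q[16:30, 1:15] <- diag(dt^2 / 2 * noise$sw)
  Q[16:30, 16:30] <- diag(dt * noise$sw)
  Q[31:45, 31:45] <- diag(dt * noise$sbw - dt^2 * noise$sbw * noise$beta +
                            dt^3 / 3 * noise$sbw * noise$beta^2)
  x <- as.numeric(Phi %*% state$x)
  x[1:15] <- wrap_angle(x[1:15])
  P <- Phi %*% state$P %*% t(Phi) + Q
  limb_state(x, P, state$t + dt)
}

# one scalar Kalman update; H is sparse: values hv at state indices hi.
# innovation optionally wrapped to (-pi, pi] for angle measurements.
kf_scalar_update <- function(state, hi, hv, z, R, wrap = FALSE) {
  PHt <- state$P[, hi, drop = FALSE] %*% hv
  S <- sum(hv * PHt[hi]) + R
  innov <- z - sum(hv * state$x[hi])
  if (wrap) innov <- wrap_angle(innov)
  K <- PHt / S
  x <- state$x + as.numeric(K) * innov
  x[1:15] <- wrap_angle(x[1:15])
  P <- state$P - K %*% t(PHt)
  limb_state(x, P, state$t)
}

#' Accelerometer tilt update for one segment
#'
#' Treats the roll and pitch derived from the specific force as direct
#' observations of that segment's attitude states. The update is skipped
#' (with a warning for a zero vector) when the measurement is unusable,
#' and gated on `| ||f|| - g |` so strongly accelerated samples do not
#' corrupt the tilt.
#'
#' @param state a [limb_state()].
#' @param segment one of `pelvis, thigh_L, thigh_R, shank_L, shank_R`.
#' @param f specific-force 3-vector, m/s^2.
#' @param noise a [filter_noise()].
#' @return Updated `limb_state` (unchanged if gated out).
#' @export
update_tilt <- function(state, segment, f, noise) {
  i <- seg_index(segment)
  if (sqrt(sum(f^2)) == 0) {
    warn("zero specific-force sample; tilt update skipped")
    return(state)
  }
  if (abs(sqrt(sum(f^2)) - noise$g) > noise$accel_gate) return(state)
  tilt <- tilt_from_accel(f)
  ia <- idx_angle(i)
  state <- kf_scalar_update(state, ia[1], 1, tilt[["roll"]], noise$v_phi,
                            wrap = TRUE)
  kf_scalar_update(state, ia[2], 1, tilt[["pitch"]], noise$v_theta,
                   wrap = TRUE)
}

#' Magnetometer heading update for one segment
#'
#' Uses the tilt-compensated magnetic heading (evaluated at the current
#' roll/pitch estimates) as a direct yaw observation. This is the only
#' observation that makes yaw observable; segments without a
#' magnetometer drift in yaw.
#'
#' @inheritParams update_tilt
#' @param m magnetic-field 3-vector.
#' @return Updated `limb_state` (unchanged if the field is degenerate).
#' @export
update_heading <- function(state, segment, m, noise) {
  i <- seg_index(segment)
  ia <- idx_angle(i)
  psi <- tryCatch(
    yaw_from_mag(m, state$x[ia[1]], state$x[ia[2]]),
    gaitkin_degenerate_field = function(e) NULL,
    gaitkin_invalid_argument = function(e) NULL)
  if (is.null(psi)) return(state)
  kf_scalar_update(state, ia[3], 1, psi, noise$v_psi, wrap = TRUE)
}

#' Gyroscope update for one segment
#'
#' The gyroscope observes the sum of the attitude-rate and bias states,
#' one axis at a time: `w_meas = rate + bias + v`.
#'
#' @inheritParams update_tilt
#' @param w_meas angular-rate 3-vector, rad/s.
#' @return Updated `limb_state`.
#' @export
update_gyro <- function(state, segment, w_meas, noise) {
  check_finite(w_meas, "w_meas")
  i <- seg_index(segment)
  ir <- idx_rate(i); ib <- idx_bias(i)
  for (ax in 1:3) {
    state <- kf_scalar_update(state, c(ir[ax], ib[ax]), c(1, 1),
                              w_meas[ax], noise$v_w)
  }
  state
}

#' Run the lower-limb orientation filter over a multi-sensor log
#'
#' Processes the pelvis, thigh and shank traces of a tidy IMU log in
#' time order. At every sample epoch the state is propagated to that
#' time, then the gyroscope and (gated) tilt updates are applied for the
#' segments observed there, plus a heading update where a magnetometer
#' column is present. Initial attitude comes from the mean accelerometer
#' tilt over the first `init_window` seconds (assumed quasi-static);
#' initial biases from the standstill gyro mean when `calibrate_bias`.
#'
#' @param log tidy IMU log (see [read_imu_log()] / [simulate_walk()])
#'   containing all five filter segments.
#' @param config a [body_config()].
#' @param noise a [filter_noise()]; defaults from `config`.
#' @param calibrate_bias initialise gyro-bias states from the initial
#'   standstill?
#' @param init_window initial averaging window, s.
#' @return An object of class `orientation_fit` with elements `angles`
#'   (tibble `t, segment, roll, pitch, yaw`, rad), `state` (final
#'   [limb_state()]), `noise`, `init` and `n_epochs`.
#' @export
run_orientation_filter <- function(log, config = body_config(),
                                   noise = filter_noise(config),
                                   calibrate_bias = TRUE,
                                   init_window = 1) {
  missing_seg <- setdiff(SEGMENTS, unique(log$site))
  if (length(missing_seg)) {
    abort(paste0("log lacks segment trace(s): ",
                 paste(missing_seg, collapse = ", ")),
          class = "gaitkin_data_error")
  }
  seg_log <- filter(log, .data$site %in% SEGMENTS)
  t0 <- min(seg_log$t)
  tspan <- vapply(SEGMENTS, function(s) {
    tt <- seg_log$t[seg_log$site == s]; c(min(tt), max(tt))
  }, numeric(2))
  if (max(tspan[1, ]) >= min(tspan[2, ])) {
    abort("segment traces do not overlap in time",
          class = "gaitkin_data_error")
  }
  has_mag <- all(c("mx", "my", "mz") %in% names(seg_log))

  # initialisation from the assumed-static lead-in
  x0 <- numeric(45)
  for (s in SEGMENTS) {
    tr <- seg_log[seg_log$site == s & seg_log$t <= t0 + init_window, ]
    fbar <- colMeans(as.matrix(tr[c("fx", "fy", "fz")]))
    tl <- tilt_from_accel(fbar)
    i <- seg_index(s)
    x0[idx_angle(i)[1:2]] <- tl
    if (has_mag && !anyNA(tr$mx)) {
      mbar <- colMeans(as.matrix(tr[c("mx", "my", "mz")]))
      x0[idx_angle(i)[3]] <- yaw_from_mag(mbar, tl[["roll"]], tl[["pitch"]])
    }
    if (calibrate_bias) {
      x0[idx_bias(i)] <- colMeans(as.matrix(tr[c("wx", "wy", "wz")]))
    }
  }
  state <- limb_state(x0, t = t0)
  init <- state

  seg_log <- arrange(seg_log, .data$t, .data$site)
  times <- seg_log$t
  f_m <- as.matrix(seg_log[c("fx", "fy", "fz")])
  w_m <- as.matrix(seg_log[c("wx", "wy", "wz")])
  m_m <- if (has_mag) as.matrix(seg_log[c("mx", "my", "mz")]) else NULL
  sites <- seg_log$site

  uts <- unique(times)
  rec_ang <- matrix(NA_real_, nrow(seg_log), 3)
  row_start <- match(uts, times)
  row_end <- c(row_start[-1] - 1, length(times))
  for (k in seq_along(uts)) {
    dt <- uts[k] - state$t
    rows <- row_start[k]:row_end[k]
    if (dt > 0) state <- predict_orientation(state, dt, noise)
    for (r in rows) {
      state <- update_gyro(state, sites[r], w_m[r, ], noise)
    }
    for (r in rows) {
      s <- sites[r]
      # quasi-static samples (rotation below the rate gate after
      # removing the estimated bias) admit the tilt update and a
      # zero-angular-rate pseudo-measurement that re-separates the
      # gyro bias from the rate states
      i <- seg_index(s)
      w_free <- w_m[r, ] - state$x[idx_bias(i)]
      if (sqrt(sum(w_free^2)) < noise$rate_gate) {
        ir <- idx_rate(i)
        for (ax in 1:3) {
          state <- kf_scalar_update(state, ir[ax], 1, 0, noise$v_zaru)
        }
        state <- update_tilt(state, s, f_m[r, ], noise)
      }
      if (has_mag && !anyNA(m_m[r, ])) {
        state <- update_heading(state, s, m_m[r, ], noise)
      }
    }
    for (r in rows) {
      rec_ang[r, ] <- state$x[idx_angle(seg_index(sites[r]))]
    }
  }
  angles <- tibble(t = times, segment = sites,
                   roll = rec_ang[, 1], pitch = rec_ang[, 2],
                   yaw = rec_ang[, 3])
  structure(list(angles = angles, state = state, noise = noise,
                 init = init, n_epochs = length(uts)),
            class = "orientation_fit")
}

#' @export
print.orientation_fit <- function(x, ...) {
  cat(sprintf("<orientation_fit> %d epochs, %d segments, t in [%.2f, %.2f] s\n",
              x$n_epochs, length(unique(x$angles$segment)),
              min(x$angles$t), max(x$angles$t)))
  invisible(x)
}

#' @describeIn run_orientation_filter tidy() returns the per-epoch
#'   segment angles as a tibble.
#' @param x an `orientation_fit`.
#' @param ... unused.
#' @export
tidy.orientation_fit <- function(x, ...) x$angles

#' @describeIn run_orientation_filter glance() returns a one-row summary.
#' @export
glance.orientation_fit <- function(x, ...) {
  tibble(n_epochs = x$n_epochs,
         n_segments = length(unique(x$angles$segment)),
         t_start = min(x$angles$t), t_end = max(x$angles$t),
         final_trace_P = sum(diag(x$state$P)))
}
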