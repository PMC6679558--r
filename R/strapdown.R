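#' Foot-mounted strapdown navigation with per-stride zero-velocity updates
#'
#' A deliberately minimal single-sensor comparison method: the foot IMU
#' is mechanized through each swing (attitude by exact axis-angle
#' integration of the gyroscope, velocity and position by trapezoidal
#' integration of the rotated specific force plus gravity), an
#' error-state extended Kalman filter propagates a 9-state covariance
#' (attitude, velocity, position errors; no bias states), and a single
#' zero-velocity pseudo-measurement at the post-swing foot-flat closes
#' the loop. An optional Rauch-Tung-Striebel backward pass smooths the
#' trajectory.
#'
#' @name foot_strapdown
NULL

#' Strapdown filter parameters
#'
#' @param srg gyroscope noise PSD, (rad/s)^2/Hz (scalar, per axis).
#' @param sra accelerometer noise PSD, (m/s^2)^2/Hz.
#' @param g gravitational acceleration, m/s^2.
#' @param zupt_variance zero-velocity measurement variance, (m/s)^2.
#' @param P0 initial 9x9 covariance (attitude, velocity, position
#'   errors).
#' @return An object of class `strapdown_params`.
#' @export
strapdown_params <- function(srg = default_noise()$gyro_psd^2,
                             sra = default_noise()$accel_psd^2,
                             g = GRAVITY, zupt_variance = 1e-4,
                             P0 = diag(c(rep((1 * pi / 180)^2, 2),
                                         (0.1 * pi / 180)^2,
                                         rep(1e-4, 3), rep(1e-8, 3)))) {
  stopifnot(srg > 0, sra > 0, zupt_variance > 0, all(dim(P0) == c(9, 9)))
  structure(list(srg = srg, sra = sra, g = g,
                 zupt_variance = zupt_variance, P0 = P0),
            class = "strapdown_params")
}

rodrigues <- function(axis_angle) {
  th <- sqrt(sum(axis_angle^2))
  if (th < 1e-14) return(diag(3) + skew(axis_angle))
  K <- skew(axis_angle / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' One strapdown mechanization step
#'
#' Advances a navigation state (body-to-local attitude `C`, velocity
#' `v`, position `p`) by one sample: the attitude rotates by the exact
#' axis-angle rotation for `w * dt`, the velocity integrates
#' `C f + g_n` (with `g_n = (0, 0, +g)` in the forward-across-down
#' frame), and the position integrates the velocity trapezoidally.
#'
#' @param state list with `C` (3x3), `v`, `p` (length-3).
#' @param f specific force, m/s^2 (body frame).
#' @param w angular rate, rad/s (body frame).
#' @param dt time step, s (> 0).
#' @param g gravitational acceleration, m/s^2.
#' @return The advanced state list.
#' @export
mechanize <- function(state, f, w, dt, g = GRAVITY) {
  if (dt <= 0) abort("dt must be positive", class = "gaitkin_invalid_argument")
  C_new <- state$C %*% rodrigues(w * dt)
  # average the specific-force projection across the step
  f_n <- 0.5 * (state$C %*% f + C_new %*% f)
  a_n <- as.numeric(f_n) + c(0, 0, g)
  v_new <- state$v + a_n * dt
  p_new <- state$p + 0.5 * (state$v + v_new) * dt
  list(C = C_new, v = v_new, p = p_new)
}

# error-state transition for [dPsi, dv, dp]: dv couples to attitude error
# through -[f_n x] dt, dp to dv through dt I
strapdown_phi <- function(f_n, dt) {
  Phi <- diag(9)
  Phi[4:6, 1:3] <- -skew(f_n) * dt
  Phi[7:9, 4:6] <- diag(3) * dt
  Phi
}

strapdown_q <- function(Phi, params, dt) {
  G <- diag(c(rep(params$srg, 3), rep(params$sra, 3), rep(0, 3)))
  Phi %*% G %*% t(Phi) * dt
}

#' Per-stride zero-velocity-update strapdown strides
#'
#' For every toe-off/heel-strike swing of a foot trace: initialise the
#' attitude from the accelerometer tilt averaged over the preceding
#' foot-flat (yaw set to 0; stride length is yaw-invariant), zero the
#' velocity and position at the end of that foot-flat (the foot is
#' still stationary there), mechanize the raw IMU samples through the
#' swing into the first post-swing foot-flat sample, apply one
#' zero-velocity update there with closed-loop correction, and report
#' the stride as the endpoint displacement of the pass - the foot is
#' motionless from heel-strike to foot-flat, so this is the toe-off to
#' heel-strike displacement. Between the logged samples the signals are
#' reconstructed by cubic splines and integrated in `substeps`
#' sub-intervals, which recovers most of the inter-sample motion of the
#' fast-moving foot. Swings without a following foot-flat are skipped
#' with a warning.
#'
#' @param trace one-foot tibble (`t, fx..fz, wx..wz`).
#' @param events a `gait_events` object for that foot (from
#'   [detect_foot_events()]), or ground-truth events in the same shape.
#' @param params a [strapdown_params()].
#' @param smooth apply the RTS backward pass to the reported trajectory?
#' @param substeps integration sub-intervals per sample interval.
#' @return An object of class `strapdown_fit`: list with `steps` (a
#'   `gait_steps` tibble of stride records), `trajectories` (tibble
#'   `stride, t, x, y, z, vx, vy, vz, smoothed`), and per-stride filter
#'   details in `details`.
#' @export
zupt_ekf_strides <- function(trace, events, params = strapdown_params(),
                             smooth = FALSE, substeps = 4) {
  ev <- if (inherits(events, "gait_events")) events$events else events
  ff <- if (inherits(events, "gait_events")) events$foot_flat else
    attr(events, "foot_flat")
  foot <- if (inherits(events, "gait_events")) events$foot else
    unique(ev$foot)[1]
  swings <- pair_swings(ev)
  t <- trace$t
  f_m <- as.matrix(trace[c("fx", "fy", "fz")])
  w_m <- as.matrix(trace[c("wx", "wy", "wz")])
  steps <- list(); trajs <- list(); details <- list()
  for (si in seq_len(nrow(swings))) {
    sw <- swings[si, ]
    # preceding foot-flat: mechanization starts at its end, where the
    # foot is still stationary
    pre <- if (!is.null(ff) && nrow(ff)) {
      cand <- ff[ff$t_start <= sw$t_toe_off, ]
      if (nrow(cand)) unlist(cand[which.max(cand$t_start),
                                  c("t_start", "t_end")]) else
        c(sw$t_toe_off - 0.5, sw$t_toe_off)
    } else c(sw$t_toe_off - 0.5, sw$t_toe_off)
    pre[2] <- min(pre[2], sw$t_toe_off)
    sel_pre <- which(t >= pre[1] & t <= pre[2])
    if (!length(sel_pre)) sel_pre <- max(1, which.min(abs(t - sw$t_toe_off)))
    fbar <- colMeans(f_m[sel_pre, , drop = FALSE])
    tl <- tilt_from_accel(fbar)
    # post-swing foot-flat sample for the ZUPT
    post <- if (!is.null(ff) && nrow(ff)) {
      cand <- ff$t_start[ff$t_start >= sw$t_heel_strike]
      if (length(cand)) min(cand) else NA_real_
    } else NA_real_
    if (is.na(post)) {
      # first sample after heel-strike as the quasi-static anchor
      after <- which(t > sw$t_heel_strike)
      if (!length(after)) {
        warn(sprintf("no foot-flat after the swing at t = %.2f s; stride skipped",
                     sw$t_toe_off))
        next
      }
      post <- t[min(after)]
    }
    i0 <- max(sel_pre)
    i1 <- which.min(abs(t - post))
    if (i1 <= i0 + 1) next
    idx <- i0:i1
    n <- length(idx)
    state <- list(C = dcm_from_euler(tl[["roll"]], tl[["pitch"]], 0),
                  v = c(0, 0, 0), p = c(0, 0, 0))
    P <- params$P0
    xs <- matrix(0, n, 9)          # [euler, v, p] at the sample times
    Ps_pred <- vector("list", n); Ps_filt <- vector("list", n)
    Phis <- vector("list", n)
    xs[1, ] <- c(euler_from_dcm(state$C), state$v, state$p)
    Ps_pred[[1]] <- P; Ps_filt[[1]] <- P; Phis[[1]] <- diag(9)
    # cubic-spline signal reconstruction on an integration sub-grid
    ts <- t[idx]
    tt <- seq_len((n - 1) * substeps + 1)
    tt <- ts[1] + (tt - 1) * (ts[n] - ts[1]) / ((n - 1) * substeps)
    fs <- apply(f_m[idx, , drop = FALSE], 2,
                function(cl) stats::spline(ts, cl, xout = tt)$y)
    ws <- apply(w_m[idx, , drop = FALSE], 2,
                function(cl) stats::spline(ts, cl, xout = tt)$y)
    for (k in 2:n) {
      dtk <- ts[k] - ts[k - 1]
      f_n <- as.numeric(state$C %*% f_m[idx[k - 1], ])
      for (j in ((k - 2) * substeps + 1):((k - 1) * substeps)) {
        state <- mechanize(state, 0.5 * (fs[j, ] + fs[j + 1, ]),
                           0.5 * (ws[j, ] + ws[j + 1, ]),
                           tt[j + 1] - tt[j], params$g)
      }
      Phi <- strapdown_phi(f_n, dtk)
      P <- Phi %*% P %*% t(Phi) + strapdown_q(Phi, params, dtk)
      P <- (P + t(P)) / 2
      Phis[[k]] <- Phi
      Ps_pred[[k]] <- P
      Ps_filt[[k]] <- P
      xs[k, ] <- c(euler_from_dcm(state$C), state$v, state$p)
    }
    # single zero-velocity update at the post-swing foot-flat sample
    H <- matrix(0, 3, 9); H[, 4:6] <- -diag(3)
    z <- -state$v
    S <- H %*% P %*% t(H) + diag(params$zupt_variance, 3)
    K <- P %*% t(H) %*% solve(S)
    dx <- as.numeric(K %*% (z - c(0, 0, 0)))
    P_upd <- (diag(9) - K %*% H) %*% P
    P_upd <- (P_upd + t(P_upd)) / 2
    Ps_filt[[n]] <- P_upd
    # closed-loop correction of the final nav state
    state$C <- rodrigues(-dx[1:3]) %*% state$C
    state$v <- state$v - dx[4:6]
    state$p <- state$p - dx[7:9]
    # endpoint displacement: the foot is motionless from heel-strike to
    # the ZUPT epoch, so this is the toe-off -> heel-strike stride
    stride_filt <- sqrt(sum(state$p^2))
    sm <- rts_smooth(xs, Ps_pred, Ps_filt, Phis, dx_final = dx)
    stride_sm <- sqrt(sum(sm$x[n, 7:9]^2))
    steps[[length(steps) + 1]] <- tibble(
      kind = "stride_length", side = sw$foot,
      value = if (smooth) stride_sm else stride_filt,
      t_toe_off = sw$t_toe_off, t_heel_strike = sw$t_heel_strike)
    use_x <- if (smooth) sm$x else xs
    trajs[[length(trajs) + 1]] <- tibble(
      stride = si, t = t[idx],
      x = use_x[, 7], y = use_x[, 8], z = use_x[, 9],
      vx = use_x[, 4], vy = use_x[, 5], vz = use_x[, 6],
      smoothed = smooth)
    details[[length(details) + 1]] <- list(
      stride = si, stride_filtered = stride_filt,
      stride_smoothed = stride_sm, dx_zupt = dx,
      P_filtered = Ps_filt, P_smoothed = sm$P, idx = idx)
  }
  steps_tb <- if (length(steps)) flag_boundary_steps(bind_rows(steps)) else
    tibble(kind = character(), side = character(), value = numeric(),
           t_toe_off = numeric(), t_heel_strike = numeric(),
           excluded = logical())
  structure(list(steps = steps_tb,
                 trajectories = if (length(trajs)) bind_rows(trajs) else NULL,
                 details = details, foot = foot, params = params),
            class = "strapdown_fit")
}

#' @export
print.strapdown_fit <- function(x, ...) {
  cat(sprintf("<strapdown_fit> foot %s: %d strides\n",
              x$foot, nrow(x$steps)))
  print(x$steps, n = 6)
  invisible(x)
}

#' Rauch-Tung-Striebel smoothing of a per-stride error-state pass
#'
#' Backward recursion over the stored forward-pass records. Because the
#' forward pass applies a single end-of-swing update, the filtered error
#' state is zero at every epoch except the last; the smoother carries
#' that final correction backwards with gain
#' `A_k = P_f(k) Phi(k+1)' P_pred(k+1)^-1` and subtracts the smoothed
#' error from the recorded trajectory. Smoothed variances never exceed
#' the filtered ones.
#'
#' @param xs n x 9 matrix of forward nav states `[euler, v, p]`.
#' @param Ps_pred,Ps_filt lists of predicted / filtered 9x9 covariances.
#' @param Phis list of transition matrices (`Phis[[k]]` maps k-1 to k).
#' @param dx_final the error-state estimate at the final epoch (from the
#'   zero-velocity update); zero vector if none.
#' @return List with `x` (smoothed n x 9 trajectory) and `P` (list of
#'   smoothed covariances).
#' @export
rts_smooth <- function(xs, Ps_pred, Ps_filt, Phis, dx_final = rep(0, 9)) {
  n <- nrow(xs)
  if (length(Ps_pred) != n || length(Ps_filt) != n || length(Phis) != n) {
    abort("forward-pass records disagree in length",
          class = "gaitkin_invalid_argument")
  }
  if (n == 1) return(list(x = xs, P = Ps_filt))
  dxs <- matrix(0, n, 9)
  dxs[n, ] <- dx_final
  Ps <- vector("list", n)
  Ps[[n]] <- Ps_filt[[n]]
  for (k in (n - 1):1) {
    A <- Ps_filt[[k]] %*% t(Phis[[k + 1]]) %*% solve(Ps_pred[[k + 1]])
    # filtered error state is zero before the final update
    dxs[k, ] <- as.numeric(A %*% dxs[k + 1, ])
    Ps[[k]] <- Ps_filt[[k]] +
      A %*% (Ps[[k + 1]] - Ps_pred[[k + 1]]) %*% t(A)
    Ps[[k]] <- (Ps[[k]] + t(Ps[[k]])) / 2
  }
  x_sm <- xs - dxs
  list(x = x_sm, P = Ps)
}
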