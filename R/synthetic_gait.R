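#' Parametric treadmill-walk simulator
#'
#' Generates seven-sensor IMU logs (pelvis, both thighs, shanks and
#' feet) for a steady walk, together with complete ground truth, so that
#' every stage of the gait pipeline can be validated without external
#' recordings. Joint-angle trajectories are smooth (C2) transitions with
#' genuine double-support dwells, so each foot has a true foot-flat
#' interval; node positions follow the five-segment forward-kinematic
#' chain with the stance foot pinned and alternating; angular rates and
#' specific forces are derived from the orientation and position
#' histories on a finely oversampled grid before decimation to the
#' logger rate, which keeps the emitted signals dynamically consistent
#' (re-differentiating the positions reproduces the specific forces).
#'
#' @name synthetic_gait
NULL

# quintic smoothstep: C2 transition from 0 at u=0 to 1 at u=1
smoothstep5 <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

# C2 bump on [0,1]: sin^3(pi u), zero value/slope at both ends
bump3 <- function(u) ifelse(u > 0 & u < 1, sin(pi * u)^3, 0)

# closed-form integral of bump3 from 0 to u (area 4/(3 pi) at u=1)
bump3_int <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  (2 / 3 - cos(pi * u) + cos(pi * u)^3 / 3) / pi
}

#' Simulator configuration
#'
#' Defaults emulate the treadmill walks the package targets: a per-foot
#' gait cycle frequency of 0.82 Hz sampled at 26 Hz, sagittal-dominant
#' limb motion (thigh pitch +-25 deg, swing knee flexion to 45 deg of
#' shank pitch, pelvis roll/pitch/yaw 2/3/5 deg), and low-cost-MEMS
#' noise levels (accelerometer 400 ug/sqrt(Hz), gyroscope
#' 0.01 deg/s/sqrt(Hz), turn-on gyro bias uniform within +-20 deg/s).
#'
#' @param cadence per-foot gait cycle frequency, Hz.
#' @param n_cycles number of full gait cycles (each cycle is one swing
#'   per foot).
#' @param thigh_amp,shank_amp,pelvis_pitch_amp,pelvis_yaw_amp,pelvis_roll_amp
#'   angle amplitudes in degrees: thigh pitch transitions between
#'   +-`thigh_amp`; `shank_amp` is the peak swing shank pitch reached via
#'   knee flexion; pelvis amplitudes as named.
#' @param swing_frac fraction of a half-cycle spent in swing (the rest
#'   is double-support dwell). The default 0.75 gives a ~61/39
#'   stance/swing split with ~12% double support per side, and leaves
#'   the double-support dwell long enough to be resolved at the 26 Hz
#'   logger rate.
#' @param foot_peak_amp amplitudes (rad/s) of the toe-off and
#'   heel-strike foot pitch-rate bumps (the mid-swing bump amplitude is
#'   set by the zero-net-rotation constraint).
#' @param lead_in,lead_out standstill padding before and after the walk, s.
#' @param sample_rate logger sample rate, Hz.
#' @param oversample fine-grid factor used for differentiation.
#' @param noise_on add sensor noise and turn-on gyro biases?
#' @param noise noise block as in [body_config()] (defaults from it).
#' @param gyro_bias_range half-width of the uniform turn-on gyro bias
#'   draw, rad/s.
#' @param mag_field local magnetic field in the navigation frame, uT
#'   (sensed by the pelvis and right-foot magnetometers).
#' @param sigma_m magnetometer noise standard deviation, uT.
#' @param knee_bound knee hyperextension bound, rad; configurations
#'   whose knee flexion drops below `-knee_bound` are rejected.
#' @param config a [body_config()] providing segment lengths.
#' @param seed integer seed for the noise draw.
#' @return An object of class `gait_sim_config`.
#' @export
gait_sim_config <- function(cadence = 0.82, n_cycles = 25,
                            thigh_amp = 25, shank_amp = 45,
                            pelvis_pitch_amp = 3, pelvis_yaw_amp = 5,
                            pelvis_roll_amp = 2,
                            swing_frac = 0.75,
                            foot_peak_amp = c(3, 3),
                            lead_in = 1.5, lead_out = 1.5,
                            sample_rate = 26, oversample = 20,
                            noise_on = TRUE, noise = list(),
                            gyro_bias_range = NULL,
                            mag_field = c(22, 0, 41), sigma_m = 0.3,
                            knee_bound = 1 * pi / 180,
                            config = body_config(), seed = 1L) {
  stopifnot(cadence > 0, n_cycles >= 1, sample_rate > 0,
            swing_frac > 0, swing_frac < 1,
            thigh_amp >= 0, pelvis_roll_amp >= 0)
  nz <- utils::modifyList(default_noise(sample_rate), as.list(noise))
  if (is.null(gyro_bias_range)) gyro_bias_range <- nz$gyro_bias_range
  flex_amp <- shank_amp * pi / 180
  if (flex_amp < -knee_bound) {
    abort("shank amplitude implies knee hyperextension beyond the bound",
          class = "gaitkin_config_error")
  }
  structure(list(cadence = cadence, n_cycles = as.integer(n_cycles),
                 thigh_amp = thigh_amp * pi / 180,
                 flex_amp = flex_amp,
                 pelvis_pitch_amp = pelvis_pitch_amp * pi / 180,
                 pelvis_yaw_amp = pelvis_yaw_amp * pi / 180,
                 pelvis_roll_amp = pelvis_roll_amp * pi / 180,
                 swing_frac = swing_frac, foot_peak_amp = foot_peak_amp,
                 lead_in = lead_in, lead_out = lead_out,
                 sample_rate = sample_rate, oversample = oversample,
                 noise_on = noise_on, noise = nz,
                 gyro_bias_range = gyro_bias_range,
                 mag_field = mag_field, sigma_m = sigma_m,
                 knee_bound = knee_bound,
                 body = config, seed = as.integer(seed)),
            class = "gait_sim_config")
}

# ---- continuous-time kinematics -------------------------------------------

# block timing: 2*n_cycles swing blocks, each swing (sw) + dwell (ds);
# odd blocks swing the right foot. Returns closure data used everywhere.
sim_timeline <- function(cfg) {
  Tc <- 1 / cfg$cadence            # full cycle per foot
  H <- Tc / 2                      # one swing block (swing + dwell)
  sw <- cfg$swing_frac * H
  ds <- H - sw
  n_blocks <- 2 * cfg$n_cycles
  t_to <- cfg$lead_in + (seq_len(n_blocks) - 1) * H
  t_hs <- t_to + sw
  total <- cfg$lead_in + n_blocks * H + cfg$lead_out
  list(H = H, sw = sw, ds = ds, n_blocks = n_blocks,
       t_to = t_to, t_hs = t_hs, total = total,
       swing_foot = ifelse(seq_len(n_blocks) %% 2 == 1, "right", "left"),
       # right-thigh target sign at the end of each block
       sgn = ifelse(seq_len(n_blocks) %% 2 == 1, 1, -1))
}

# segment Euler angles at arbitrary times; returns list of 3-col matrices
sim_angles <- function(tvec, cfg, tl) {
  n <- length(tvec)
  blk <- findInterval(tvec, tl$t_to)        # 0 = lead-in
  u <- numeric(n)                            # swing phase in [0,1]
  in_swing <- blk >= 1 & tvec < tl$t_hs[pmax(blk, 1)]
  u[blk >= 1] <- pmin((tvec[blk >= 1] - tl$t_to[blk[blk >= 1]]) / tl$sw, 1)
  sgn <- ifelse(blk >= 1, tl$sgn[pmax(blk, 1)], -tl$sgn[1])
  # transition waveform: from -sgn to +sgn over the swing, held in dwell
  wave <- sgn * (2 * smoothstep5(u) - 1)
  wave[blk == 0] <- -tl$sgn[1]
  th_TR <- cfg$thigh_amp * wave
  th_TL <- -th_TR
  swing_R <- in_swing & tl$swing_foot[pmax(blk, 1)] == "right" & blk >= 1
  swing_L <- in_swing & tl$swing_foot[pmax(blk, 1)] == "left" & blk >= 1
  flex_R <- ifelse(swing_R, cfg$flex_amp * bump3(u), 0)
  flex_L <- ifelse(swing_L, cfg$flex_amp * bump3(u), 0)
  th_SR <- th_TR - flex_R
  th_SL <- th_TL - flex_L
  # pelvis: yaw alternates with the swings, pitch bumps every swing,
  # roll bumps with the side of the swinging leg
  ps_yaw <- cfg$pelvis_yaw_amp * wave
  bump_all <- ifelse(in_swing, bump3(u), 0)
  ps_pitch <- cfg$pelvis_pitch_amp * bump_all
  ps_roll <- cfg$pelvis_roll_amp * bump_all *
    ifelse(blk >= 1 & tl$swing_foot[pmax(blk, 1)] == "right", 1, -1)
  # foot pitch: integral of the three-bump sagittal rate pattern,
  # extending half a bump beyond the swing on both sides (heel pivot)
  th_FR <- foot_pitch_series(tvec, "right", cfg, tl)
  th_FL <- foot_pitch_series(tvec, "left", cfg, tl)
  zero <- numeric(n)
  list(pelvis = cbind(roll = ps_roll, pitch = ps_pitch, yaw = ps_yaw),
       thigh_L = cbind(roll = zero, pitch = th_TL, yaw = zero),
       thigh_R = cbind(roll = zero, pitch = th_TR, yaw = zero),
       shank_L = cbind(roll = zero, pitch = th_SL, yaw = zero),
       shank_R = cbind(roll = zero, pitch = th_SR, yaw = zero),
       foot_L = cbind(roll = zero, pitch = th_FL, yaw = zero),
       foot_R = cbind(roll = zero, pitch = th_FR, yaw = zero))
}

# bump layout of the foot sagittal rate (in swing-phase units u, with
# u = 0 at toe-off and u = 1 at heel-strike): negative bumps centred AT
# toe-off and heel-strike - the foot pivots about the grounded heel
# during late stance (heel-off) and early stance (forefoot lowering),
# so the rotation starts before toe-off and ends after heel-strike
# while the heel position stays pinned - and a positive mid-swing bump
# whose amplitude enforces zero net rotation per stride.
foot_rate_layout <- function(cfg) {
  ctr <- c(0, 0.50, 1); wid <- c(0.30, 0.40, 0.30)
  a1 <- cfg$foot_peak_amp[1]; a3 <- cfg$foot_peak_amp[2]
  a2 <- (a1 * wid[1] + a3 * wid[3]) / wid[2]
  list(ctr = ctr, wid = wid, amp = c(-a1, a2, -a3))
}

# integrated foot pitch as a function of swing phase u; zero for
# u <= -0.15 and u >= 1.15
foot_pitch_profile <- function(u, cfg, tl) {
  ly <- foot_rate_layout(cfg)
  th <- numeric(length(u))
  for (i in 1:3) {
    x <- (u - ly$ctr[i] + ly$wid[i] / 2) / ly$wid[i]
    th <- th + ly$amp[i] * ly$wid[i] * tl$sw * bump3_int(x)
  }
  th
}

# foot pitch over absolute time for one foot, summing the contributions
# of its own swing blocks (supports are disjoint)
foot_pitch_series <- function(tvec, foot, cfg, tl) {
  to <- tl$t_to[tl$swing_foot == foot]
  j <- findInterval(tvec, to)
  th <- numeric(length(tvec))
  ok <- j >= 1
  th[ok] <- foot_pitch_profile((tvec[ok] - to[j[ok]]) / tl$sw, cfg, tl)
  ok2 <- j + 1 <= length(to)
  th[ok2] <- th[ok2] +
    foot_pitch_profile((tvec[ok2] - to[j[ok2] + 1]) / tl$sw, cfg, tl)
  th
}

# node positions at arbitrary times: stance pinning with per-regime pins
sim_positions <- function(tvec, ang, cfg, tl) {
  ln <- cfg$body$lengths
  # per-time chain displacement vectors (3-col matrices)
  seg_vec <- function(a, l) cbind(-l * sin(a[, "pitch"]), 0,
                                  -l * cos(a[, "pitch"]))
  vSR <- seg_vec(ang$shank_R, ln$shank_R)
  vTR <- seg_vec(ang$thigh_R, ln$thigh_R)
  vSL <- seg_vec(ang$shank_L, ln$shank_L)
  vTL <- seg_vec(ang$thigh_L, ln$thigh_L)
  ph <- ang$pelvis[, "roll"]; th <- ang$pelvis[, "pitch"]
  ps <- ang$pelvis[, "yaw"]
  # second column of the pelvis DCM times -l_P: right hip -> left hip
  vP <- -ln$pelvis * cbind(-cos(ph) * sin(ps) + sin(ph) * sin(th) * cos(ps),
                           cos(ph) * cos(ps) + sin(ph) * sin(th) * sin(ps),
                           sin(ph) * cos(th))
  regime <- findInterval(tvec, tl$t_hs)    # pin switches at heel-strikes
  stance_right <- regime %% 2 == 1         # regime 0: left foot at origin
  n <- length(tvec)
  nodes <- c("foot_L", "knee_L", "hip_L", "hip_R", "knee_R", "foot_R")
  pos <- lapply(setNames(nodes, nodes), function(x) matrix(0, n, 3))
  # chains relative to the pinned foot
  iR <- which(stance_right); iL <- which(!stance_right)
  if (length(iR)) {
    pos$foot_R[iR, ] <- 0
    pos$knee_R[iR, ] <- vSR[iR, , drop = FALSE]
    pos$hip_R[iR, ] <- pos$knee_R[iR, , drop = FALSE] + vTR[iR, , drop = FALSE]
    pos$hip_L[iR, ] <- pos$hip_R[iR, , drop = FALSE] + vP[iR, , drop = FALSE]
    pos$knee_L[iR, ] <- pos$hip_L[iR, , drop = FALSE] - vTL[iR, , drop = FALSE]
    pos$foot_L[iR, ] <- pos$knee_L[iR, , drop = FALSE] - vSL[iR, , drop = FALSE]
  }
  if (length(iL)) {
    pos$foot_L[iL, ] <- 0
    pos$knee_L[iL, ] <- vSL[iL, , drop = FALSE]
    pos$hip_L[iL, ] <- pos$knee_L[iL, , drop = FALSE] + vTL[iL, , drop = FALSE]
    pos$hip_R[iL, ] <- pos$hip_L[iL, , drop = FALSE] - vP[iL, , drop = FALSE]
    pos$knee_R[iL, ] <- pos$hip_R[iL, , drop = FALSE] - vTR[iL, , drop = FALSE]
    pos$foot_R[iL, ] <- pos$knee_R[iL, , drop = FALSE] - vSR[iL, , drop = FALSE]
  }
  pos
}

# world pin positions per regime (regime r covers [t_hs[r], t_hs[r+1]))
sim_pins <- function(cfg, tl) {
  pins <- matrix(0, tl$n_blocks + 1, 3)   # pin of regime r in row r+1
  for (r in seq_len(tl$n_blocks)) {
    # landing foot position at t_hs[r] relative to regime r-1's pin:
    # evaluate just below the switch (angles are C2, slope zero there)
    t_ev <- tl$t_hs[r] - 1e-9
    ang0 <- sim_angles(t_ev, cfg, tl)
    rel0 <- sim_positions(t_ev, ang0, cfg, tl)
    landing <- if (tl$swing_foot[r] == "right") "foot_R" else "foot_L"
    pins[r + 1, ] <- pins[r, ] + rel0[[landing]][1, ]
  }
  pins
}

# absolute node positions: relative chain + pin of the active regime
sim_world_positions <- function(tvec, ang, cfg, tl, pins) {
  rel <- sim_positions(tvec, ang, cfg, tl)
  regime <- findInterval(tvec, tl$t_hs)
  offset <- pins[regime + 1, , drop = FALSE]
  lapply(rel, function(m) m + offset)
}

# ---- sensor synthesis ------------------------------------------------------

euler_rates_to_body <- function(ang, dang) {
  ph <- ang[, "roll"]; th <- ang[, "pitch"]
  cbind(dang[, "roll"] - dang[, "yaw"] * sin(th),
        dang[, "pitch"] * cos(ph) + dang[, "yaw"] * sin(ph) * cos(th),
        -dang[, "pitch"] * sin(ph) + dang[, "yaw"] * cos(ph) * cos(th))
}

# rotate nav-frame rows into the body frame given Euler angle rows
rotate_to_body <- function(vec_n, ang) {
  ph <- ang[, "roll"]; th <- ang[, "pitch"]; ps <- ang[, "yaw"]
  cph <- cos(ph); sph <- sin(ph); cth <- cos(th); sth <- sin(th)
  cps <- cos(ps); sps <- sin(ps)
  # rows of C' (= columns of C)
  x <- vec_n[, 1]; y <- vec_n[, 2]; z <- vec_n[, 3]
  cbind(cth * cps * x + cth * sps * y - sth * z,
        (-cph * sps + sph * sth * cps) * x +
          (cph * cps + sph * sth * sps) * y + sph * cth * z,
        (sph * sps + cph * sth * cps) * x +
          (-sph * cps + cph * sth * sps) * y + cph * cth * z)
}

central_diff <- function(m, dt) {
  n <- nrow(m)
  d <- (m[c(2:n, n), , drop = FALSE] - m[c(1, 1:(n - 1)), , drop = FALSE]) /
    (dt * c(1, rep(2, n - 2), 1))
  d
}

second_diff <- function(m, dt) {
  n <- nrow(m)
  up <- m[c(2:n, n), , drop = FALSE]
  dn <- m[c(1, 1:(n - 1)), , drop = FALSE]
  d2 <- (up - 2 * m + dn) / dt^2
  d2[1, ] <- d2[2, ]; d2[n, ] <- d2[n - 1, ]
  d2
}

#' Simulate a treadmill walk
#'
#' @param config a [gait_sim_config()].
#' @return An object of class `gait_sim`: list with
#'   * `log`: tidy IMU log tibble (`t, site, fx..fz, wx..wz, mx..mz`;
#'     magnetometer columns are `NA` except on the pelvis and right
#'     foot);
#'   * `truth`: list with `angles` (per-segment Euler series),
#'     `events` (`foot, event, t` toe-offs and heel-strikes),
#'     `foot_flat` (`foot, t_start, t_end`), `steps` (true step/stride
#'     records), `trajectories` (node positions), and `gyro_bias`
#'     (planted per-site biases);
#'   * `config`: the configuration used.
#' @examples
#' sim <- simulate_walk(gait_sim_config(n_cycles = 3, noise_on = FALSE))
#' sim$truth$steps
#' @export
simulate_walk <- function(config = gait_sim_config()) {
  cfg <- config
  tl <- sim_timeline(cfg)
  dt <- 1 / cfg$sample_rate
  dtf <- dt / cfg$oversample
  n_s <- floor(tl$total / dt) + 1
  t_s <- (seq_len(n_s) - 1) * dt
  n_f <- (n_s - 1) * cfg$oversample + 1
  t_f <- (seq_len(n_f) - 1) * dtf

  ang_f <- sim_angles(t_f, cfg, tl)
  pins <- sim_pins(cfg, tl)
  nodes_f <- sim_world_positions(t_f, ang_f, cfg, tl, pins)

  # sensor mounting: pelvis at the hip midpoint, thigh/shank sensors at
  # the segment midpoints, foot sensors at the heels
  sens_pos <- list(
    pelvis = (nodes_f$hip_L + nodes_f$hip_R) / 2,
    thigh_L = (nodes_f$hip_L + nodes_f$knee_L) / 2,
    thigh_R = (nodes_f$hip_R + nodes_f$knee_R) / 2,
    shank_L = (nodes_f$knee_L + nodes_f$foot_L) / 2,
    shank_R = (nodes_f$knee_R + nodes_f$foot_R) / 2,
    foot_L = nodes_f$foot_L,
    foot_R = nodes_f$foot_R)

  pick <- seq(1, n_f, by = cfg$oversample)
  g_n <- c(0, 0, cfg$body$g)
  rows <- list()
  for (s in SITES) {
    ang <- ang_f[[s]]
    dang <- central_diff(ang, dtf)
    w_b <- euler_rates_to_body(ang, dang)
    a_n <- second_diff(sens_pos[[s]], dtf)
    f_b <- rotate_to_body(sweep(a_n, 2, g_n), ang)
    has_mag <- s %in% c("pelvis", "foot_R")
    m_b <- if (has_mag) {
      rotate_to_body(matrix(cfg$mag_field, n_f, 3, byrow = TRUE), ang)
    } else NULL
    rows[[s]] <- tibble(
      t = t_s, site = s,
      fx = f_b[pick, 1], fy = f_b[pick, 2], fz = f_b[pick, 3],
      wx = w_b[pick, 1], wy = w_b[pick, 2], wz = w_b[pick, 3],
      mx = if (has_mag) m_b[pick, 1] else NA_real_,
      my = if (has_mag) m_b[pick, 2] else NA_real_,
      mz = if (has_mag) m_b[pick, 3] else NA_real_)
  }
  log <- bind_rows(rows)

  # ---- ground truth --------------------------------------------------------
  truth_angles <- bind_rows(lapply(SITES, function(s) {
    tibble(t = t_s, segment = s,
           roll = ang_f[[s]][pick, 1], pitch = ang_f[[s]][pick, 2],
           yaw = ang_f[[s]][pick, 3])
  }))
  events <- tibble(
    foot = rep(ifelse(tl$swing_foot == "right", "right", "left"), 2),
    event = rep(c("toe_off", "heel_strike"), each = tl$n_blocks),
    t = c(tl$t_to, tl$t_hs)) %>% arrange(.data$t)
  # the foot pivots about the heel for 0.15*sw on both sides of the
  # swing, so the flat (zero-rotation) interval is correspondingly
  # shorter than the pinned-position stance
  tail <- 0.15 * tl$sw
  foot_flat <- bind_rows(lapply(c("left", "right"), function(ft) {
    to <- tl$t_to[tl$swing_foot == ft]
    hs <- tl$t_hs[tl$swing_foot == ft]
    tibble(foot = ft,
           t_start = c(0, hs + tail),
           t_end = c(to - tail, tl$total))
  }))
  # true step records at exact event times
  steps <- list()
  for (r in seq_len(tl$n_blocks)) {
    t_ev <- c(tl$t_to[r], tl$t_hs[r])
    angr <- sim_angles(t_ev, cfg, tl)
    wp <- sim_world_positions(t_ev, angr, cfg, tl, pins)
    ft <- tl$swing_foot[r]
    land <- if (ft == "right") "foot_R" else "foot_L"
    d_step <- wp$foot_L[2, ] - wp$foot_R[2, ]
    d_stride <- wp[[land]][2, ] - wp[[land]][1, ]
    hip_st <- if (ft == "right") "hip_L" else "hip_R"
    hip_sw <- if (ft == "right") "hip_R" else "hip_L"
    d_hst <- wp[[hip_st]][2, 1:2] - wp[[hip_st]][1, 1:2]
    d_hsw <- wp[[hip_sw]][2, 1:2] - wp[[hip_sw]][1, 1:2]
    steps[[r]] <- tibble(
      kind = c("step_length_feet", "stride_length",
               "step_length_hip_stance", "step_length_hip_swing"),
      side = c(ft, ft, if (ft == "right") "left" else "right", ft),
      value = c(sqrt(sum(d_step^2)), sqrt(sum(d_stride^2)),
                sqrt(sum(d_hst^2)), sqrt(sum(d_hsw^2))),
      t_toe_off = tl$t_to[r], t_heel_strike = tl$t_hs[r])
  }
  truth_steps <- flag_boundary_steps(bind_rows(steps))
  traj <- bind_rows(lapply(names(nodes_f), function(nd) {
    tibble(t = t_s, node = nd, x = nodes_f[[nd]][pick, 1],
           y = nodes_f[[nd]][pick, 2], z = nodes_f[[nd]][pick, 3])
  }))

  # ---- noise ---------------------------------------------------------------
  biases <- setNames(vector("list", length(SITES)), SITES)
  for (s in SITES) biases[[s]] <- c(0, 0, 0)
  if (cfg$noise_on) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(cfg$seed)
    for (s in SITES) {
      sel <- log$site == s
      ns <- sum(sel)
      b <- runif(3, -cfg$gyro_bias_range, cfg$gyro_bias_range)
      biases[[s]] <- b
      wc <- c("wx", "wy", "wz"); fc <- c("fx", "fy", "fz")
      log[sel, wc] <- as.data.frame(
        as.matrix(log[sel, wc]) + matrix(b, ns, 3, byrow = TRUE) +
          matrix(rnorm(3 * ns, sd = cfg$noise$sigma_w), ns, 3))
      log[sel, fc] <- as.data.frame(
        as.matrix(log[sel, fc]) +
          matrix(rnorm(3 * ns, sd = cfg$noise$sigma_a), ns, 3))
      if (!anyNA(log$mx[sel])) {
        mc <- c("mx", "my", "mz")
        log[sel, mc] <- as.data.frame(
          as.matrix(log[sel, mc]) +
            matrix(rnorm(3 * ns, sd = cfg$sigma_m), ns, 3))
      }
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  attr(log, "units") <- "SI"
  structure(list(log = log,
                 truth = list(angles = truth_angles, events = events,
                              foot_flat = foot_flat, steps = truth_steps,
                              trajectories = traj, gyro_bias = biases,
                              timeline = tl),
                 config = cfg),
            class = "gait_sim")
}

#' @export
print.gait_sim <- function(x, ...) {
  tl <- x$truth$timeline
  cat(sprintf(paste0("<gait_sim> %.1f s walk, %d cycles/foot at %.2f Hz, ",
                     "%d sites x %d samples (noise %s)\n"),
              tl$total, x$config$n_cycles, x$config$cadence,
              length(unique(x$log$site)), sum(x$log$site == "pelvis"),
              if (x$config$noise_on) "on" else "off"))
  invisible(x)
}

#' Synthetic three-peak foot gyroscope fixture
#'
#' Builds the idealised sagittal angular-rate pattern of a foot-mounted
#' sensor over one swing: negative bumps at toe-off and heel-strike and
#' a positive bump at mid-swing, so the low-passed magnitude shows
#' exactly three peaks. Used as a unit fixture for the gait event
#' detector.
#'
#' @param times evaluation timestamps, s.
#' @param t_toe_off,t_heel_strike swing bounds (peak times of the outer
#'   bumps), s.
#' @param peak_amplitudes length-3 amplitudes (rad/s, positive) of the
#'   toe-off, mid-swing and heel-strike bumps.
#' @param width full bump width, s.
#' @return Numeric signal, zero outside the bumps.
#' @export
make_fig5_gyro <- function(times, t_toe_off, t_heel_strike,
                           peak_amplitudes = c(3, 3, 3), width = 0.3) {
  stopifnot(t_toe_off < t_heel_strike, length(peak_amplitudes) == 3)
  ctr <- c(t_toe_off, (t_toe_off + t_heel_strike) / 2, t_heel_strike)
  amp <- peak_amplitudes * c(-1, 1, -1)
  y <- numeric(length(times))
  for (i in 1:3) {
    y <- y + amp[i] * bump3((times - ctr[i] + width / 2) / width)
  }
  y
}
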