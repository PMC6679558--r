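#' Forward kinematics of the five-segment lower-limb skeletal model
#'
#' The skeleton consists of the pelvis and the left/right thighs and
#' shanks; the feet are folded into extended shanks reaching the heel.
#' Positions are accumulated from the stance foot (pinned at the origin
#' of the local-level frame) along shank - thigh - pelvis - thigh -
#' shank to the swing foot, each segment vector being a constant
#' body-frame vector rotated by that segment's direction cosine matrix.
#' Body-frame conventions: the shank vector foot-to-knee and the thigh
#' vector knee-to-hip are `(0, 0, -l)` (up along the negative down-axis
#' at zero attitude), and the pelvis vector right-hip-to-left-hip is
#' `(0, -l_P, 0)`; the zero-angle pose is therefore a vertical stance.
#'
#' @name skeleton_fk
NULL

angles_row <- function(angles, segment) {
  r <- angles[angles$segment == segment, , drop = FALSE]
  if (nrow(r) != 1) {
    abort(sprintf("angles must contain exactly one row for segment '%s'",
                  segment), class = "gaitkin_invalid_argument")
  }
  c(r$roll, r$pitch, r$yaw)
}

#' Compute the skeleton pose from segment angles
#'
#' @param angles tibble (or data frame) with one row per segment:
#'   columns `segment, roll, pitch, yaw` (radians) for `pelvis,
#'   thigh_L, thigh_R, shank_L, shank_R`.
#' @param config a [body_config()] providing segment lengths.
#' @param stance_side `"left"` or `"right"`: which foot is pinned at the
#'   origin.
#' @return A `skeleton_pose`: tibble with columns `node`
#'   (`foot_L, knee_L, hip_L, hip_R, knee_R, foot_R`), `x, y, z` (m,
#'   local-level frame, z down) and attribute `stance_side`.
#' @examples
#' ang <- tibble::tibble(segment = c("pelvis", "thigh_L", "thigh_R",
#'                                   "shank_L", "shank_R"),
#'                       roll = 0, pitch = 0, yaw = 0)
#' forward_kinematics(ang, body_config(), "right")
#' @export
forward_kinematics <- function(angles, config, stance_side = c("right", "left")) {
  stance_side <- match.arg(stance_side)
  ln <- config$lengths
  eu <- lapply(setNames(SEGMENTS, SEGMENTS), function(s) angles_row(angles, s))
  C <- lapply(eu, function(a) dcm_from_euler(a[1], a[2], a[3]))
  up <- function(l) c(0, 0, -l)   # ascending the chain
  if (stance_side == "right") {
    pFR <- c(0, 0, 0)
    pKR <- pFR + as.numeric(C$shank_R %*% up(ln$shank_R))
    pHR <- pKR + as.numeric(C$thigh_R %*% up(ln$thigh_R))
    pHL <- pHR + as.numeric(C$pelvis %*% c(0, -ln$pelvis, 0))
    pKL <- pHL - as.numeric(C$thigh_L %*% up(ln$thigh_L))
    pFL <- pKL - as.numeric(C$shank_L %*% up(ln$shank_L))
  } else {
    pFL <- c(0, 0, 0)
    pKL <- pFL + as.numeric(C$shank_L %*% up(ln$shank_L))
    pHL <- pKL + as.numeric(C$thigh_L %*% up(ln$thigh_L))
    pHR <- pHL - as.numeric(C$pelvis %*% c(0, -ln$pelvis, 0))
    pKR <- pHR - as.numeric(C$thigh_R %*% up(ln$thigh_R))
    pFR <- pKR - as.numeric(C$shank_R %*% up(ln$shank_R))
  }
  pos <- rbind(pFL, pKL, pHL, pHR, pKR, pFR)
  dimnames(pos) <- NULL
  pose <- tibble(node = c("foot_L", "knee_L", "hip_L",
                          "hip_R", "knee_R", "foot_R"),
                 x = pos[, 1], y = pos[, 2], z = pos[, 3])
  attr(pose, "stance_side") <- stance_side
  class(pose) <- c("skeleton_pose", class(pose))
  pose
}

pose_node <- function(pose, node) {
  unlist(pose[pose$node == node, c("x", "y", "z")], use.names = FALSE)
}

#' Step length from the distance between the two heels
#'
#' Three-dimensional distance between the left and right heel positions
#' of a pose computed at a heel-strike instant.
#'
#' @param pose a `skeleton_pose` from [forward_kinematics()].
#' @param t_toe_off,t_heel_strike bounding event times recorded in the
#'   output (optional).
#' @return A one-row `step_record` tibble: `kind, side, value,
#'   t_toe_off, t_heel_strike`.
#' @export
step_length_feet <- function(pose, t_toe_off = NA_real_,
                             t_heel_strike = NA_real_) {
  d <- pose_node(pose, "foot_L") - pose_node(pose, "foot_R")
  tibble(kind = "step_length_feet", side = "n/a",
         value = sqrt(sum(d^2)),
         t_toe_off = t_toe_off, t_heel_strike = t_heel_strike)
}

#' Step length from the hip displacement over an interval
#'
#' Horizontal displacement magnitude of one hip node between the first
#' and last pose of an interval (the stance or swing phase bounded by
#' toe-off and heel-strike). The poses must share a common pinned
#' stance foot so their coordinates are comparable.
#'
#' @param poses list of `skeleton_pose` objects spanning the interval,
#'   time-ordered.
#' @param side `"left"` or `"right"`: which hip to track.
#' @param kind `"step_length_hip_stance"` or `"step_length_hip_swing"`,
#'   recording which phase's limb the hip belongs to.
#' @inheritParams step_length_feet
#' @return A one-row `step_record` tibble.
#' @export
step_length_hip <- function(poses, side = c("right", "left"),
                            kind = c("step_length_hip_stance",
                                     "step_length_hip_swing"),
                            t_toe_off = NA_real_, t_heel_strike = NA_real_) {
  side <- match.arg(side); kind <- match.arg(kind)
  if (!length(poses)) {
    abort("empty pose interval", class = "gaitkin_range_error")
  }
  node <- if (side == "left") "hip_L" else "hip_R"
  d <- pose_node(poses[[length(poses)]], node) - pose_node(poses[[1]], node)
  tibble(kind = kind, side = side, value = sqrt(sum(d[1:2]^2)),
         t_toe_off = t_toe_off, t_heel_strike = t_heel_strike)
}

#' Stride length from the swing-foot displacement
#'
#' Displacement of the swinging foot between its toe-off and the
#' following heel-strike. Both poses must be pinned on the same stance
#' side; if the stance anchor itself moved in the world frame over the
#' interval (it does not on a treadmill-fixed stance foot), supply its
#' displacement.
#'
#' @param pose_toe_off,pose_heel_strike `skeleton_pose` objects at the
#'   bounding events.
#' @param swing_side `"left"` or `"right"`.
#' @param anchor_displacement world displacement of the stance anchor
#'   across the interval (3-vector, m). Default zero.
#' @inheritParams step_length_feet
#' @return A one-row `step_record` tibble.
#' @export
stride_length <- function(pose_toe_off, pose_heel_strike,
                          swing_side = c("right", "left"),
                          anchor_displacement = c(0, 0, 0),
                          t_toe_off = NA_real_, t_heel_strike = NA_real_) {
  swing_side <- match.arg(swing_side)
  s1 <- attr(pose_toe_off, "stance_side")
  s2 <- attr(pose_heel_strike, "stance_side")
  if (!identical(s1, s2) || identical(s1, swing_side)) {
    abort("both poses must be pinned on the same, contralateral stance side",
          class = "gaitkin_invalid_argument")
  }
  node <- if (swing_side == "left") "foot_L" else "foot_R"
  d <- pose_node(pose_heel_strike, node) + anchor_displacement -
    pose_node(pose_toe_off, node)
  tibble(kind = "stride_length", side = swing_side, value = sqrt(sum(d^2)),
         t_toe_off = t_toe_off, t_heel_strike = t_heel_strike)
}

#' Sagittal step length from the leading thigh pitch alone
#'
#' Two-dimensional step-length model that replaces the trailing shank
#' pitch by twice the thigh pitch (their observed ratio around toe-off):
#' `(l_T + l_S) sin|th| + l_T sin|th| + l_S sin|2 th|`.
#'
#' @param theta_T leading thigh pitch angle, rad.
#' @param l_T,l_S thigh and shank lengths, m.
#' @return Step length, m.
#' @export
step_length_sagittal_thigh_only <- function(theta_T, l_T, l_S) {
  stopifnot(l_T > 0, l_S > 0)
  (l_T + l_S) * sin(abs(theta_T)) + l_T * sin(abs(theta_T)) +
    l_S * sin(abs(2 * theta_T))
}

#' Sagittal step-length error from neglecting the trailing shank
#'
#' The step-size error committed on the sagittal plane when the trailing
#' shank pitch is ignored: `l_S (sin|th_S| - sin|th_T|)`.
#'
#' @param theta_T,theta_S trailing thigh and shank pitch angles, rad.
#' @param l_S shank length, m.
#' @return Error, m.
#' @export
shank_neglect_error <- function(theta_T, theta_S, l_S) {
  stopifnot(l_S >= 0)
  l_S * (sin(abs(theta_S)) - sin(abs(theta_T)))
}

# angles tibble -> one pose row set at time t (nearest sample per segment)
angles_at <- function(angles, t) {
  out <- lapply(SEGMENTS, function(s) {
    a <- angles[angles$segment == s, ]
    if (!nrow(a)) abort(sprintf("no angles for segment '%s'", s),
                        class = "gaitkin_invalid_argument")
    i <- which.min(abs(a$t - t))
    a[i, c("segment", "roll", "pitch", "yaw")]
  })
  bind_rows(out)
}

#' Extract step and stride lengths from angles and gait events
#'
#' Combines an angle time series (from [run_orientation_filter()] or
#' ground truth) with detected per-foot toe-off/heel-strike pairs into a
#' table of step records. For every valid swing the function computes,
#' with the contralateral foot pinned: the 3-D heel-to-heel step length
#' at heel-strike, the stride length of the swinging foot, the stance-
#' and swing-side hip step lengths, and (for `method = "fk2d"`) the
#' thigh-only sagittal model. The first and last steps of the session
#' are flagged `excluded` and left out of summary statistics.
#'
#' @param angles tibble `t, segment, roll, pitch, yaw` (rad).
#' @param events a tibble of events (`foot, event, t`) as returned by
#'   [detect_gait_events()], or a `gait_events` object.
#' @param config a [body_config()].
#' @param method `"fk"` (full 3-D forward kinematics) or `"fk2d"`
#'   (leading-thigh-only sagittal model).
#' @param anchor_displacement stance-anchor world displacement per
#'   stride (3-vector); zero on a treadmill-fixed frame.
#' @param eval_offset settling offset, s: the heel-strike pose is
#'   evaluated this long after the detected heel-strike and the
#'   toe-off pose this long before the detected toe-off. During double
#'   support both heels are grounded, so the inter-heel distance is
#'   stationary there and the pose read-out is insensitive to the
#'   sample-level timing jitter of the event detector. Set to 0 to read
#'   the instantaneous event poses.
#' @return A `gait_steps` tibble: `kind, side, value, t_toe_off,
#'   t_heel_strike, excluded`.
#' @export
compute_step_lengths <- function(angles, events, config,
                                 method = c("fk", "fk2d"),
                                 anchor_displacement = c(0, 0, 0),
                                 eval_offset = 0.1) {
  method <- match.arg(method)
  if (inherits(events, "gait_events")) events <- events$events
  if (inherits(angles, "orientation_fit")) angles <- angles$angles
  swings <- pair_swings(events)
  rows <- list()
  for (i in seq_len(nrow(swings))) {
    sw <- swings[i, ]
    stance <- if (sw$foot == "left") "right" else "left"
    a_hs <- angles_at(angles, sw$t_heel_strike + eval_offset)
    if (method == "fk2d") {
      lead_thigh <- if (sw$foot == "left") "thigh_L" else "thigh_R"
      th <- a_hs$pitch[a_hs$segment == lead_thigh]
      lT <- if (sw$foot == "left") config$lengths$thigh_L else config$lengths$thigh_R
      lS <- if (sw$foot == "left") config$lengths$shank_L else config$lengths$shank_R
      rows[[length(rows) + 1]] <- tibble(
        kind = "step_length_feet", side = sw$foot,
        value = step_length_sagittal_thigh_only(th, lT, lS),
        t_toe_off = sw$t_toe_off, t_heel_strike = sw$t_heel_strike)
      next
    }
    a_to <- angles_at(angles, sw$t_toe_off - eval_offset)
    pose_hs <- forward_kinematics(a_hs, config, stance)
    pose_to <- forward_kinematics(a_to, config, stance)
    step <- step_length_feet(pose_hs, sw$t_toe_off, sw$t_heel_strike)
    step$side <- sw$foot
    stride <- stride_length(pose_to, pose_hs, swing_side = sw$foot,
                            anchor_displacement = anchor_displacement,
                            t_toe_off = sw$t_toe_off,
                            t_heel_strike = sw$t_heel_strike)
    hips <- bind_rows(
      step_length_hip(list(pose_to, pose_hs), side = stance,
                      kind = "step_length_hip_stance",
                      t_toe_off = sw$t_toe_off,
                      t_heel_strike = sw$t_heel_strike),
      step_length_hip(list(pose_to, pose_hs), side = sw$foot,
                      kind = "step_length_hip_swing",
                      t_toe_off = sw$t_toe_off,
                      t_heel_strike = sw$t_heel_strike))
    rows[[length(rows) + 1]] <- bind_rows(step, stride, hips)
  }
  if (!length(rows)) {
    return(tibble(kind = character(), side = character(), value = numeric(),
                  t_toe_off = numeric(), t_heel_strike = numeric(),
                  excluded = logical()))
  }
  out <- bind_rows(rows)
  flag_boundary_steps(out)
}

# first and last swing of the session are excluded from summaries
flag_boundary_steps <- function(steps) {
  sw_times <- sort(unique(steps$t_heel_strike))
  mutate(steps, excluded = .data$t_heel_strike %in%
           c(sw_times[1], sw_times[length(sw_times)]))
}

# toe-off / heel-strike pairing per foot, in time order
pair_swings <- function(events) {
  out <- list()
  for (ft in unique(events$foot)) {
    ev <- events[events$foot == ft & events$event %in%
                   c("toe_off", "heel_strike"), ]
    ev <- arrange(ev, .data$t)
    to_t <- NA_real_
    for (j in seq_len(nrow(ev))) {
      if (ev$event[j] == "toe_off") {
        to_t <- ev$t[j]
      } else if (!is.na(to_t)) {
        out[[length(out) + 1]] <- tibble(foot = ft, t_toe_off = to_t,
                                         t_heel_strike = ev$t[j])
        to_t <- NA_real_
      }
    }
  }
  if (!length(out)) {
    return(tibble(foot = character(), t_toe_off = numeric(),
                  t_heel_strike = numeric()))
  }
  arrange(bind_rows(out), .data$t_toe_off)
}
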