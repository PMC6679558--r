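cfg_sym <- body_config(pelvis = 0.3, thigh_L = 0.45, thigh_R = 0.45,
                       shank_L = 0.45, shank_R = 0.45)

test_that("the zero-angle pose is a vertical stance", {
  cfg <- body_config(pelvis = 0.3, thigh_L = 0.5, thigh_R = 0.5,
                     shank_L = 0.5, shank_R = 0.5)
  pose <- forward_kinematics(flat_angles(), cfg, "right")
  hips <- pose[pose$node %in% c("hip_L", "hip_R"), ]
  expect_equal(hips$z, c(-1, -1))
  feet <- pose[pose$node %in% c("foot_L", "foot_R"), ]
  expect_equal(feet$z, c(0, 0))
  expect_equal(feet$x, c(0, 0))
  expect_equal(step_length_feet(pose)$value, 0.3)
})

test_that("the symmetric sagittal pose matches its closed form", {
  th <- 20 * pi / 180
  ang <- flat_angles(c(pelvis = 0, thigh_L = th, thigh_R = -th,
                       shank_L = th, shank_R = -th))
  pose <- forward_kinematics(ang, cfg_sym, "right")
  sep <- pose$x[pose$node == "foot_L"] - pose$x[pose$node == "foot_R"]
  expect_equal(sep, 2 * 0.9 * sin(th), tolerance = 1e-12)
  expect_equal(step_length_feet(pose)$value,
               sqrt((2 * 0.9 * sin(th))^2 + 0.3^2), tolerance = 1e-12)
  # degenerate pelvis: the step is the forward separation exactly
  cfg0 <- body_config(pelvis = 1e-12, thigh_L = 0.45, thigh_R = 0.45,
                      shank_L = 0.45, shank_R = 0.45)
  pose0 <- forward_kinematics(ang, cfg0, "right")
  expect_equal(step_length_feet(pose0)$value, 2 * 0.9 * sin(th),
               tolerance = 1e-9)
})

test_that("chain distances equal the configured segment lengths", {
  set.seed(33)
  cfg <- body_config(pelvis = 0.28, thigh_L = 0.44, thigh_R = 0.46,
                     shank_L = 0.41, shank_R = 0.43)
  dist <- function(pose, a, b) {
    pa <- unlist(pose[pose$node == a, c("x", "y", "z")])
    pb <- unlist(pose[pose$node == b, c("x", "y", "z")])
    sqrt(sum((pa - pb)^2))
  }
  worst <- 0
  for (i in 1:100) {
    ang <- tibble::tibble(
      segment = c("pelvis", "thigh_L", "thigh_R", "shank_L", "shank_R"),
      roll = runif(5, -0.5, 0.5), pitch = runif(5, -1.2, 1.2),
      yaw = runif(5, -pi, pi))
    for (side in c("left", "right")) {
      pose <- forward_kinematics(ang, cfg, side)
      worst <- max(worst,
                   abs(dist(pose, "foot_L", "knee_L") - 0.41),
                   abs(dist(pose, "knee_L", "hip_L") - 0.44),
                   abs(dist(pose, "hip_L", "hip_R") - 0.28),
                   abs(dist(pose, "hip_R", "knee_R") - 0.46),
                   abs(dist(pose, "knee_R", "foot_R") - 0.43))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("mirrored angle sets mirror the pose across the sagittal plane", {
  ang <- tibble::tibble(
    segment = c("pelvis", "thigh_L", "thigh_R", "shank_L", "shank_R"),
    roll = 0, pitch = c(0.05, 0.4, -0.3, 0.5, -0.6), yaw = 0)
  mirrored <- tibble::tibble(
    segment = c("pelvis", "thigh_L", "thigh_R", "shank_L", "shank_R"),
    roll = 0, pitch = c(0.05, -0.3, 0.4, -0.6, 0.5), yaw = 0)
  p1 <- forward_kinematics(ang, cfg_sym, "right")
  p2 <- forward_kinematics(mirrored, cfg_sym, "left")
  swap <- c(foot_L = "foot_R", knee_L = "knee_R", hip_L = "hip_R",
            hip_R = "hip_L", knee_R = "knee_L", foot_R = "foot_L")
  for (nd in names(swap)) {
    a <- unlist(p1[p1$node == nd, c("x", "y", "z")])
    b <- unlist(p2[p2$node == swap[[nd]], c("x", "y", "z")])
    expect_equal(unname(a), unname(b * c(1, -1, 1)), tolerance = 1e-12)
  }
})

test_that("heel-to-heel step length is invariant under a common yaw", {
  ang <- tibble::tibble(
    segment = c("pelvis", "thigh_L", "thigh_R", "shank_L", "shank_R"),
    roll = c(0.02, 0, 0, 0, 0), pitch = c(0.05, 0.4, -0.3, 0.5, -0.6),
    yaw = 0)
  base <- step_length_feet(forward_kinematics(ang, cfg_sym, "right"))$value
  for (psi in c(-2.5, 0.7, 3.0)) {
    ang2 <- dplyr::mutate(ang, yaw = yaw + psi)
    v <- step_length_feet(forward_kinematics(ang2, cfg_sym, "right"))$value
    expect_equal(v, base, tolerance = 1e-12)
  }
})

test_that("hip and stride records behave on static and yawed poses", {
  pose <- forward_kinematics(flat_angles(), cfg_sym, "right")
  expect_equal(step_length_hip(list(pose, pose), "right")$value, 0)
  expect_equal(stride_length(pose, pose, "left")$value, 0)
  expect_error(step_length_hip(list(), "right"), class = "gaitkin_range_error")
  # mismatched stance sides are rejected
  pose_l <- forward_kinematics(flat_angles(), cfg_sym, "left")
  expect_error(stride_length(pose, pose_l, "left"),
               class = "gaitkin_invalid_argument")
  expect_error(stride_length(pose, pose, "right"),
               class = "gaitkin_invalid_argument")

  # pelvis yaw at the events separates stance- from swing-hip steps
  th <- 0.35
  a_to <- flat_angles(c(pelvis = 0, thigh_L = -th, thigh_R = th,
                        shank_L = -th, shank_R = th))
  a_hs <- flat_angles(c(pelvis = 0, thigh_L = th, thigh_R = -th,
                        shank_L = th, shank_R = -th))
  a_to$yaw[a_to$segment == "pelvis"] <- 0.1
  a_hs$yaw[a_hs$segment == "pelvis"] <- -0.1
  p_to <- forward_kinematics(a_to, cfg_sym, "right")
  p_hs <- forward_kinematics(a_hs, cfg_sym, "right")
  h_st <- step_length_hip(list(p_to, p_hs), "right",
                          "step_length_hip_stance")$value
  h_sw <- step_length_hip(list(p_to, p_hs), "left",
                          "step_length_hip_swing")$value
  expect_gt(abs(h_st - h_sw), 1e-6)
})

test_that("mirror poses double the forward separation into the stride", {
  th <- 0.3
  a_to <- flat_angles(c(pelvis = 0, thigh_L = -th, thigh_R = th,
                        shank_L = -th, shank_R = th))
  a_hs <- flat_angles(c(pelvis = 0, thigh_L = th, thigh_R = -th,
                        shank_L = th, shank_R = -th))
  p_to <- forward_kinematics(a_to, cfg_sym, "right")
  p_hs <- forward_kinematics(a_hs, cfg_sym, "right")
  s <- stride_length(p_to, p_hs, "left")$value
  expect_equal(s, 2 * 2 * 0.9 * sin(th), tolerance = 1e-12)
})

test_that("the thigh-only sagittal model and shank-neglect error evaluate", {
  expect_equal(step_length_sagittal_thigh_only(0, 0.5, 0.5), 0)
  expect_equal(step_length_sagittal_thigh_only(30 * pi / 180, 0.5, 0.5),
               0.5 + 0.25 + 0.5 * sin(60 * pi / 180), tolerance = 1e-12)
  expect_equal(step_length_sagittal_thigh_only(pi / 2, 0.4, 0.5),
               0.9 + 0.4, tolerance = 1e-12)
  expect_equal(shank_neglect_error(0.3, 0.3, 0.45), 0)
  expect_equal(shank_neglect_error(20 * pi / 180, 40 * pi / 180, 0.45),
               0.45 * (sin(40 * pi / 180) - sin(20 * pi / 180)),
               tolerance = 1e-12)
  expect_equal(shank_neglect_error(0.2, 0.8, 0), 0)
})

test_that("step extraction flags first and last steps of a session", {
  sim <- walk_short()
  ev <- detect_gait_events(sim$log)
  steps <- compute_step_lengths(sim$truth$angles, ev, body_config())
  hs <- sort(unique(steps$t_heel_strike))
  expect_true(all(steps$excluded[steps$t_heel_strike == hs[1]]))
  expect_true(all(steps$excluded[steps$t_heel_strike == hs[length(hs)]]))
  expect_false(any(steps$excluded[!steps$t_heel_strike %in%
                                    c(hs[1], hs[length(hs)])]))
  expect_true(all(steps$t_toe_off < steps$t_heel_strike))
})
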