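g <- 9.80665

test_that("prediction integrates rates, inflates covariance, decays biases", {
  nz <- filter_noise()
  st <- limb_state(t = 0)
  st2 <- predict_orientation(st, 0.1, nz)
  expect_equal(st2$x, st$x)                      # zero rates: angles fixed
  expect_gt(sum(diag(st2$P)), sum(diag(st$P)))   # free propagation inflates

  # a pitch rate of 0.5 rad/s for 0.1 s advances pitch by 0.05 rad
  # (thigh_R is segment 3 in the state ordering)
  st3 <- limb_state(t = 0)
  st3$x[15 + (3 - 1) * 3 + 2] <- 0.5             # thigh_R pitch rate
  st4 <- predict_orientation(st3, 0.1, nz)
  expect_equal(st4$x[(3 - 1) * 3 + 2], 0.05, tolerance = 1e-12)

  # Gauss-Markov bias block: mean decays by (1 - dt/tau)
  tau <- 1 / nz$beta[1]
  st5 <- limb_state(t = 0)
  st5$x[31] <- 0.2
  st6 <- predict_orientation(st5, 0.5, nz)
  expect_equal(st6$x[31], 0.2 * (1 - 0.5 / tau), tolerance = 1e-12)

  expect_error(predict_orientation(st, 0, nz),
               class = "gaitkin_invalid_argument")
})

test_that("tilt updates shrink variance, converge, and respect the gate", {
  nz <- filter_noise()
  st <- limb_state(t = 0)
  st1 <- update_tilt(st, "pelvis", c(0, 0, -g), nz)
  expect_equal(st1$x, st$x, tolerance = 1e-12)   # zero innovation
  expect_lt(st1$P[1, 1], st$P[1, 1])
  expect_lt(st1$P[2, 2], st$P[2, 2])

  # high-gain limit: diffuse prior pulled to the measured pi/4 pitch
  P_big <- diag(c(rep(1e4, 15), rep(0.25, 15), rep(0.0025, 15)))
  st2 <- limb_state(P = P_big, t = 0)
  st3 <- update_tilt(st2, "pelvis", c(g / sqrt(2), 0, -g / sqrt(2)), nz)
  expect_equal(st3$x[2], pi / 4, tolerance = 1e-4)

  # gate: strongly accelerated samples leave the state untouched
  st4 <- update_tilt(st1, "pelvis", c(3, 0, -g), nz)
  expect_identical(st4$x, st1$x)
  expect_warning(update_tilt(st1, "pelvis", c(0, 0, 0), nz), "skipped")
})

test_that("static tilt filtering is statistically consistent", {
  nz <- filter_noise()
  set.seed(7)
  theta_true <- 0.2
  C <- dcm_from_euler(0, theta_true, 0)
  st <- limb_state(t = 0)
  for (k in 1:80) {
    st <- predict_orientation(st, 1 / 26, nz)
    f <- as.numeric(t(C) %*% c(0, 0, -g)) + rnorm(3, sd = 0.014)
    st <- update_tilt(st, "thigh_L", f, nz)
  }
  i_pitch <- (2 - 1) * 3 + 2
  sigma <- sqrt(st$P[i_pitch, i_pitch])
  expect_lt(abs(st$x[i_pitch] - theta_true), 3 * sigma + 0.005)
})

test_that("heading updates constrain yaw and only yaw is unobservable", {
  nz <- filter_noise()
  st <- limb_state(t = 0)
  m0 <- c(22, 0, 41)
  st1 <- update_heading(st, "pelvis", m0, nz)
  expect_equal(st1$x[3], 0, tolerance = 1e-12)
  expect_lt(st1$P[3, 3], st$P[3, 3])

  # drifted yaw is pulled back toward the field-implied zero
  st2 <- limb_state(t = 0); st2$x[3] <- 0.2
  st3 <- update_heading(st2, "pelvis", m0, nz)
  expect_lt(st3$x[3], 0.2)
  expect_gt(st3$x[3], 0)

  # degenerate field: no change
  st4 <- update_heading(st, "pelvis", c(0, 0, 50), nz)
  expect_identical(st4$x, st$x)

  # without heading updates yaw variance never decreases
  st5 <- limb_state(t = 0)
  v <- numeric(20)
  for (k in 1:20) {
    st5 <- predict_orientation(st5, 1 / 26, nz)
    st5 <- update_gyro(st5, "thigh_L", c(0, 0.3, 0), nz)
    st5 <- update_tilt(st5, "thigh_L", c(0, 0, -g), nz)
    v[k] <- st5$P[(2 - 1) * 3 + 3, (2 - 1) * 3 + 3]
  }
  expect_true(all(diff(v) > -1e-12))
})

test_that("gyro updates observe the rate-plus-bias sum", {
  nz <- filter_noise()
  st <- limb_state(t = 0)
  st$x[15 + 2] <- 0.3; st$x[30 + 2] <- 0.1
  st1 <- update_gyro(st, "pelvis", c(0.1, 0.4, 0), nz)
  expect_equal(st1$x[15 + 2], 0.3, tolerance = 1e-9)  # zero innovation on y
  expect_equal(st1$x[30 + 2], 0.1, tolerance = 1e-9)

  # persistent constant measurement: rate + bias converges to it
  st2 <- limb_state(t = 0)
  for (k in 1:50) {
    st2 <- predict_orientation(st2, 1 / 26, nz)
    st2 <- update_gyro(st2, "shank_R", c(0, 0.7, 0), nz)
  }
  i <- which(SEGMENTS_IDX$segment == "shank_R")
  expect_equal(st2$x[15 + (i - 1) * 3 + 2] + st2$x[30 + (i - 1) * 3 + 2],
               0.7, tolerance = 1e-3)
})

test_that("covariance stays symmetric positive semi-definite through a run", {
  nz <- filter_noise()
  set.seed(11)
  st <- limb_state(t = 0)
  worst <- 0
  for (k in 1:60) {
    st <- predict_orientation(st, 1 / 26, nz)
    st <- update_gyro(st, "pelvis", rnorm(3, sd = 0.5), nz)
    st <- update_tilt(st, "pelvis", c(0.1, -0.2, -g), nz)
    st <- update_heading(st, "pelvis", c(22, 3, 41), nz)
    expect_equal(st$P, t(st$P))
    worst <- min(worst, min(eigen(st$P, symmetric = TRUE,
                                  only.values = TRUE)$values))
  }
  expect_gt(worst, -1e-9)
})

test_that("all-static traces converge to the accelerometer tilt", {
  sim <- simulate_walk(gait_sim_config(n_cycles = 1, lead_in = 4,
                                       lead_out = 0.2, noise_on = FALSE))
  log <- dplyr::filter(sim$log, t < 3.8)
  fit <- run_orientation_filter(log, body_config())
  last <- dplyr::slice_tail(dplyr::group_by(fit$angles, segment), n = 1)
  truth <- dplyr::distinct(
    dplyr::filter(sim$truth$angles, t < 0.1, segment %in% SEGMENTS),
    segment, .keep_all = TRUE)
  cmp <- dplyr::inner_join(last, truth, by = "segment",
                           suffix = c("", "_true"))
  expect_lt(max(abs(cmp$pitch - cmp$pitch_true)), 1e-3)
  expect_lt(max(abs(cmp$roll - cmp$roll_true)), 1e-3)
})

test_that("halving the sample interval does not degrade pitch accuracy", {
  sim26 <- simulate_walk(gait_sim_config(n_cycles = 4, noise_on = FALSE,
                                         sample_rate = 26))
  sim52 <- simulate_walk(gait_sim_config(n_cycles = 4, noise_on = FALSE,
                                         sample_rate = 52))
  e26 <- pitch_errors(run_orientation_filter(sim26$log, body_config()), sim26)
  e52 <- pitch_errors(run_orientation_filter(sim52$log, body_config()), sim52)
  expect_lte(max(e52$rmse_deg), max(e26$rmse_deg) * 1.2)
})

test_that("pelvis magnetometer updates bound the yaw uncertainty", {
  sim <- walk_noisy()
  fit <- fit_noisy()
  log_nomag <- sim$log
  log_nomag$mx <- NA_real_; log_nomag$my <- NA_real_; log_nomag$mz <- NA_real_
  fit_nomag <- run_orientation_filter(log_nomag, body_config())
  # with the magnetometer the pelvis yaw error stays small
  a <- dplyr::filter(fit$angles, segment == "pelvis")
  tr <- dplyr::filter(sim$truth$angles, segment == "pelvis")
  j <- dplyr::inner_join(a, tr, by = c("t", "segment"),
                         suffix = c("", "_true"))
  n <- nrow(j)
  expect_lt(mean(abs(wrap_angle(j$yaw - j$yaw_true))[(n - 200):n]),
            5 * pi / 180)
  # yaw is unobservable without it: the filter's final yaw variance
  # keeps growing where the heading-aided filter's has converged
  expect_gt(fit_nomag$state$P[3, 3], 10 * fit$state$P[3, 3])
})

test_that("gyro bias states track the planted turn-on biases", {
  sim <- walk_noisy()
  fit <- fit_noisy()
  for (s in c("thigh_R", "shank_L")) {
    i <- which(SEGMENTS_IDX$segment == s)
    b_est <- fit$state$x[30 + (i - 1) * 3 + 1:3]
    b_true <- sim$truth$gyro_bias[[s]]
    # planted turn-on biases reach +-0.35 rad/s; the filter should hold
    # them to a couple of degrees per second throughout the walk
    expect_lt(max(abs(b_est - b_true)), 0.04)
  }
})
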