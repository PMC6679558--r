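test_that("simulation is deterministic and noise is seed-separable", {
  cfg <- gait_sim_config(n_cycles = 2, seed = 31)
  s1 <- simulate_walk(cfg)
  s2 <- simulate_walk(cfg)
  expect_identical(s1$log, s2$log)
  s3 <- simulate_walk(gait_sim_config(n_cycles = 2, seed = 32))
  expect_false(identical(s1$log$wx, s3$log$wx))
  expect_identical(s1$truth$steps, s3$truth$steps)
  expect_identical(s1$truth$angles, s3$truth$angles)
})

test_that("the stance foot is pinned during every foot-flat interval", {
  sim <- walk_short()
  tr <- sim$truth$trajectories
  for (ft in c("left", "right")) {
    nd <- if (ft == "left") "foot_L" else "foot_R"
    fr <- tr[tr$node == nd, ]
    ff <- sim$truth$foot_flat[sim$truth$foot_flat$foot == ft, ]
    for (i in seq_len(nrow(ff))) {
      sel <- fr$t >= ff$t_start[i] & fr$t <= ff$t_end[i]
      p <- as.matrix(fr[sel, c("x", "y", "z")])
      expect_lt(max(abs(sweep(p, 2, p[1, ]))), 1e-9)
    }
  }
})

test_that("noise-free foot specific force has gravity magnitude at foot-flat", {
  sim <- walk_short()
  g <- sim$config$body$g
  for (site in c("foot_L", "foot_R")) {
    ft <- if (site == "foot_L") "left" else "right"
    tr <- dplyr::filter(sim$log, site == !!site)
    ff <- sim$truth$foot_flat[sim$truth$foot_flat$foot == ft, ]
    # away from the interval edges, where the heel pivot begins
    sel <- rep(FALSE, nrow(tr))
    for (i in seq_len(nrow(ff))) {
      sel <- sel | (tr$t >= ff$t_start[i] + 0.05 & tr$t <= ff$t_end[i] - 0.05)
    }
    fmag <- sqrt(tr$fx[sel]^2 + tr$fy[sel]^2 + tr$fz[sel]^2)
    expect_lt(max(abs(fmag - g)), 1e-6)
    wmag <- sqrt(tr$wx[sel]^2 + tr$wy[sel]^2 + tr$wz[sel]^2)
    expect_lt(max(wmag), 1e-6)
  }
})

test_that("per-foot swing counts equal the configured cycle count", {
  sim <- walk_short()
  ev <- sim$truth$events
  for (ft in c("left", "right")) {
    expect_equal(sum(ev$foot == ft & ev$event == "toe_off"),
                 sim$config$n_cycles)
    to <- ev$t[ev$foot == ft & ev$event == "toe_off"]
    hs <- ev$t[ev$foot == ft & ev$event == "heel_strike"]
    expect_true(all(to < hs))
  }
})

test_that("feeding true angles through the FK chain reproduces true steps", {
  sim <- walk_short()
  steps <- compute_step_lengths(sim$truth$angles, sim$truth$events,
                                sim$config$body)
  m <- merge(steps, sim$truth$steps,
             by = c("kind", "side", "t_toe_off"), suffixes = c("", "_ref"))
  expect_gt(nrow(m), 0)
  expect_lt(max(abs(m$value - m$value_ref)), 1e-3)
})

test_that("re-differentiating the foot path reproduces the specific force", {
  sim <- walk_short()
  g_n <- c(0, 0, sim$config$body$g)
  tr <- dplyr::filter(sim$log, site == "foot_R")
  fr <- sim$truth$trajectories
  fr <- fr[fr$node == "foot_R", ]
  ang <- sim$truth$angles[sim$truth$angles$segment == "foot_R", ]
  dt <- 1 / 26
  n <- nrow(fr)
  p <- as.matrix(fr[c("x", "y", "z")])
  a_num <- (p[3:n, ] - 2 * p[2:(n - 1), ] + p[1:(n - 2), ]) / dt^2
  # rotate emitted specific force to the nav frame and add gravity
  mid <- 2:(n - 1)
  a_emit <- t(vapply(mid, function(k) {
    C <- dcm_from_euler(ang$roll[k], ang$pitch[k], ang$yaw[k])
    as.numeric(C %*% c(tr$fx[k], tr$fy[k], tr$fz[k])) + g_n
  }, numeric(3)))
  # second differences at the logger rate carry O(dt^2) curvature error;
  # compare against that scale
  expect_lt(stats::median(abs(a_num - a_emit)), 0.05)
  expect_lt(max(abs(a_num - a_emit)) / max(abs(a_num)), 0.15)
})

test_that("config validation rejects impossible gaits", {
  expect_error(gait_sim_config(shank_amp = -30),
               class = "gaitkin_config_error")
  expect_error(gait_sim_config(cadence = 0))
})

test_that("the synthetic swing fixture has exactly three magnitude peaks", {
  t <- seq(0, 3, by = 1 / 260)
  y <- make_fig5_gyro(t, 1.0, 1.5, peak_amplitudes = c(3, 4.5, 3))
  pk <- find_peaks(abs(y), t, prominence = 0.5)
  expect_equal(length(pk), 3)
  expect_equal(t[pk], c(1.0, 1.25, 1.5), tolerance = 0.01)
  expect_true(all(make_fig5_gyro(t, 1, 1.5,
                                 peak_amplitudes = c(0, 0, 0)) == 0))
})

test_that("planted gyro biases fall inside the configured turn-on range", {
  sim <- walk_short_noisy()
  rng <- sim$config$gyro_bias_range
  for (b in sim$truth$gyro_bias) expect_true(all(abs(b) <= rng))
})
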