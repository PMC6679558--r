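g <- 9.80665

test_that("GLRT statistic matches its closed forms", {
  N <- 7
  f_rest <- matrix(rep(c(0, 0, -g), each = N), N)
  w_zero <- matrix(0, N, 3)
  expect_equal(glrt_statistic(f_rest, w_zero, 0.01, 0.001), 0)
  # constant f with |f| = g, constant rotation w about x: S = w^2/sigma_w^2
  w <- 0.4
  w_const <- cbind(rep(w, N), 0, 0)
  expect_equal(glrt_statistic(f_rest, w_const, 0.01, 0.002),
               w^2 / 0.002^2, tolerance = 1e-12)
  expect_error(glrt_statistic(matrix(0, N, 3), w_zero, 0.01, 0.001),
               class = "gaitkin_degenerate_window")
  expect_error(glrt_statistic(f_rest[1, , drop = FALSE],
                              w_zero[1, , drop = FALSE], 0.01, 0.001),
               class = "gaitkin_invalid_argument")
})

test_that("quasi-static detection flags rest and isolates swings", {
  p <- detector_params()
  tr <- static_trace(60)
  expect_true(all(detect_quasi_static(tr, p)))

  # rest - swing - rest with gyro far above the noise floor
  tr2 <- static_trace(120)
  swing <- 41:70
  tr2$wy[swing] <- 2
  mask <- detect_quasi_static(tr2, p)
  r <- rle(mask)
  expect_equal(r$values, c(TRUE, FALSE, TRUE))
  moving <- which(!mask)
  expect_lte(abs(min(moving) - min(swing)), p$N)
  expect_lte(abs(max(moving) - max(swing)), p$N)

  # single-sample spikes shorter than min_swing are merged away
  tr3 <- static_trace(120)
  tr3$wy[c(30, 60, 90)] <- 5
  expect_true(all(detect_quasi_static(tr3, p)))

  expect_error(detect_quasi_static(static_trace(3), p),
               class = "gaitkin_insufficient_data")
})

test_that("gait cycles pair each static run with the following moving run", {
  times <- (0:119) / 26
  mask <- rep(TRUE, 120)
  mask[31:60] <- FALSE; mask[91:110] <- FALSE
  cyc <- segment_gait_cycles(mask, times)
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$i_stance_start, c(1L, 61L))
  expect_equal(cyc$i_swing_end, c(60L, 110L))

  expect_equal(nrow(segment_gait_cycles(rep(TRUE, 50), times[1:50])), 0)

  mask2 <- c(rep(FALSE, 20), rep(TRUE, 50), rep(FALSE, 30), rep(TRUE, 20))
  expect_warning(cyc2 <- segment_gait_cycles(mask2, times),
                 "leading moving run")
  expect_equal(nrow(cyc2), 1)
})

test_that("peak finding respects prominence and separation", {
  t <- seq(0, 2, by = 1 / 26)
  x <- make_fig5_gyro(t, 0.5, 1.5, peak_amplitudes = c(3, 4, 3))
  pk <- find_peaks(abs(x), t, prominence = 0.5, min_sep = 0.1)
  expect_equal(length(pk), 3)
  expect_equal(t[pk], c(0.5, 1.0, 1.5), tolerance = 1 / 26)
  # low outer bumps fall under the prominence threshold
  x2 <- make_fig5_gyro(t, 0.5, 1.5, peak_amplitudes = c(0.2, 4, 0.2))
  expect_equal(length(find_peaks(abs(x2), t, prominence = 0.5,
                                 min_sep = 0.1)), 1)
  expect_equal(find_peaks(numeric(10), seq_len(10)), integer())
})

test_that("the three-peak swing fixture yields toe-off and heel-strike", {
  dt <- 1 / 26
  t <- seq(0, 4, by = dt)
  tr <- static_trace(length(t))
  tr$t <- t
  tr$wy <- make_fig5_gyro(t, 1.0, 1.6, peak_amplitudes = c(3, 4, 3),
                          width = 0.3)
  ev <- detect_foot_events(tr, detector_params(), calibrate_bias = FALSE,
                           foot = "right")
  expect_equal(sum(ev$valid), 1)
  expect_equal(ev$events$t[ev$events$event == "toe_off"], 1.0,
               tolerance = dt)
  expect_equal(ev$events$t[ev$events$event == "heel_strike"], 1.6,
               tolerance = dt)
  expect_true(all(ev$events$t[ev$events$event == "toe_off"] <
                    ev$events$t[ev$events$event == "heel_strike"]))

  # a swing with a single detectable bump is skipped (no events)
  tr$wy <- make_fig5_gyro(t, 1.0, 1.6, peak_amplitudes = c(0.2, 3, 0.2),
                          width = 0.3)
  ev2 <- detect_foot_events(tr, detector_params(), calibrate_bias = FALSE)
  expect_equal(sum(ev2$valid), 0)
  expect_equal(nrow(ev2$events), 0)

  # an all-static trace has no cycles and no events
  ev3 <- detect_foot_events(static_trace(120), detector_params(),
                            calibrate_bias = FALSE)
  expect_equal(nrow(ev3$cycles), 0)
  expect_equal(nrow(ev3$events), 0)
})

test_that("valid step count never exceeds the cycle count", {
  sim <- walk_short_noisy()
  for (site in c("foot_L", "foot_R")) {
    tr <- dplyr::filter(sim$log, site == !!site)
    ev <- detect_foot_events(tr, foot = "left")
    expect_lte(sum(ev$valid), nrow(ev$cycles))
  }
})

test_that("standstill gyro-bias estimation recovers the planted bias", {
  sim <- walk_short_noisy()
  tr <- dplyr::filter(sim$log, site == "foot_R")
  b_est <- estimate_gyro_bias(tr, window = 1)
  expect_equal(unname(b_est), unname(sim$truth$gyro_bias$foot_R),
               tolerance = 0.01)
})

test_that("the zero-phase low-pass filter does not delay a peak", {
  t <- seq(0, 2, by = 1 / 26)
  x <- exp(-((t - 1) / 0.15)^2)
  y <- lowpass1(x, 1 / 26, cutoff = 5)
  expect_equal(t[which.max(y)], t[which.max(x)], tolerance = 1 / 26)
})
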