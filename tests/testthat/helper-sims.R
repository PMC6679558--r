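# cached simulations shared across test files (building a one-minute
# walk and filtering it is the expensive part of the suite)
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) assign(key, force(expr), .sim_cache)
  get(key, .sim_cache)
}

# ~62 s treadmill walk: 49 cycles/foot at 0.82 Hz
walk_clean <- function() {
  cached("walk_clean",
         simulate_walk(gait_sim_config(n_cycles = 49, noise_on = FALSE)))
}

walk_noisy <- function() {
  cached("walk_noisy",
         simulate_walk(gait_sim_config(n_cycles = 49, noise_on = TRUE,
                                       seed = 42)))
}

fit_clean <- function() {
  cached("fit_clean", run_orientation_filter(walk_clean()$log, body_config()))
}

fit_noisy <- function() {
  cached("fit_noisy", run_orientation_filter(walk_noisy()$log, body_config()))
}

events_clean <- function() {
  cached("events_clean", detect_gait_events(walk_clean()$log))
}

events_noisy <- function() {
  cached("events_noisy", detect_gait_events(walk_noisy()$log))
}

# short walks for cheaper unit tests
walk_short <- function() {
  cached("walk_short",
         simulate_walk(gait_sim_config(n_cycles = 5, noise_on = FALSE)))
}

walk_short_noisy <- function() {
  cached("walk_short_noisy",
         simulate_walk(gait_sim_config(n_cycles = 5, noise_on = TRUE,
                                       seed = 9)))
}

# per-segment pitch error table of a fit against simulator truth
pitch_errors <- function(fit, sim) {
  angles <- if (inherits(fit, "orientation_fit")) fit$angles else fit
  err <- dplyr::inner_join(angles, sim$truth$angles,
                           by = c("t", "segment"), suffix = c("", "_true"))
  dplyr::summarise(
    dplyr::group_by(err, .data$segment),
    rmse_deg = sqrt(mean((.data$pitch - .data$pitch_true)^2)) * 180 / pi,
    mae_deg = mean(abs(.data$pitch - .data$pitch_true)) * 180 / pi,
    .groups = "drop")
}

# stationary synthetic trace fixture: level foot at rest
static_trace <- function(n = 100, dt = 1 / 26, g = 9.80665) {
  tibble::tibble(t = (seq_len(n) - 1) * dt, fx = 0, fy = 0, fz = -g,
                 wx = 0, wy = 0, wz = 0)
}

# angle set for the five filter segments
flat_angles <- function(pitches = c(pelvis = 0, thigh_L = 0, thigh_R = 0,
                                    shank_L = 0, shank_R = 0)) {
  tibble::tibble(segment = names(pitches), roll = 0,
                 pitch = unname(pitches), yaw = 0)
}

expect_no_warning <- function(expr) expect_warning(expr, regexp = NA)

# state ordering of the orientation filter segments
SEGMENTS_IDX <- tibble::tibble(
  segment = c("pelvis", "thigh_L", "thigh_R", "shank_L", "shank_R"))
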