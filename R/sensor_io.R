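#' Read a multi-sensor IMU log
#'
#' Reads a CSV log with one row per (time, sensor) sample and columns
#' `t, sensor_id, fx, fy, fz, wx, wy, wz` and optionally `mx, my, mz`.
#' Values are normalised to SI units (seconds, m/s^2, rad/s, uT) and the
#' result is returned as one tidy tibble with a `site` column, sorted by
#' site and time.
#'
#' @param path path to the CSV file.
#' @param site_map named character vector translating `sensor_id` values
#'   to body sites (`pelvis`, `thigh_L`, `thigh_R`, `shank_L`, `shank_R`,
#'   `foot_L`, `foot_R`). Defaults to the identity mapping, i.e.
#'   `sensor_id` already holds site names.
#' @param gyro_units `"rad/s"` (default) or `"deg/s"`; the latter is
#'   converted on read.
#' @param accel_units `"m/s2"` (default) or `"g"`.
#' @return A tibble with columns `t, site, fx, fy, fz, wx, wy, wz` and,
#'   when present in the file, `mx, my, mz`. Carries attribute
#'   `units = "SI"` so a second conversion is refused.
#' @export
read_imu_log <- function(path, site_map = NULL,
                         gyro_units = c("rad/s", "deg/s"),
                         accel_units = c("m/s2", "g")) {
  gyro_units <- match.arg(gyro_units)
  accel_units <- match.arg(accel_units)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("t", "sensor_id", "fx", "fy", "fz", "wx", "wy", "wz")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(paste0("IMU log is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "gaitkin_format_error")
  }
  has_mag <- all(c("mx", "my", "mz") %in% names(raw))
  log <- as_tibble(raw)
  if (!is.null(site_map)) {
    unknown <- setdiff(unique(log$sensor_id), names(site_map))
    if (length(unknown)) {
      abort(paste0("sensor_id(s) not in site_map: ",
                   paste(unknown, collapse = ", ")),
            class = "gaitkin_format_error")
    }
    log$site <- unname(site_map[as.character(log$sensor_id)])
  } else {
    log$site <- as.character(log$sensor_id)
  }
  bad_site <- setdiff(unique(log$site), SITES)
  if (length(bad_site)) {
    abort(paste0("unknown body site(s): ", paste(bad_site, collapse = ", ")),
          class = "gaitkin_format_error")
  }
  if (gyro_units == "deg/s") {
    log[c("wx", "wy", "wz")] <- log[c("wx", "wy", "wz")] * pi / 180
  }
  if (accel_units == "g") {
    log[c("fx", "fy", "fz")] <- log[c("fx", "fy", "fz")] * GRAVITY
  }
  keep <- c("t", "site", "fx", "fy", "fz", "wx", "wy", "wz",
            if (has_mag) c("mx", "my", "mz"))
  log <- log[keep]
  num_cols <- setdiff(keep, "site")
  for (cl in num_cols[!num_cols %in% c("mx", "my", "mz")]) {
    check_finite(log[[cl]], cl)
  }
  log <- arrange(log, .data$site, .data$t)
  dup <- log %>% group_by(.data$site) %>%
    summarise(dup = anyDuplicated(.data$t) > 0)
  if (any(dup$dup)) {
    abort(paste0("duplicate timestamps within sensor(s): ",
                 paste(dup$site[dup$dup], collapse = ", ")),
          class = "gaitkin_data_error")
  }
  attr(log, "units") <- "SI"
  log
}

#' Write a multi-sensor IMU log
#'
#' Inverse of [read_imu_log()]; writes SI values so that reading the file
#' back reproduces the tibble.
#'
#' @param log tibble as returned by [read_imu_log()] or
#'   [simulate_walk()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_imu_log <- function(log, path) {
  out <- as.data.frame(log)
  out$sensor_id <- out$site
  out$site <- NULL
  cols <- c("t", "sensor_id", "fx", "fy", "fz", "wx", "wy", "wz",
            intersect(c("mx", "my", "mz"), names(out)))
  write.csv(out[cols], path, row.names = FALSE)
  invisible(path)
}

# Table-1 style noise defaults, converted to SI. PSDs are one-sided
# densities; sigma values assume a 26 Hz sample rate (13 Hz bandwidth).
default_noise <- function(sample_rate = 26) {
  bw <- sample_rate / 2
  accel_psd <- 400e-6 * GRAVITY            # 400 ug/sqrt(Hz) -> (m/s^2)/sqrt(Hz)
  gyro_psd <- 0.01 * pi / 180              # 0.01 deg/s/sqrt(Hz) -> rad/s/sqrt(Hz)
  list(
    accel_psd = accel_psd,
    gyro_psd = gyro_psd,
    sigma_a = accel_psd * sqrt(bw),
    sigma_w = gyro_psd * sqrt(bw),
    gyro_bias_range = 20 * pi / 180,       # initial zero tolerance, rad/s
    bias_psd = 5e-7,                       # gyro bias drift PSD, (rad/s^2)^2 s
    bias_tau = 300                         # Gauss-Markov correlation time, s
  )
}

#' Construct a body configuration
#'
#' Segment lengths of the five-segment skeletal model (pelvis width and
#' thigh/shank lengths; the shank length runs from the knee to the heel
#' because the foot segment is folded into an extended shank) together
#' with sensor noise parameters. Missing noise entries are filled with
#' defaults derived from the data sheets of the low-cost MEMS parts the
#' package targets (accelerometer noise 300-400 ug/sqrt(Hz), gyroscope
#' noise 0.005-0.01 deg/s/sqrt(Hz)).
#'
#' @param pelvis,thigh_L,thigh_R,shank_L,shank_R segment lengths in m.
#' @param noise optional named list overriding entries of the default
#'   noise block (`accel_psd`, `gyro_psd`, `sigma_a`, `sigma_w`,
#'   `gyro_bias_range`, `bias_psd`, `bias_tau`).
#' @param g gravitational acceleration, m/s^2.
#' @param sample_rate nominal sample rate in Hz, used only to convert
#'   noise densities to per-sample standard deviations.
#' @return An object of class `body_config`.
#' @export
body_config <- function(pelvis = 0.3, thigh_L = 0.45, thigh_R = 0.45,
                        shank_L = 0.45, shank_R = 0.45,
                        noise = list(), g = GRAVITY, sample_rate = 26) {
  lengths <- c(pelvis = pelvis, thigh_L = thigh_L, thigh_R = thigh_R,
               shank_L = shank_L, shank_R = shank_R)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    abort("all segment lengths must be positive and finite",
          class = "gaitkin_validation_error")
  }
  nz <- utils::modifyList(default_noise(sample_rate), as.list(noise))
  if (any(unlist(nz) <= 0)) {
    abort("all noise parameters must be positive",
          class = "gaitkin_validation_error")
  }
  structure(list(lengths = as.list(lengths), noise = nz, g = g,
                 sample_rate = sample_rate),
            class = "body_config")
}

#' @export
print.body_config <- function(x, ...) {
  cat("<body_config>\n")
  cat(sprintf("  lengths (m): pelvis %.3f, thigh %.3f/%.3f, shank %.3f/%.3f\n",
              x$lengths$pelvis, x$lengths$thigh_L, x$lengths$thigh_R,
              x$lengths$shank_L, x$lengths$shank_R))
  cat(sprintf("  noise: sigma_a %.4g m/s^2, sigma_w %.4g rad/s\n",
              x$noise$sigma_a, x$noise$sigma_w))
  cat(sprintf("  g = %.5f m/s^2, sample rate %.3g Hz\n", x$g, x$sample_rate))
  invisible(x)
}

#' Load a body configuration from YAML or JSON
#'
#' The file must contain a `lengths` block with the five segment lengths;
#' `noise`, `g` and `sample_rate` are optional and default as in
#' [body_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `body_config` object.
#' @export
load_body_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$lengths)) {
    abort("config must contain a `lengths` block",
          class = "gaitkin_validation_error")
  }
  ln <- cfg$lengths
  body_config(pelvis = ln$pelvis, thigh_L = ln$thigh_L, thigh_R = ln$thigh_R,
              shank_L = ln$shank_L, shank_R = ln$shank_R,
              noise = if (is.null(cfg$noise)) list() else cfg$noise,
              g = if (is.null(cfg$g)) GRAVITY else cfg$g,
              sample_rate = if (is.null(cfg$sample_rate)) 26 else cfg$sample_rate)
}

#' Write a body configuration to YAML or JSON
#'
#' @param config a `body_config` object.
#' @param path output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_body_config <- function(config, path) {
  stopifnot(inherits(config, "body_config"))
  out <- list(lengths = config$lengths, noise = config$noise,
              g = config$g, sample_rate = config$sample_rate)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    # emit doubles verbatim at full precision (yaml caps `precision` at 12)
    num17 <- function(x) structure(sprintf("%.17e", x), class = "verbatim")
    yaml::write_yaml(out, path,
                     handlers = list(numeric = num17, integer = num17))
  }
  invisible(path)
}

# extract one site's samples as a plain tibble, validating presence
site_trace <- function(log, site) {
  tr <- filter(log, .data$site == !!site)
  if (nrow(tr) == 0) {
    abort(sprintf("log contains no samples for site '%s'", site),
          class = "gaitkin_data_error")
  }
  tr
}
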