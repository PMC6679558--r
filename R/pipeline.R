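#' Percentage-of-distance error
#'
#' Positioning error expressed as a percentage of the total travelled
#' distance: `100 * |sum(est) - sum(true)| / sum(true)` over paired
#' per-step lengths.
#'
#' @param estimated,reference equal-length vectors of per-step lengths, m.
#' @return Percentage (scalar).
#' @export
percent_distance_error <- function(estimated, reference) {
  stopifnot(length(estimated) == length(reference))
  tot <- sum(reference)
  if (tot == 0) {
    abort("reference distance is zero", class = "gaitkin_invalid_argument")
  }
  100 * abs(sum(estimated) - tot) / tot
}

# match estimated step records to reference records of the same kind and
# side by nearest heel-strike time (within half a cycle)
match_steps <- function(est, ref, max_dt = 0.6) {
  est <- est[!est$excluded, ]
  ref <- ref[!ref$excluded, ]
  out <- list()
  for (i in seq_len(nrow(est))) {
    cand <- ref[ref$kind == est$kind[i] &
                  (ref$side == est$side[i] | est$side[i] == "n/a" |
                     ref$side == "n/a"), ]
    if (!nrow(cand)) next
    j <- which.min(abs(cand$t_heel_strike - est$t_heel_strike[i]))
    if (abs(cand$t_heel_strike[j] - est$t_heel_strike[i]) > max_dt) next
    out[[length(out) + 1]] <- tibble(
      kind = est$kind[i], side = est$side[i],
      t_heel_strike = est$t_heel_strike[i],
      estimate = est$value[i], reference = cand$value[j],
      error = est$value[i] - cand$value[j])
  }
  if (!length(out)) {
    return(tibble(kind = character(), side = character(),
                  t_heel_strike = numeric(), estimate = numeric(),
                  reference = numeric(), error = numeric()))
  }
  bind_rows(out)
}

step_error_stats <- function(matched) {
  matched %>%
    group_by(.data$kind, .data$side) %>%
    summarise(n = dplyr::n(),
              mean_error = mean(abs(.data$error)),
              sd_error = stats::sd(.data$error),
              max_error = max(abs(.data$error)),
              .groups = "drop")
}

#' Run the full gait pipeline on a multi-sensor log
#'
#' Chains gait event detection, orientation filtering, forward-kinematic
#' step extraction and, on request, the empirical step models and the
#' foot strapdown filter; when ground truth is supplied (e.g. from
#' [simulate_walk()]) every method's step records are matched to the
#' true ones and summarised as mean/sd/max absolute errors and a
#' percentage-of-distance error.
#'
#' @param log tidy IMU log.
#' @param config a [body_config()].
#' @param methods subset of `c("fk", "fk2d", "weinberg", "kim",
#'   "strapdown")`.
#' @param truth optional ground-truth list (`steps`, `events`, ...) as
#'   produced by [simulate_walk()].
#' @param params a [detector_params()].
#' @param noise a [filter_noise()].
#' @param strap a [strapdown_params()].
#' @param calibrate_k calibrate the Weinberg/Kim `k` against the truth
#'   (when available) instead of using the defaults?
#' @return An object of class `gait_report`: list with `steps` (all step
#'   records, with a `method` column), `events`, `orientation` (the
#'   `orientation_fit`), `summary` (per-method error statistics, when
#'   truth is given), `percent_distance` (per method, from
#'   `step_length_feet` records), `swing_counts` and `k` (fitted model
#'   parameters).
#' @export
run_gait_pipeline <- function(log, config = body_config(),
                              methods = c("fk", "fk2d", "weinberg", "kim",
                                          "strapdown"),
                              truth = NULL,
                              params = detector_params(),
                              noise = filter_noise(config),
                              strap = strapdown_params(),
                              calibrate_k = !is.null(truth)) {
  methods <- match.arg(methods, several.ok = TRUE)
  events <- detect_gait_events(log, params)
  per_foot <- attr(events, "per_foot")
  fit <- run_orientation_filter(log, config, noise)
  steps <- list(); ks <- list()
  if ("fk" %in% methods) {
    steps$fk <- mutate(compute_step_lengths(fit$angles, events, config,
                                            method = "fk"), method = "fk")
  }
  if ("fk2d" %in% methods) {
    steps$fk2d <- mutate(compute_step_lengths(fit$angles, events, config,
                                              method = "fk2d"),
                         method = "fk2d")
  }
  for (mm in intersect(c("weinberg", "kim"), methods)) {
    st <- model_step_lengths(log, events, method = mm)
    if (calibrate_k && !is.null(truth)) {
      ref_kind <- if (mm == "weinberg") "step_length_feet" else "stride_length"
      matched <- match_steps(mutate(st, value = .data$raw),
                             truth$steps[truth$steps$kind == ref_kind, ])
      if (nrow(matched)) {
        k <- calibrate_k(matched$reference, matched$estimate)
        st$value <- k * st$raw
        ks[[mm]] <- k
      }
    }
    steps[[mm]] <- mutate(st, method = mm)
  }
  if ("strapdown" %in% methods) {
    sd_fit <- lapply(per_foot, function(pf) {
      tr <- site_trace(log, if (pf$foot == "left") "foot_L" else "foot_R")
      zupt_ekf_strides(tr, pf, strap)
    })
    steps$strapdown <- mutate(bind_rows(lapply(sd_fit, `[[`, "steps")),
                              method = "strapdown")
  }
  all_steps <- bind_rows(steps)
  swing_counts <- vapply(per_foot, function(pf) sum(pf$valid), integer(1))
  summary_tb <- NULL; pct <- NULL
  if (!is.null(truth)) {
    summary_tb <- bind_rows(lapply(names(steps), function(mm) {
      m <- match_steps(steps[[mm]], truth$steps)
      if (!nrow(m)) return(NULL)
      mutate(step_error_stats(m), method = mm, .before = 1)
    }))
    pct <- vapply(names(steps), function(mm) {
      m <- match_steps(steps[[mm]], truth$steps)
      m <- m[m$kind == "step_length_feet", ]
      if (!nrow(m)) return(NA_real_)
      percent_distance_error(m$estimate, m$reference)
    }, numeric(1))
  }
  structure(list(steps = all_steps, events = events, orientation = fit,
                 summary = summary_tb, percent_distance = pct,
                 swing_counts = swing_counts, k = ks,
                 methods = methods),
            class = "gait_report")
}

#' @export
print.gait_report <- function(x, ...) {
  cat(sprintf("<gait_report> methods: %s; %d step records\n",
              paste(x$methods, collapse = ", "), nrow(x$steps)))
  cat("swing counts:", paste(names(x$swing_counts), x$swing_counts,
                             collapse = ", "), "\n")
  if (!is.null(x$summary)) {
    cat("error summary vs ground truth (m):\n")
    print(x$summary)
  }
  invisible(x)
}

#' @describeIn run_gait_pipeline tidy() returns all step records.
#' @param x a `gait_report`.
#' @param ... unused.
#' @export
tidy.gait_report <- function(x, ...) x$steps

#' @describeIn run_gait_pipeline glance() returns a one-row summary.
#' @export
glance.gait_report <- function(x, ...) {
  tibble(n_steps = sum(!x$steps$excluded),
         n_methods = length(x$methods),
         swings_left = unname(x$swing_counts["foot_L"]),
         swings_right = unname(x$swing_counts["foot_R"]),
         pct_distance_fk = if (!is.null(x$percent_distance))
           unname(x$percent_distance["fk"]) else NA_real_)
}

#' Serialise a gait report to JSON
#'
#' @param report a `gait_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gait_report <- function(report, path) {
  out <- list(
    methods = report$methods,
    swing_counts = as.list(report$swing_counts),
    k = report$k,
    summary = report$summary,
    percent_distance = as.list(report$percent_distance),
    steps = report$steps)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
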