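#' Spatio-temporal gait parameters from step events
#'
#' Computes the classic per-side and overall gait metrics from the complete
#' step events inside the GAP window. Conventions (with steps ordered by
#' contact time and a "step" being an event together with its immediately
#' preceding contralateral contact):
#'
#' * step length (m): mean `|dz|` between the contact position of the event
#'   and the preceding contralateral contact, along the walking (z) axis;
#' * step time (s): same difference on contact times;
#' * mean velocity (m/s): mean of per-step length / time ratios;
#' * stance (% of gait cycle): mean stationary-run duration divided by the
#'   same-side stride duration (contact to next same-side contact);
#' * double support (s): mean time per stride during which both ankles are
#'   stationary, attributed to the side whose stride contains it;
#' * step width (m): mean `|dx|` between an event and the preceding
#'   contralateral contact (reported per side and overall);
#' * cadence (steps/min): `(number of complete steps - 1)` divided by the
#'   time from first to last complete contact, times 60 (overall).
#'
#' @param events A `step_events` data frame (after
#'   [exclude_boundary_steps()]).
#' @param window A `gap_window`.
#' @param intervals Optional data frame of *all* stationary intervals of
#'   both ankles (columns `side`, `on`, `off`, see [ankle_intervals()]);
#'   used for the double-support overlaps, which need contralateral runs
#'   whose contact precedes the window. When `NULL`, the intervals are taken
#'   from `events` (which may undercount double support in the first
#'   analyzed stride).
#' @return A `gait_parameters` object: `$per_side` data frame (rows `left`,
#'   `right`) and `$overall` list with `cadence`, `step_width`, `ml_sway`,
#'   `v_sway` (sways are `NA` until [com_sway()] fills them, e.g. via
#'   [analyze_gait()]).
#' @export
gait_spatiotemporal <- function(events, window, intervals = NULL) {
  ev <- events[events$complete, , drop = FALSE]
  ev <- ev[order(ev$contact_time), , drop = FALSE]
  for (s in c("left", "right")) {
    if (sum(ev$side == s) < 2L) {
      stop("insufficient steps: fewer than 2 complete events on the ", s,
           " side", call. = FALSE)
    }
  }
  m <- nrow(ev)
  idx <- 2:m
  prev_other <- ev$side[idx - 1L] != ev$side[idx]
  steps <- data.frame(
    side = ev$side[idx],
    length = abs(ev$z[idx] - ev$z[idx - 1L]),
    time = ev$contact_time[idx] - ev$contact_time[idx - 1L],
    width = abs(ev$x[idx] - ev$x[idx - 1L])
  )[prev_other, , drop = FALSE]
  steps$velocity <- steps$length / steps$time

  # strides: event -> next same-side event
  if (is.null(intervals)) {
    intervals <- data.frame(side = events$side, on = events$contact_time,
                            off = events$liftoff_time)
  }
  li <- intervals[intervals$side == "left", , drop = FALSE]
  ri <- intervals[intervals$side == "right", , drop = FALSE]
  stance_pct <- double_support <- c(left = NA_real_, right = NA_real_)
  for (s in c("left", "right")) {
    es <- ev[ev$side == s, , drop = FALSE]
    if (nrow(es) < 2L) next
    stride_t <- diff(es$contact_time)
    stance_d <- (es$liftoff_time - es$contact_time)[-nrow(es)]
    stance_pct[s] <- mean(stance_d / stride_t) * 100
    ds <- vapply(seq_len(nrow(es) - 1L), function(i) {
      w0 <- es$contact_time[i]
      w1 <- es$contact_time[i + 1L]
      tot <- 0
      for (a in seq_len(nrow(li))) for (b in seq_len(nrow(ri))) {
        lo <- max(li$on[a], ri$on[b], w0)
        hi <- min(li$off[a], ri$off[b], w1)
        if (hi > lo) tot <- tot + (hi - lo)
      }
      tot
    }, 0)
    double_support[s] <- mean(ds)
  }

  per_side <- do.call(rbind, lapply(c("left", "right"), function(s) {
    st <- steps[steps$side == s, , drop = FALSE]
    data.frame(side = s,
               n_steps = sum(ev$side == s),
               step_length = mean(st$length),
               step_time = mean(st$time),
               mean_velocity = mean(st$velocity),
               stance_pct = stance_pct[[s]],
               double_support_s = double_support[[s]],
               step_width = mean(st$width))
  }))
  rownames(per_side) <- per_side$side
  # cadence over whole strides: with an odd number of inter-contact
  # intervals an asymmetric gait (unequal left/right step times) would bias
  # the mean interval, so the last contact is dropped when needed to keep
  # equally many left- and right-ending steps
  mc <- if ((m - 1L) %% 2L == 0L) m else m - 1L
  cadence <- (mc - 1L) / (ev$contact_time[mc] - ev$contact_time[1L]) * 60
  structure(list(per_side = per_side,
                 overall = list(cadence = cadence,
                                step_width = mean(steps$width),
                                ml_sway = NA_real_,
                                v_sway = NA_real_)),
            class = "gait_parameters")
}

#' @export
print.gait_parameters <- function(x, ...) {
  cat("<gait_parameters>\n")
  ps <- x$per_side
  for (s in rownames(ps)) {
    cat(sprintf("  %-5s n=%d  step length %.3f m  velocity %.3f m/s  stance %.1f %%  double support %.3f s  width %.3f m\n",
                s, ps[s, "n_steps"], ps[s, "step_length"],
                ps[s, "mean_velocity"], ps[s, "stance_pct"],
                ps[s, "double_support_s"], ps[s, "step_width"]))
  }
  ov <- x$overall
  cat(sprintf("  overall: cadence %.2f steps/min  step width %.3f m  ML sway %.3f m  V sway %.3f m\n",
              ov$cadence, ov$step_width, ov$ml_sway, ov$v_sway))
  invisible(x)
}

#' Peak-to-peak center-of-mass sway inside the GAP window
#'
#' Medio-lateral sway is the peak-to-peak excursion of the hip-midpoint x
#' coordinate after removing its linear drift over time (a walking path not
#' perfectly aligned with the sensor axis would otherwise masquerade as
#' sway); vertical sway is the raw peak-to-peak excursion of y. Both are
#' restricted to the GAP window.
#'
#' @param com A `com_trajectory`, normally from [com_hip()].
#' @param window A `gap_window`.
#' @param detrend_ml Remove the linear time trend from x before taking the
#'   medio-lateral peak-to-peak (default `TRUE`).
#' @param cycle_s Optional gait-cycle duration (s). When given, the drift
#'   line is estimated jointly with stride-frequency harmonics (the sway
#'   itself), so that an analysis window covering a non-integer number of
#'   sway cycles does not tilt the fitted line and inflate the peak-to-peak;
#'   only the linear part is then removed. [analyze_gait()] passes the mean
#'   stride duration here.
#' @return Named numeric vector `c(ml_sway =, v_sway =)` in meters.
#' @export
com_sway <- function(com, window, detrend_ml = TRUE, cycle_s = NULL) {
  idx <- window$entry_index:window$exit_index
  if (length(idx) < 2L) stop("empty GAP window", call. = FALSE)
  xs <- com$pos[idx, 1L]
  ys <- com$pos[idx, 2L]
  if (detrend_ml) {
    tt <- com$time[idx] - com$time[idx[1L]]
    X <- cbind(1, tt)
    span <- tt[length(tt)]
    if (!is.null(cycle_s) && is.finite(cycle_s) && cycle_s > 0 &&
        span > 1.5 * cycle_s) {
      w <- 2 * pi / cycle_s
      X <- cbind(X, sin(w * tt), cos(w * tt), sin(2 * w * tt), cos(2 * w * tt))
    }
    beta <- stats::lm.fit(X, xs)$coefficients
    xs <- xs - (beta[1L] + beta[2L] * tt)
  }
  c(ml_sway = max(xs) - min(xs), v_sway = max(ys) - min(ys))
}

#' Min-max normalization of gait parameters for radar display
#'
#' Each parameter is rescaled to \[0, 1\] between a normative "best" anchor
#' (healthy adult value, mapping to 1) and a cohort "worst" anchor (mapping
#' to 0), then clipped. For parameters with a *direct* relationship to gait
#' impairment (stance duration, double support, step width, sways: larger is
#' worse) the best anchor is the smaller number, so larger raw values land
#' near 0; for *inverse* parameters (step length, mean velocity, cadence:
#' smaller is worse) the best anchor is the larger number. A radar chart of
#' the normalized profile therefore expands outward for good walking
#' performance and collapses inward for impaired gait.
#'
#' @param values Named numeric vector of raw parameter values.
#' @param best Named numeric vector of normative best anchors (same names).
#' @param worst Named numeric vector of cohort worst anchors (same names).
#' @param relationship Named character vector, `"direct"` or `"inverse"` per
#'   parameter; defaults cover the standard eight parameters.
#' @return A `radar_profile` data frame with columns `parameter`, `value`,
#'   `normalized`, `relationship`.
#' @export
radar_normalize <- function(values, best, worst,
                            relationship = c(step_length = "inverse",
                                             mean_velocity = "inverse",
                                             cadence = "inverse",
                                             stance_pct = "direct",
                                             double_support_s = "direct",
                                             step_width = "direct",
                                             ml_sway = "direct",
                                             v_sway = "direct")) {
  pars <- names(values)
  stopifnot(all(pars %in% names(best)), all(pars %in% names(worst)))
  norm <- vapply(pars, function(p) {
    b <- best[[p]]
    w <- worst[[p]]
    if (b == w) {
      stop("degenerate anchors for '", p, "': best == worst", call. = FALSE)
    }
    rel <- relationship[[p]]
    if (rel == "direct" && b > w) {
      stop("direct parameter '", p,
           "' must have best anchor below worst anchor", call. = FALSE)
    }
    min(1, max(0, (values[[p]] - w) / (b - w)))
  }, 0)
  structure(data.frame(parameter = pars, value = as.numeric(values),
                       normalized = norm,
                       relationship = as.character(relationship[pars]),
                       row.names = NULL),
            class = c("radar_profile", "data.frame"))
}

#' Run the full gait pipeline on one trial
#'
#' End-to-end analysis of one walking trial: resample to a uniform grid,
#' zero-phase low-pass filter, locate the GAP window from the body center of
#' mass, binarize and debounce both ankle depth trajectories, extract and
#' boundary-filter the step events, and assemble the spatio-temporal
#' parameters and hip-midpoint sways.
#'
#' @param x A `skeleton_sequence` (raw capture or already uniform).
#' @param config A [gait_config()] list of processing settings.
#' @return A `gait_analysis` list: `params` ([gait_spatiotemporal()] result
#'   with sways filled in), `events`, `window`, `uniform` (the filtered
#'   sequence), `com_body`, `com_hip`, and `activities`.
#' @export
analyze_gait <- function(x, config = gait_config()) {
  config <- gait_config_validate(config)
  log_msg <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  log_msg("input: %d frames", n_frames(x))
  u <- resample_uniform(x, config$resample_hz, config$max_gap_ms)
  u <- lowpass(u, config$lowpass_hz)
  log_msg("uniform grid: %d frames at %g Hz", n_frames(u), config$resample_hz)
  cb <- com_body(u)
  window <- detect_gap_window(cb, config$gap_start_m, config$gap_end_m)
  log_msg("GAP window: %.3f-%.3f s", window$entry_time, window$exit_time)
  acts <- list(
    left = clean_activity(binarize_ankle(joint_xyz(u, "AnkleLeft")[, "z"],
                                         config$resample_hz,
                                         config$threshold_m),
                          config$min_run_ms),
    right = clean_activity(binarize_ankle(joint_xyz(u, "AnkleRight")[, "z"],
                                          config$resample_hz,
                                          config$threshold_m),
                           config$min_run_ms))
  events <- extract_steps(acts$left, acts$right, u, window)
  events <- exclude_boundary_steps(events, window)
  log_msg("steps: %d in window, %d complete", nrow(events),
          sum(events$complete))
  intervals <- rbind(ankle_intervals(acts$left, u, "left"),
                     ankle_intervals(acts$right, u, "right"))
  params <- gait_spatiotemporal(events, window, intervals)
  ch <- com_hip(u)
  cycle_s <- 2 * mean(params$per_side$step_time)
  sw <- com_sway(ch, window, config$detrend_ml, cycle_s)
  params$overall$ml_sway <- sw[["ml_sway"]]
  params$overall$v_sway <- sw[["v_sway"]]
  structure(list(params = params, events = events, window = window,
                 uniform = u, com_body = cb, com_hip = ch,
                 activities = acts, config = config),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  print(x$window)
  print(x$params)
  invisible(x)
}
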