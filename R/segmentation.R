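#' Binarize an ankle depth trajectory into stationary / in-movement frames
#'
#' Frame `i` is "in movement" (1) when the absolute difference between the
#' next and current depth (z) samples strictly exceeds `threshold_m`;
#' otherwise it is "stationary" (0). The last frame copies its predecessor's
#' state. The default threshold of 2 cm per 50 Hz frame (an ankle z-speed of
#' 1 m/s) separates the stance foot, which is planted, from the swing foot,
#' which is transported forward much faster; the same threshold works for
#' parkinsonian and hemiparetic gait without retuning. Segmentation uses the
#' z component only: the walk is along the sensor axis.
#'
#' @param z Numeric vector of ankle depth samples on a uniform grid (m).
#' @param rate_hz Sample rate of the grid (Hz).
#' @param threshold_m Per-frame displacement threshold (m), default 0.02.
#' @return An `ankle_activity`: list with the binary `active` vector,
#'   `rate_hz` and `threshold_m`.
#' @export
binarize_ankle <- function(z, rate_hz, threshold_m = 0.02) {
  n <- length(z)
  if (n < 2L) stop("need at least 2 frames to binarize", call. = FALSE)
  # strict inequality, with one part in 1e9 of slack so that a displacement
  # of exactly threshold_m stays stationary under floating-point rounding
  active <- as.integer(abs(diff(z)) > threshold_m * (1 + 1e-9))
  active <- c(active, active[n - 1L])
  structure(list(active = active, rate_hz = rate_hz,
                 threshold_m = threshold_m),
            class = "ankle_activity")
}

#' Debounce a binary activity array
#'
#' Raw per-frame thresholding is noise-fragile: a single noisy frame can
#' split a stance phase in two. Runs shorter than `min_run_ms` are merged
#' into the surrounding state, shortest run first (first of ties), iterated
#' to a fixpoint, after which the remaining runs alternate and all last at
#' least `min_run_ms`. The default 100 ms is well below any physiological
#' stance or swing phase, so genuine gait phases are never merged away;
#' `min_run_ms = 0` disables cleaning.
#'
#' @param activity An `ankle_activity` from [binarize_ankle()].
#' @param min_run_ms Minimum run duration to keep (ms), default 100.
#' @return The cleaned `ankle_activity`.
#' @export
clean_activity <- function(activity, min_run_ms = 100) {
  a <- activity$active
  if (min_run_ms > 0 && length(a) > 0L) {
    min_frames <- activity$rate_hz * min_run_ms / 1000
    repeat {
      r <- rle(a)
      if (length(r$lengths) <= 1L) break
      short <- which(r$lengths < min_frames)
      if (length(short) == 0L) break
      k <- short[which.min(r$lengths[short])]
      r$values[k] <- 1L - r$values[k]
      a <- inverse.rle(r)
    }
  }
  activity$active <- a
  activity$min_run_ms <- min_run_ms
  activity
}

# Stationary runs of a cleaned activity array as (start, end) frame indices.
stationary_runs <- function(activity) {
  r <- rle(activity$active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 0L
  data.frame(start = starts[keep], end = ends[keep])
}

#' All stationary intervals of one ankle as time intervals
#'
#' Every stationary run of the (cleaned) activity array, regardless of the
#' GAP window, as `[on, off)` time intervals with the same contact/liftoff
#' convention as [extract_steps()]. Used for double-support computation,
#' which needs the contralateral run even when its contact precedes the
#' window.
#'
#' @param activity A cleaned `ankle_activity`.
#' @param x The `uniform_skeleton` the activity was computed on.
#' @param side `"left"` or `"right"` (selects `AnkleLeft` / `AnkleRight`).
#' @return Data frame with columns `side`, `on`, `off`.
#' @export
ankle_intervals <- function(activity, x, side) {
  runs <- stationary_runs(activity)
  ankle <- if (side == "left") "AnkleLeft" else "AnkleRight"
  rt <- refine_run_times(runs, joint_xyz(x, ankle)[, "z"], x$time,
                         activity$threshold_m)
  data.frame(side = rep(side, nrow(runs)), on = rt$on, off = rt$off)
}

# Sub-frame boundary refinement. Which frames belong to a stationary run is
# decided by the displacement threshold alone; the *timing* of each
# contact/liftoff is then refined to the half-maximum crossing of the local
# speed transition. The raw threshold-crossing time shifts with swing speed
# (for a transition with rise time R smoothed by the low-pass filter it sits
# about R * (1/2 - v_thr / v_swing) away from the true event), whereas the
# half-maximum point of the transition is insensitive to the swing speed;
# it also resolves timing well below the 20 ms frame quantum.
refine_run_times <- function(runs, z, time, thr) {
  n <- length(z)
  dz <- abs(diff(z))
  nd <- length(dz)
  dt <- if (n > 1L) time[2L] - time[1L] else 0
  m <- nrow(runs)
  on <- time[runs$start]
  off <- time[pmin(runs$end + 1L, n)]
  for (j in seq_len(m)) {
    s <- runs$start[j]
    if (s > 1L) {
      mov <- max(1L, if (j > 1L) runs$end[j - 1L] + 1L else 1L):(s - 1L)
      mov <- mov[mov <= nd]
      if (length(mov) > 0L) {
        lev <- max(thr, stats::quantile(dz[mov], 0.9, names = FALSE) / 2)
        i <- mov[dz[mov] >= lev]
        i <- if (length(i) > 0L) max(i) else s - 1L
        d1 <- dz[i]
        d2 <- if (i + 1L <= nd) dz[i + 1L] else 0
        frac <- if (d1 > d2) (d1 - lev) / (d1 - d2) else 0.5
        on[j] <- time[i] + dt / 2 + min(1, max(0, frac)) * dt
      }
    }
    e <- runs$end[j]
    if (e < n && e < nd + 1L) {
      mov <- (e + 1L):(if (j < m) runs$start[j + 1L] - 1L else nd)
      mov <- mov[mov >= 1L & mov <= nd]
      if (length(mov) > 0L) {
        lev <- max(thr, stats::quantile(dz[mov], 0.9, names = FALSE) / 2)
        i <- mov[dz[mov] >= lev]
        i <- if (length(i) > 0L) min(i) else e + 1L
        d1 <- if (i - 1L >= 1L) dz[i - 1L] else 0
        d2 <- dz[i]
        frac <- if (d2 > d1) (lev - d1) / (d2 - d1) else 0.5
        off[j] <- time[i - 1L] + dt / 2 + min(1, max(0, frac)) * dt
      }
    }
  }
  data.frame(on = on, off = off)
}

#' Extract step events from the two ankle activity arrays
#'
#' Every stationary run of an ankle is a candidate foot placement: the start
#' of the run is the foot contact, its end the liftoff, and the contact
#' position is the ankle (x, z) averaged over the run (averaging suppresses
#' single-frame noise in the later length/width estimates). One event is
#' produced per stationary run whose contact time lies inside the GAP window;
#' the merged list is ordered by contact time. Runs clipped by the start or
#' end of the recording have an unknown contact or liftoff and are marked
#' incomplete.
#'
#' @param left,right Cleaned `ankle_activity` arrays for the two ankles.
#' @param x A `uniform_skeleton` holding the `AnkleLeft` / `AnkleRight`
#'   trajectories the activities were computed from.
#' @param window A `gap_window`.
#' @return A `step_events` data frame with columns `side`, `contact_time`,
#'   `liftoff_time`, `x`, `z`, `start_index`, `end_index`, `complete`.
#' @export
extract_steps <- function(left, right, x, window) {
  one_side <- function(activity, side, ankle) {
    runs <- stationary_runs(activity)
    if (nrow(runs) == 0L) return(NULL)
    pos <- joint_xyz(x, ankle)
    n <- length(activity$active)
    rt <- refine_run_times(runs, pos[, 3L], x$time, activity$threshold_m)
    data.frame(
      side = side,
      contact_time = rt$on,
      liftoff_time = rt$off,
      x = vapply(seq_len(nrow(runs)),
                 function(i) mean(pos[runs$start[i]:runs$end[i], 1L]), 0),
      z = vapply(seq_len(nrow(runs)),
                 function(i) mean(pos[runs$start[i]:runs$end[i], 3L]), 0),
      start_index = runs$start,
      end_index = runs$end,
      complete = runs$start > 1L & runs$end < n
    )
  }
  ev <- rbind(one_side(left, "left", "AnkleLeft"),
              one_side(right, "right", "AnkleRight"))
  if (is.null(ev)) ev <- data.frame(side = character(), contact_time = numeric(),
                                    liftoff_time = numeric(), x = numeric(),
                                    z = numeric(), start_index = integer(),
                                    end_index = integer(), complete = logical())
  ev <- ev[ev$contact_time >= window$entry_time &
             ev$contact_time <= window$exit_time, , drop = FALSE]
  ev <- ev[order(ev$contact_time), , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) == 0L) {
    warning("no step events inside the GAP window", call. = FALSE)
  }
  class(ev) <- c("step_events", class(ev))
  ev
}

#' Drop steps clipped by the GAP boundaries
#'
#' The first and last placements of a walk typically straddle the start or
#' end line of the analysis corridor, so their stance phases are truncated
#' and their timings unreliable. Events whose stationary run begins before
#' the window entry or ends after the window exit are marked
#' `complete = FALSE`; parameter estimation uses complete events only.
#'
#' @param events A `step_events` data frame.
#' @param window A `gap_window`.
#' @return The same data frame with the `complete` flag updated.
#' @export
exclude_boundary_steps <- function(events, window) {
  if (nrow(events) == 0L) return(events)
  events$complete <- events$complete &
    events$contact_time >= window$entry_time &
    events$liftoff_time <= window$exit_time
  events
}
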