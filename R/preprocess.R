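#' Resample a skeleton sequence onto a uniform grid
#'
#' Interpolates every coordinate channel with a natural cubic spline onto the
#' arithmetic grid `t0 + k / rate_hz` spanning the original support
#' (no extrapolation), producing `floor(duration * rate_hz) + 1` frames.
#' Tracking flags, when present, are carried over by nearest-neighbour
#' resampling. This removes the timestamp jitter of a variable-framerate
#' (~30 FPS) capture before filtering and segmentation; the pipeline order is
#' always resample, then filter.
#'
#' Frames flagged `"not-tracked"` on a joint are treated as gaps for that
#' joint and bridged by the spline; if any bridged gap exceeds `max_gap_ms`
#' a warning of class `rgbdgait_long_gap` is emitted, since interpolating long
#' stretches fabricates motion.
#'
#' @param x A [skeleton_sequence()] with at least 4 frames.
#' @param rate_hz Target sample rate in Hz (default 50).
#' @param max_gap_ms Longest gap (ms) bridged silently (default 200).
#' @return A `uniform_skeleton` (a `skeleton_sequence` with attribute
#'   `rate_hz` and exactly gridded timestamps).
#' @export
resample_uniform <- function(x, rate_hz = 50, max_gap_ms = 200) {
  t_in <- x$time
  if (length(t_in) < 4L) {
    stop("insufficient data: need at least 4 frames, got ", length(t_in),
         call. = FALSE)
  }
  if (anyDuplicated(t_in)) stop("duplicate timestamps", call. = FALSE)
  if (is.unsorted(t_in, strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  n_out <- floor((t_in[length(t_in)] - t_in[1L]) * rate_hz) + 1L
  t_out <- t_in[1L] + (seq_len(n_out) - 1L) / rate_hz

  joints <- vector("list", length(x$joints))
  names(joints) <- names(x$joints)
  state <- if (is.null(x$state)) NULL else vector("list", 0L)
  gap_joints <- character(0)
  gap_ms <- 0
  for (j in names(x$joints)) {
    m <- x$joints[[j]]
    keep <- rep(TRUE, nrow(m))
    if (!is.null(x$state) && !is.null(x$state[[j]])) {
      keep <- x$state[[j]] != "not-tracked"
    }
    keep <- keep & is.finite(rowSums(m))
    if (sum(keep) < 4L) {
      stop("insufficient tracked frames for joint '", j, "'", call. = FALSE)
    }
    tk <- t_in[keep]
    if (max(diff(tk)) * 1000 > max_gap_ms) {
      gap_joints <- c(gap_joints, j)
      gap_ms <- max(gap_ms, max(diff(tk)) * 1000)
    }
    out <- matrix(NA_real_, n_out, 3L)
    for (k in 1:3) {
      out[, k] <- stats::spline(tk, m[keep, k], xout = t_out,
                                method = "natural")$y
    }
    joints[[j]] <- out
    if (!is.null(x$state) && !is.null(x$state[[j]])) {
      nn <- vapply(t_out, function(tt) which.min(abs(t_in - tt)), integer(1L))
      state[[j]] <- x$state[[j]][nn]
    }
  }
  if (length(gap_joints) > 0L) {
    warning(warningCondition(
      paste0("tracking gap of up to ", round(gap_ms), " ms (> ", max_gap_ms,
             " ms) bridged on joint(s) ",
             paste(utils::head(gap_joints, 5L), collapse = ", "),
             if (length(gap_joints) > 5L) ", ..." else "",
             "; interpolated values there are unreliable"),
      class = "rgbdgait_long_gap"))
  }
  if (!is.null(state) && length(state) == 0L) state <- NULL
  out <- skeleton_sequence(t_out, joints, state)
  attr(out, "rate_hz") <- rate_hz
  class(out) <- c("uniform_skeleton", class(out))
  out
}

#' Test whether a sequence sits on a uniform grid
#' @param x A `skeleton_sequence`.
#' @return `TRUE` if `x` carries a `rate_hz` attribute from
#'   [resample_uniform()] or the generator.
#' @export
is_uniform <- function(x) !is.null(attr(x, "rate_hz"))

# Zero-phase IIR filtering with odd-reflection edge padding (the padding that
# signal::filtfilt lacks; without it a constant channel picks up ~1 unit of
# edge transient). Pad length covers the filter's startup transient at the
# default 10 Hz / 50 Hz design.
zero_phase_filter <- function(b, a, x, pad) {
  n <- length(x)
  np <- min(pad, n - 1L)
  pre <- 2 * x[1L] - x[seq(np + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - np)]
  xp <- c(pre, x, post)
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(np + 1L):(np + n)]
}

#' Low-pass filter a uniform skeleton sequence
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' (zero phase, so event timings are not delayed) to every coordinate channel.
#' DC gain is exactly 1: a constant channel passes unchanged. The default
#' 10 Hz cutoff removes sensor noise while leaving gait-band motion
#' (fundamental stride frequencies are below 2 Hz) untouched.
#'
#' @param x A `uniform_skeleton` from [resample_uniform()] (or the generator).
#' @param cutoff_hz Cutoff frequency in Hz (default 10); must be below half
#'   the sample rate.
#' @param order Butterworth order of each pass (default 4).
#' @return A `uniform_skeleton` with filtered coordinates.
#' @export
lowpass <- function(x, cutoff_hz = 10, order = 4) {
  rate <- attr(x, "rate_hz")
  if (is.null(rate)) {
    stop("input must be uniform; run resample_uniform() first", call. = FALSE)
  }
  if (rate <= 2 * cutoff_hz) {
    stop("sample rate (", rate, " Hz) must exceed twice the cutoff (",
         cutoff_hz, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (rate / 2))
  pad <- max(24L, as.integer(ceiling(20 * rate / cutoff_hz)))
  joints <- lapply(x$joints, function(m) {
    for (k in 1:3) m[, k] <- zero_phase_filter(bf$b, bf$a, m[, k], pad)
    m
  })
  out <- skeleton_sequence(x$time, joints, x$state)
  attr(out, "rate_hz") <- rate
  class(out) <- c("uniform_skeleton", class(out))
  out
}
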