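#' The 25 joints of the Kinect v2 skeletal model
#'
#' Ordered joint names of the skeletal model produced by the body-tracking
#' algorithm of Kinect-v2-class RGB-D sensors. All skeleton containers in this
#' package use these names; the five joints in [required_joints()] must always
#' be present.
#'
#' @return Character vector of 25 joint names.
#' @export
kinect_joints <- function() {
  c("SpineBase", "SpineMid", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight",
    "SpineShoulder", "HandTipLeft", "ThumbLeft",
    "HandTipRight", "ThumbRight")
}

#' Joints that every skeleton sequence must contain
#'
#' The gait pipeline needs the two ankles (step segmentation), the two hips
#' (hip-midpoint center of mass) and the spine base (body center of mass).
#'
#' @return Character vector of joint names.
#' @export
required_joints <- function() {
  c("AnkleLeft", "AnkleRight", "HipLeft", "HipRight", "SpineBase")
}

#' Construct a skeletal time series
#'
#' A `skeleton_sequence` holds time-stamped 3D joint positions in the sensor
#' reference frame: x is medio-lateral, y vertical, z depth increasing away
#' from the sensor; units are meters and seconds throughout. Timestamps may be
#' irregular (a Kinect-class sensor delivers roughly 30 frames/s with
#' timestamp jitter).
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing.
#' @param joints Named list of n-by-3 numeric matrices (columns x, y, z in
#'   meters), one per joint, each with `length(time)` rows. Must contain at
#'   least [required_joints()].
#' @param state Optional named list of character vectors (per joint, per
#'   frame) with tracking states `"tracked"`, `"inferred"` or `"not-tracked"`.
#' @return An object of class `skeleton_sequence`.
#' @seealso [read_skeleton()], [write_skeleton()], [resample_uniform()]
#' @export
skeleton_sequence <- function(time, joints, state = NULL) {
  obj <- structure(list(time = as.numeric(time),
                        joints = joints,
                        state = state),
                   class = "skeleton_sequence")
  validate_skeleton(obj)
  obj
}

validate_skeleton <- function(x) {
  time <- x$time
  if (length(time) > 1L) {
    d <- diff(time)
    bad <- which(d <= 0)
    if (length(bad) > 0L) {
      stop("timestamps must be strictly increasing; first offending index: ",
           bad[1L] + 1L, call. = FALSE)
    }
  }
  missing <- setdiff(required_joints(), names(x$joints))
  if (length(missing) > 0L) {
    stop("required joint(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (j in names(x$joints)) {
    m <- x$joints[[j]]
    if (!is.matrix(m) || ncol(m) != 3L) {
      stop("joint '", j, "' must be an n-by-3 matrix", call. = FALSE)
    }
    if (nrow(m) != length(time)) {
      stop("joint '", j, "' has ", nrow(m), " frames but there are ",
           length(time), " timestamps", call. = FALSE)
    }
    tracked <- rep(TRUE, nrow(m))
    if (!is.null(x$state) && !is.null(x$state[[j]])) {
      tracked <- x$state[[j]] != "not-tracked"
    }
    if (any(tracked & !stats::complete.cases(m) |
            tracked & !is.finite(rowSums(m)))) {
      stop("joint '", j, "' has non-finite coordinates on tracked frames",
           call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  n <- length(x$time)
  cat("<skeleton_sequence> ", n, " frames, ", length(x$joints), " joints\n",
      sep = "")
  if (n > 0L) {
    dur <- x$time[n] - x$time[1L]
    cat(sprintf("  span %.3f s (mean rate %.1f Hz)\n", dur,
                if (dur > 0) (n - 1L) / dur else NA_real_))
  }
  rate <- attr(x, "rate_hz")
  if (!is.null(rate)) cat("  uniform grid at ", rate, " Hz\n", sep = "")
  invisible(x)
}

#' Number of frames in a skeleton sequence
#' @param x A `skeleton_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) length(x$time)

#' Extract one joint's trajectory
#'
#' @param x A `skeleton_sequence`.
#' @param joint Joint name, e.g. `"AnkleLeft"`.
#' @return n-by-3 matrix with columns `x`, `y`, `z` (meters).
#' @export
joint_xyz <- function(x, joint) {
  m <- x$joints[[joint]]
  if (is.null(m)) stop("joint '", joint, "' not present", call. = FALSE)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Mirror a skeleton across the medio-lateral origin
#'
#' Negates every x coordinate and swaps each Left joint with its Right
#' counterpart, producing the left-right mirrored walk. Running the pipeline
#' on a mirrored trial swaps the per-side gait parameters exactly and leaves
#' the overall parameters unchanged, which makes this useful for symmetry
#' checks and data augmentation.
#'
#' @param x A `skeleton_sequence`.
#' @return A mirrored `skeleton_sequence`.
#' @export
mirror_skeleton <- function(x) {
  swap <- function(nm) {
    out <- nm
    out[grepl("Left", nm)] <- sub("Left", "Right", nm[grepl("Left", nm)])
    out[grepl("Right", nm)] <- sub("Right", "Left", nm[grepl("Right", nm)])
    out
  }
  joints <- x$joints
  names(joints) <- swap(names(joints))
  joints <- lapply(joints, function(m) {
    m[, 1L] <- -m[, 1L]
    m
  })
  state <- x$state
  if (!is.null(state)) names(state) <- swap(names(state))
  out <- skeleton_sequence(x$time, joints, state)
  attr(out, "rate_hz") <- attr(x, "rate_hz")
  class(out) <- class(x)
  out
}
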