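new_com_trajectory <- function(time, pos, kind) {
  colnames(pos) <- c("x", "y", "z")
  structure(list(time = time, pos = pos, kind = kind),
            class = "com_trajectory")
}

#' @export
print.com_trajectory <- function(x, ...) {
  cat("<com_trajectory> ", x$kind, ", ", length(x$time), " frames\n", sep = "")
  invisible(x)
}

#' Body center-of-mass proxy
#'
#' Per-frame unweighted centroid of the trunk joints SpineBase, SpineMid,
#' HipLeft and HipRight. A trunk-dominated proxy is robust to limb tracking
#' noise and is what the pipeline uses to decide when the subject is inside
#' the gait analysis path; the contributing joint set is an argument so the
#' estimator can be swapped.
#'
#' @param x A `skeleton_sequence`.
#' @param joints Joints to average (default the four trunk joints).
#' @return A `com_trajectory` of kind `"COM_BODY"`.
#' @export
com_body <- function(x, joints = c("SpineBase", "SpineMid",
                                   "HipLeft", "HipRight")) {
  joints_here <- intersect(joints, names(x$joints))
  missing <- setdiff(joints, names(x$joints))
  if (length(missing) > 0L) {
    stop("missing torso joint(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pos <- Reduce(`+`, x$joints[joints_here]) / length(joints_here)
  new_com_trajectory(x$time, pos, "COM_BODY")
}

#' Hip-midpoint center of mass
#'
#' Exact per-frame 3D midpoint of the HipLeft-HipRight segment. Its
#' peak-to-peak excursions along the medio-lateral (x) and vertical (y)
#' directions are the sway parameters reported by [com_sway()].
#'
#' @param x A `skeleton_sequence`.
#' @return A `com_trajectory` of kind `"COM_HIP"`.
#' @export
com_hip <- function(x) {
  for (j in c("HipLeft", "HipRight")) {
    if (is.null(x$joints[[j]])) stop("missing hip joint: ", j, call. = FALSE)
  }
  pos <- (x$joints[["HipLeft"]] + x$joints[["HipRight"]]) / 2
  new_com_trajectory(x$time, pos, "COM_HIP")
}

#' Detect the gait analysis path (GAP) window
#'
#' The subject walks toward the sensor; the analysis corridor starts
#' `gap_start_m` from the sensor (4.2 m by default, where body tracking
#' becomes reliable) and ends about `gap_end_m` (1.5 m) from it. Entry is the
#' first frame whose full 3D Euclidean COM distance from the sensor origin
#' drops to `gap_start_m` or below; exit is the first later frame whose
#' distance falls below `gap_end_m`, or the last frame if the subject never
#' gets that close.
#'
#' @param com A `com_trajectory` (normally from [com_body()]).
#' @param gap_start_m Distance of the start line from the sensor (m).
#' @param gap_end_m Distance of the end line from the sensor (m).
#' @return A `gap_window`: list with `entry_index`, `exit_index`,
#'   `entry_time`, `exit_time`, `gap_start_m`, `gap_end_m`.
#' @export
detect_gap_window <- function(com, gap_start_m = 4.2, gap_end_m = 1.5) {
  stopifnot(gap_start_m > gap_end_m)
  d <- sqrt(rowSums(com$pos^2))
  entry <- which(d <= gap_start_m)[1L]
  if (is.na(entry)) {
    stop("subject never enters the GAP (min distance ",
         round(min(d), 2), " m > ", gap_start_m, " m)", call. = FALSE)
  }
  later <- which(d < gap_end_m & seq_along(d) > entry)[1L]
  exit <- if (is.na(later)) length(d) else later
  structure(list(entry_index = entry, exit_index = exit,
                 entry_time = com$time[entry], exit_time = com$time[exit],
                 gap_start_m = gap_start_m, gap_end_m = gap_end_m),
            class = "gap_window")
}

#' @export
print.gap_window <- function(x, ...) {
  cat(sprintf("<gap_window> %.2f-%.2f m corridor: frames %d..%d (%.3f-%.3f s)\n",
              x$gap_start_m, x$gap_end_m, x$entry_index, x$exit_index,
              x$entry_time, x$exit_time))
  invisible(x)
}
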