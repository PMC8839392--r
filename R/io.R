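#' Read a skeletal time series from CSV or JSON
#'
#' The CSV dialect is one row per frame: a `time_s` column followed by
#' `<Joint>_x`, `<Joint>_y`, `<Joint>_z` columns (and optionally
#' `<Joint>_state`) for each joint of [kinect_joints()] present in the file.
#' The JSON dialect mirrors the same fields (`time_s` array plus a `joints`
#' object with `x`/`y`/`z`/`state` arrays per joint). Coordinates are meters
#' unless `units = "mm"`, in which case they are converted on read. Frames
#' whose required joints are flagged `"not-tracked"` are retained with their
#' flag, never dropped: downstream interpolation decides what to do with them.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"`; by default guessed from the extension.
#' @param units `"m"` (default) or `"mm"`.
#' @return A [skeleton_sequence()].
#' @export
read_skeleton <- function(path, format = c("auto", "csv", "json"),
                          units = c("m", "mm")) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  scale <- if (units == "mm") 1e-3 else 1
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!"time_s" %in% names(df)) {
      stop("format error: column 'time_s' missing", call. = FALSE)
    }
    cols <- names(df)
    joint_names <- unique(sub("_(x|y|z|state)$", "",
                              grep("_(x|y|z|state)$", cols, value = TRUE)))
    joints <- list()
    state <- list()
    for (j in joint_names) {
      need <- paste0(j, "_", c("x", "y", "z"))
      miss <- setdiff(need, cols)
      if (length(miss) > 0L) {
        stop("format error: missing column(s) ", paste(miss, collapse = ", "),
             call. = FALSE)
      }
      joints[[j]] <- cbind(df[[need[1L]]], df[[need[2L]]], df[[need[3L]]]) * scale
      sc <- paste0(j, "_state")
      if (sc %in% cols) state[[j]] <- as.character(df[[sc]])
    }
    for (j in required_joints()) {
      if (!j %in% joint_names) {
        stop("format error: required joint '", j, "' absent (no ",
             j, "_z column)", call. = FALSE)
      }
    }
    if (length(state) == 0L) state <- NULL
    skeleton_sequence(df$time_s, joints, state)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$time_s)) {
      stop("format error: field 'time_s' missing", call. = FALSE)
    }
    joints <- list()
    state <- list()
    for (j in names(obj$joints)) {
      rec <- obj$joints[[j]]
      if (is.null(rec$x) || is.null(rec$y) || is.null(rec$z)) {
        stop("format error: joint '", j, "' lacks x/y/z arrays", call. = FALSE)
      }
      joints[[j]] <- cbind(rec$x, rec$y, rec$z) * scale
      if (!is.null(rec$state)) state[[j]] <- as.character(rec$state)
    }
    for (j in required_joints()) {
      if (!j %in% names(joints)) {
        stop("format error: required joint '", j, "' absent", call. = FALSE)
      }
    }
    if (length(state) == 0L) state <- NULL
    skeleton_sequence(as.numeric(obj$time_s), joints, state)
  }
}

#' Write a skeletal time series to CSV or JSON
#'
#' Inverse of [read_skeleton()]: the written file round-trips to an identical
#' sequence (coordinates to better than 1e-9 m). Numeric precision is 9
#' decimals of a meter.
#'
#' @param x A [skeleton_sequence()].
#' @param path Output file.
#' @param format `"csv"` or `"json"`; by default guessed from the extension.
#' @return Invisibly, `path`.
#' @export
write_skeleton <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- data.frame(time_s = round(x$time, 9L))
    for (j in names(x$joints)) {
      m <- x$joints[[j]]
      df[[paste0(j, "_x")]] <- round(m[, 1L], 9L)
      df[[paste0(j, "_y")]] <- round(m[, 2L], 9L)
      df[[paste0(j, "_z")]] <- round(m[, 3L], 9L)
      if (!is.null(x$state) && !is.null(x$state[[j]])) {
        df[[paste0(j, "_state")]] <- x$state[[j]]
      }
    }
    ok <- tryCatch({
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write '", path, "': ",
                          conditionMessage(ok), call. = FALSE)
  } else {
    joints <- lapply(names(x$joints), function(j) {
      m <- x$joints[[j]]
      rec <- list(x = round(m[, 1L], 9L), y = round(m[, 2L], 9L),
                  z = round(m[, 3L], 9L))
      if (!is.null(x$state) && !is.null(x$state[[j]])) {
        rec$state <- x$state[[j]]
      }
      rec
    })
    names(joints) <- names(x$joints)
    ok <- tryCatch({
      jsonlite::write_json(list(time_s = round(x$time, 9L), joints = joints),
                           path, auto_unbox = TRUE, digits = NA)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write '", path, "': ",
                          conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}
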