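#' Gait-pattern map of one analyzed trial
#'
#' Footfall positions and the hip-midpoint trace in the walking plane, with
#' the GAP boundary lines: depth (distance from the sensor) runs along the
#' horizontal axis and the medio-lateral position along the vertical axis,
#' so the subject walks right-to-left toward the sensor. Complete steps are
#' filled, boundary-clipped ones hollow.
#'
#' @param analysis A `gait_analysis` from [analyze_gait()].
#' @return A ggplot object.
#' @export
plot_gait_pattern <- function(analysis) {
  ev <- as.data.frame(analysis$events)
  idx <- analysis$window$entry_index:analysis$window$exit_index
  com <- data.frame(z = analysis$com_hip$pos[idx, "z"],
                    x = analysis$com_hip$pos[idx, "x"])
  ggplot2::ggplot() +
    ggplot2::geom_path(data = com, ggplot2::aes(.data$z, .data$x),
                       color = "magenta") +
    ggplot2::geom_point(data = ev,
                        ggplot2::aes(.data$z, .data$x, color = .data$side,
                                     shape = .data$complete), size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::geom_vline(xintercept = c(analysis$window$gap_start_m,
                                       analysis$window$gap_end_m),
                        linetype = "dotted") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "distance from sensor (m)",
                  y = "medio-lateral position (m)",
                  color = "side") +
    ggplot2::theme_minimal()
}

#' Radar chart of a normalized gait profile
#'
#' Displays a [radar_normalize()] profile on a polar axis: values near the
#' rim (1) are normatively good, values collapsing toward the center (0)
#' indicate impairment.
#'
#' @param profile A `radar_profile`, or a named list of them (overlaid).
#' @return A ggplot object.
#' @export
plot_radar <- function(profile) {
  if (inherits(profile, "radar_profile")) profile <- list(profile = profile)
  df <- do.call(rbind, lapply(names(profile), function(nm) {
    d <- as.data.frame(profile[[nm]])
    d$trace <- nm
    d
  }))
  df$parameter <- factor(df$parameter, levels = unique(df$parameter))
  closed <- rbind(df, df[!duplicated(df$trace, fromLast = TRUE) &
                           df$parameter == levels(df$parameter)[1L], ])
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$normalized,
                                   group = .data$trace,
                                   color = .data$trace)) +
    ggplot2::geom_polygon(ggplot2::aes(fill = .data$trace), alpha = 0.15) +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "normalized value", color = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman panel for a paired table
#'
#' One difference-versus-mean panel per parameter, with the bias line and
#' the 95% limits of agreement.
#'
#' @param table A [read_paired_table()] data frame.
#' @return A ggplot object faceted by parameter.
#' @export
plot_bland_altman <- function(table) {
  systems <- sort(unique(table$system))
  pts <- do.call(rbind, lapply(unique(table$parameter), function(p) {
    wide <- paired_wide(table, p)
    ba <- bland_altman(wide[[systems[1L]]], wide[[systems[2L]]])
    cbind(parameter = p, ba$points,
          bias = ba$mean_diff, lo = ba$loa_low, hi = ba$loa_high)
  }))
  ggplot2::ggplot(pts, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$bias),
                        linetype = "solid", color = "steelblue") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$lo),
                        linetype = "dashed") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$hi),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = paste("mean of", systems[1L], "and", systems[2L]),
                  y = paste0("difference (", systems[1L], " - ",
                             systems[2L], ")")) +
    ggplot2::theme_minimal()
}
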