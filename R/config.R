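#' Processing configuration for the gait pipeline
#'
#' Collects every tunable setting of the pipeline with defaults matching the
#' reference acquisition protocol: resample to 50 Hz, low-pass at 10 Hz,
#' 2 cm per-frame ankle displacement threshold, GAP corridor from 4.2 m to
#' 1.5 m in front of the sensor.
#'
#' @param resample_hz Uniform grid rate (Hz).
#' @param lowpass_hz Low-pass cutoff (Hz).
#' @param max_gap_ms Longest tracking gap bridged without warning (ms).
#' @param threshold_m Ankle per-frame displacement threshold (m).
#' @param min_run_ms Debouncing minimum run duration (ms); 0 disables.
#' @param gap_start_m,gap_end_m GAP corridor boundaries (m from the sensor).
#' @param detrend_ml Remove linear drift from the ML axis before sway.
#' @param verbose Emit per-stage log messages.
#' @return A named list of class `gait_config`.
#' @export
gait_config <- function(resample_hz = 50, lowpass_hz = 10, max_gap_ms = 200,
                        threshold_m = 0.02, min_run_ms = 100,
                        gap_start_m = 4.2, gap_end_m = 1.5,
                        detrend_ml = TRUE, verbose = FALSE) {
  cfg <- list(resample_hz = resample_hz, lowpass_hz = lowpass_hz,
              max_gap_ms = max_gap_ms, threshold_m = threshold_m,
              min_run_ms = min_run_ms, gap_start_m = gap_start_m,
              gap_end_m = gap_end_m, detrend_ml = detrend_ml,
              verbose = verbose)
  class(cfg) <- "gait_config"
  gait_config_validate(cfg)
}

gait_config_validate <- function(cfg) {
  if (!inherits(cfg, "gait_config")) {
    cfg <- do.call(gait_config, cfg)
    return(cfg)
  }
  num <- function(field, lo = 0) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < lo) {
      stop("config field '", field, "' must be a single number >= ", lo,
           call. = FALSE)
    }
  }
  for (f in c("resample_hz", "lowpass_hz", "threshold_m")) num(f, 1e-9)
  for (f in c("max_gap_ms", "min_run_ms", "gap_end_m")) num(f)
  num("gap_start_m", 1e-9)
  if (cfg$resample_hz <= 2 * cfg$lowpass_hz) {
    stop("resample_hz must exceed twice lowpass_hz", call. = FALSE)
  }
  if (cfg$gap_start_m <= cfg$gap_end_m) {
    stop("gap_start_m must exceed gap_end_m", call. = FALSE)
  }
  cfg
}
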