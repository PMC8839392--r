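#' Specify a synthetic walking trial
#'
#' A `gait_command` fixes everything the generator needs: per-side step
#' lengths and step times, per-side stance percentages, per-side step widths,
#' sinusoidal medio-lateral and vertical hip sway amplitudes, the start
#' distance from the sensor, the capture model (nominal frame rate, uniform
#' timestamp jitter, additive white position noise) and a seed. The implied
#' double-support time per stride,
#' `stride_time * (stance_left + stance_right - 100) / 100`, is derived and
#' stored (stance and double support are not independent in an alternating
#' event model).
#'
#' @param step_length_left,step_length_right Step lengths (m): forward
#'   distance between a foot contact and the preceding contralateral contact.
#' @param step_time_left,step_time_right Step times (s): the interval ending
#'   at a contact of that side.
#' @param stance_pct_left,stance_pct_right Stance as % of the gait cycle,
#'   each in (50, 90), summing above 100 (otherwise there is no double
#'   support and the model is not a walk).
#' @param step_width_left,step_width_right Lateral offsets (m) of each
#'   landing relative to the preceding contralateral contact.
#' @param ml_sway_amp,v_sway_amp Hip-midpoint sway sinusoid amplitudes (m);
#'   peak-to-peak sway is twice these.
#' @param start_distance First foot placement depth (m), beyond the GAP
#'   start line.
#' @param n_steps Number of commanded landings; by default enough to carry
#'   the subject from `start_distance` to about 0.6 m from the sensor.
#' @param noise_sd Additive white position noise SD (m) on every joint
#'   coordinate (default 2 mm).
#' @param frame_rate_hz Nominal capture rate (default 30 FPS).
#' @param jitter_ms Uniform timestamp jitter half-width (ms, default 5).
#' @param seed Integer seed for reproducibility (optional).
#' @param swing_blend Fraction of the swing spent in each half-cosine speed
#'   blend at its ends (default 0.02). The swing core is constant-speed, so
#'   nearly all swing frames clear the segmentation threshold and the
#'   threshold crossing stays within a small fraction of the swing of the
#'   true event time.
#' @param lead_in_s Standing time before the first step (s).
#' @param tail_s Standing time after the last landing (s).
#' @param hip_height Hip-midpoint height (m).
#' @param step_height Peak ankle lift during swing (m).
#' @return A validated `gait_command` list (with derived fields
#'   `stride_time`, `stride_length`, `double_support_s`, `cadence`).
#' @export
gait_command <- function(step_length_left, step_length_right,
                         step_time_left, step_time_right,
                         stance_pct_left, stance_pct_right,
                         step_width_left = 0.10, step_width_right = 0.10,
                         ml_sway_amp = 0.02, v_sway_amp = 0.015,
                         start_distance = 5.2, n_steps = NULL,
                         noise_sd = 0.002, frame_rate_hz = 30,
                         jitter_ms = 5, seed = NULL,
                         swing_blend = 0.02, lead_in_s = 0.8, tail_s = 1.0,
                         hip_height = 0.95, step_height = 0.05) {
  cmd <- as.list(environment())
  pos <- c("step_length_left", "step_length_right", "step_time_left",
           "step_time_right", "step_width_left", "step_width_right",
           "start_distance", "frame_rate_hz", "lead_in_s", "hip_height")
  for (f in pos) {
    if (!is.numeric(cmd[[f]]) || cmd[[f]] <= 0) {
      stop("invalid command: '", f, "' must be positive", call. = FALSE)
    }
  }
  for (f in c("stance_pct_left", "stance_pct_right")) {
    if (cmd[[f]] <= 50 || cmd[[f]] >= 90) {
      stop("invalid command: '", f, "' must lie in (50, 90)", call. = FALSE)
    }
  }
  cmd$stride_time <- step_time_left + step_time_right
  cmd$stride_length <- step_length_left + step_length_right
  cmd$cadence <- 120 / cmd$stride_time
  stance_s <- c(left = stance_pct_left, right = stance_pct_right) / 100 *
    cmd$stride_time
  cmd$stance_dur_s <- stance_s
  cmd$swing_dur_s <- cmd$stride_time - stance_s
  cmd$double_support_s <- sum(stance_s) - cmd$stride_time
  if (cmd$double_support_s <= 0) {
    stop("invalid command: stance percentages sum to <= 100 ",
         "(no double support)", call. = FALSE)
  }
  # the two double-support phases per stride: leading contact to trailing
  # liftoff; each must be positive (else a foot lifts before the other
  # lands) and shorter than the step ending the phase
  ds_phase <- c(stance_s[["right"]] - step_time_left,
                stance_s[["left"]] - step_time_right)
  if (any(ds_phase <= 0)) {
    stop("invalid command: a foot would lift before the other lands",
         call. = FALSE)
  }
  if (any(ds_phase >= c(step_time_left, step_time_right))) {
    stop("invalid command: a double-support phase (",
         round(max(ds_phase), 3), " s) is not below the step time",
         call. = FALSE)
  }
  # the swing must be clearly separable from the stationary state: its core
  # z-speed has to exceed the reference detection speed (2 cm per 50 Hz
  # frame = 1 m/s) with a factor-2 margin, otherwise threshold crossings
  # smear and no displacement-threshold segmentation can recover the
  # commanded timings (physiological swings are 2-4 m/s even in slow gait)
  core_speed <- cmd$stride_length / (cmd$swing_dur_s * (1 - swing_blend))
  if (any(core_speed < 2)) {
    stop("invalid command: swing z-speed (",
         paste(round(core_speed, 2), collapse = ", "),
         " m/s) below 2 m/s; the swing would not clear the segmentation ",
         "threshold cleanly", call. = FALSE)
  }
  if (jitter_ms / 1000 >= 0.45 / frame_rate_hz) {
    stop("invalid command: jitter too large for the frame rate ",
         "(timestamps would not be increasing)", call. = FALSE)
  }
  if (is.null(n_steps)) {
    cmd$n_steps <- as.integer(ceiling((start_distance - 0.6) /
                                        (cmd$stride_length / 2)))
  }
  if (cmd$n_steps < 2L) stop("invalid command: n_steps < 2", call. = FALSE)
  class(cmd) <- "gait_command"
  cmd
}

# Displacement profile of the swing: constant-speed core with half-cosine
# velocity blends over fraction `beta` of the swing at each end. Returns the
# fraction of the total displacement covered at normalized time s in [0, 1].
swing_profile <- function(s, beta) {
  ramp <- function(u) (u - (beta / pi) * sin(pi * u / beta)) / 2
  i <- ifelse(s <= beta, ramp(pmin(s, beta)),
              ifelse(s <= 1 - beta, beta / 2 + (s - beta),
                     (1 - beta) - ramp(pmax(1 - s, 0))))
  pmin(1, pmax(0, i / (1 - beta)))
}

# Piecewise ankle trajectory for one foot: plants (position + interval) and
# blended swings between consecutive plants.
foot_track <- function(t, plants, beta, ankle_h, step_h) {
  n <- length(t)
  out <- matrix(NA_real_, n, 3L)
  np <- nrow(plants)
  for (i in seq_len(np)) {
    on <- plants$t_on[i]
    off <- plants$t_off[i]
    in_stance <- t >= on & t <= off
    out[in_stance, 1L] <- plants$x[i]
    out[in_stance, 2L] <- ankle_h
    out[in_stance, 3L] <- plants$z[i]
    if (i < np) {
      t_land <- plants$t_on[i + 1L]
      in_swing <- t > off & t < t_land
      if (any(in_swing)) {
        s <- (t[in_swing] - off) / (t_land - off)
        prof <- swing_profile(s, beta)
        smooth <- s^2 * (3 - 2 * s)
        out[in_swing, 1L] <- plants$x[i] +
          (plants$x[i + 1L] - plants$x[i]) * smooth
        out[in_swing, 2L] <- ankle_h + step_h * sin(pi * s)
        out[in_swing, 3L] <- plants$z[i] +
          (plants$z[i + 1L] - plants$z[i]) * prof
      }
    }
  }
  # before the first plant / after the last one the foot rests in place
  out[t < plants$t_on[1L], 1L] <- plants$x[1L]
  out[t < plants$t_on[1L], 2L] <- ankle_h
  out[t < plants$t_on[1L], 3L] <- plants$z[1L]
  out[t > plants$t_off[np], 1L] <- plants$x[np]
  out[t > plants$t_off[np], 2L] <- ankle_h
  out[t > plants$t_off[np], 3L] <- plants$z[np]
  out
}

#' Generate a synthetic skeletal walking trial with ground truth
#'
#' Synthesizes a 25-joint skeletal capture of a subject walking toward the
#' sensor with the commanded gait: ankles alternate planted stance phases
#' (exactly constant position in the noiseless limit) and constant-speed
#' swings with brief cosine speed blends; the hip midpoint advances at the
#' implied mean speed with sinusoidal medio-lateral (one cycle per stride)
#' and vertical (two cycles per stride) sway; timestamps are drawn at the
#' nominal frame rate with uniform jitter; white position noise is added to
#' every coordinate. The output is reproducible for a given seed.
#'
#' @param command A [gait_command()].
#' @param seed Overrides `command$seed` when given.
#' @return A list with `sequence` (the [skeleton_sequence()]), `truth` (a
#'   list with the per-step event table `steps` and the commanded parameter
#'   values `params`) and `command`.
#' @export
generate_gait <- function(command, seed = command$seed) {
  stopifnot(inherits(command, "gait_command"))
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  cmd <- command
  sides <- rep_len(c("left", "right"), cmd$n_steps)
  L <- c(left = cmd$step_length_left, right = cmd$step_length_right)
  Tm <- c(left = cmd$step_time_left, right = cmd$step_time_right)
  W <- c(left = cmd$step_width_left, right = cmd$step_width_right)
  dirs <- ifelse(sides == "left", 1, -1)

  contact <- cmd$lead_in_s + cumsum(Tm[sides])
  z_land <- cmd$start_distance - cumsum(L[sides])
  x_land <- cumsum(dirs * W[sides])
  liftoff <- contact + cmd$stance_dur_s[sides]

  plants <- function(s) {
    k <- which(sides == s)
    # the first-swinging foot starts one stride behind its first landing;
    # the other foot starts planted at start_distance
    init_z <- if (s == sides[1L]) z_land[1L] + cmd$stride_length else
      cmd$start_distance
    init_x <- if (s == sides[1L]) x_land[1L] else 0
    df <- data.frame(
      t_on = c(0, contact[k]),
      t_off = c(contact[k[1L]] - cmd$swing_dur_s[[s]], liftoff[k]),
      x = c(init_x, x_land[k]),
      z = c(init_z, z_land[k]))
    df$t_off[nrow(df)] <- Inf # final plant holds to the end of the recording
    df
  }

  t_end <- contact[cmd$n_steps] + cmd$tail_s
  rate <- cmd$frame_rate_hz
  n <- floor(t_end * rate) + 1L
  tt <- (seq_len(n) - 1L) / rate +
    stats::runif(n, -cmd$jitter_ms, cmd$jitter_ms) / 1000
  tt[1L] <- max(tt[1L], 0)
  stopifnot(!is.unsorted(tt, strictly = TRUE))

  ankle_h <- 0.08
  ankles <- list(left = foot_track(tt, plants("left"), cmd$swing_blend,
                                   ankle_h, cmd$step_height),
                 right = foot_track(tt, plants("right"), cmd$swing_blend,
                                    ankle_h, cmd$step_height))

  # root (hip midpoint) path
  t0 <- cmd$lead_in_s
  tn <- contact[cmd$n_steps]
  z0 <- cmd$start_distance + L[[sides[2L]]] / 2
  zn <- (z_land[cmd$n_steps] + z_land[cmd$n_steps - 1L]) / 2
  x0 <- x_land[1L] / 2
  xn <- (x_land[cmd$n_steps] + x_land[cmd$n_steps - 1L]) / 2
  frac <- pmin(1, pmax(0, (tt - t0) / (tn - t0)))
  root <- cbind(x0 + (xn - x0) * frac +
                  cmd$ml_sway_amp * sin(2 * pi * tt / cmd$stride_time),
                cmd$hip_height +
                  cmd$v_sway_amp * sin(4 * pi * tt / cmd$stride_time),
                z0 + (zn - z0) * frac)

  off <- function(dx, dy, dz = 0) sweep(root, 2L, c(-dx, -dy, -dz), `-`)
  joints <- list(
    SpineBase = off(0, 0.05), SpineMid = off(0, 0.25),
    SpineShoulder = off(0, 0.40), Neck = off(0, 0.45), Head = off(0, 0.60),
    ShoulderLeft = off(0.18, 0.40), ShoulderRight = off(-0.18, 0.40),
    ElbowLeft = off(0.22, 0.18), ElbowRight = off(-0.22, 0.18),
    WristLeft = off(0.24, -0.02), WristRight = off(-0.24, -0.02),
    HandLeft = off(0.25, -0.08), HandRight = off(-0.25, -0.08),
    HandTipLeft = off(0.25, -0.12), HandTipRight = off(-0.25, -0.12),
    ThumbLeft = off(0.22, -0.10), ThumbRight = off(-0.22, -0.10),
    HipLeft = off(0.10, 0), HipRight = off(-0.10, 0),
    AnkleLeft = ankles$left, AnkleRight = ankles$right,
    KneeLeft = (off(0.10, 0) + ankles$left) / 2,
    KneeRight = (off(-0.10, 0) + ankles$right) / 2,
    FootLeft = sweep(ankles$left, 2L, c(0, 0.05, 0.07), `-`),
    FootRight = sweep(ankles$right, 2L, c(0, 0.05, 0.07), `-`)
  )
  joints <- joints[kinect_joints()]
  if (cmd$noise_sd > 0) {
    joints <- lapply(joints, function(m) {
      m + matrix(stats::rnorm(length(m), 0, cmd$noise_sd), nrow(m))
    })
  }
  seq <- skeleton_sequence(tt, joints)

  truth <- list(
    steps = data.frame(side = sides, contact_time = contact,
                       liftoff_time = liftoff, x = x_land, z = z_land),
    params = list(
      step_length = L, step_time = Tm, mean_velocity = L / Tm,
      stance_pct = c(left = cmd$stance_pct_left, right = cmd$stance_pct_right),
      double_support_s = cmd$double_support_s,
      step_width = W, cadence = cmd$cadence,
      ml_sway = 2 * cmd$ml_sway_amp, v_sway = 2 * cmd$v_sway_amp))
  list(sequence = seq, truth = truth, command = command)
}

#' Named gait presets
#'
#' Worked-example commands for the generator. `"pd_table2"` and
#' `"ps_table2"` carry the per-side spatio-temporal parameters of the
#' parkinsonian and post-stroke worked examples (short variable steps with
#' high cadence for PD; longer, slower, more swaying gait for PS);
#' `"healthy"` is a symmetric normative adult gait. The printed worked-example
#' values are rounded and therefore mutually inconsistent (lengths / velocities
#' imply a slightly different cadence than the printed one; stance percentages
#' imply a slightly different double support). The presets reconcile them
#' once: step times are per-side length/velocity ratios rescaled by a common
#' factor so the overall cadence is exact, and a common offset added to both
#' stance percentages splits the stance / double-support discrepancy by
#' tolerance-weighted least squares (2 pp stance vs 0.04 s double support).
#'
#' @param name One of `"pd_table2"`, `"ps_table2"`, `"healthy"`.
#' @param ... Overrides passed on to [gait_command()] (e.g. `noise_sd`,
#'   `seed`).
#' @return A [gait_command()].
#' @export
gait_preset <- function(name = c("pd_table2", "ps_table2", "healthy"), ...) {
  name <- match.arg(name)
  reconcile <- function(L, v, stance, ds_print, cadence) {
    t0 <- L / v
    step_time <- t0 * (120 / cadence) / sum(t0)
    stride <- sum(step_time)
    ds0 <- stride * (sum(stance) - 100) / 100
    cc <- stride / 50 # d(double support)/d(stance offset, pp)
    delta <- cc * (ds_print - ds0) / (0.0008 + cc^2)
    list(step_time = step_time, stance = stance + delta)
  }
  args <- switch(name,
    pd_table2 = {
      r <- reconcile(L = c(0.39, 0.29), v = c(0.77, 0.56),
                     stance = c(76.20, 77.69), ds_print = 0.60,
                     cadence = 114.65)
      list(step_length_left = 0.39, step_length_right = 0.29,
           step_time_left = r$step_time[1L], step_time_right = r$step_time[2L],
           stance_pct_left = r$stance[1L], stance_pct_right = r$stance[2L],
           step_width_left = 0.13, step_width_right = 0.19,
           ml_sway_amp = 0.05 / 2, v_sway_amp = 0.03 / 2)
    },
    ps_table2 = {
      r <- reconcile(L = c(0.45, 0.39), v = c(0.59, 0.55),
                     stance = c(72.20, 72.65), ds_print = 0.70,
                     cadence = 79.47)
      list(step_length_left = 0.45, step_length_right = 0.39,
           step_time_left = r$step_time[1L], step_time_right = r$step_time[2L],
           stance_pct_left = r$stance[1L], stance_pct_right = r$stance[2L],
           step_width_left = 0.19, step_width_right = 0.23,
           ml_sway_amp = 0.10 / 2, v_sway_amp = 0.04 / 2)
    },
    healthy = list(step_length_left = 0.65, step_length_right = 0.65,
                   step_time_left = 60 / 110, step_time_right = 60 / 110,
                   stance_pct_left = 62, stance_pct_right = 62,
                   step_width_left = 0.10, step_width_right = 0.10,
                   ml_sway_amp = 0.02, v_sway_amp = 0.015)
  )
  do.call(gait_command, utils::modifyList(args, list(...)))
}
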