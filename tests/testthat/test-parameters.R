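test_that("a symmetric commanded gait is recovered at its commanded values", {
  cmd <- gait_command(0.50, 0.50, 0.6, 0.6, 62, 62)
  expect_equal(cmd$cadence, 100)
  sim <- generate_gait(cmd, seed = 9)
  p <- analyze_gait(sim$sequence)$params
  expect_lt(max(abs(p$per_side$step_length - 0.50)), 0.01)
  expect_lt(abs(p$overall$cadence - 100), 1)
  expect_lt(max(abs(p$per_side$stance_pct - 62)), 2)
})

test_that("coincident contacts give zero step length", {
  ev <- data.frame(side = rep(c("left", "right"), 2),
                   contact_time = c(1, 1.5, 2, 2.5),
                   liftoff_time = c(1.8, 2.3, 2.8, 3.3),
                   x = 0.1, z = 2.5,
                   start_index = 1:4, end_index = 2:5, complete = TRUE)
  w <- structure(list(entry_time = 0, exit_time = 4), class = "gap_window")
  p <- gait_spatiotemporal(ev, w)
  expect_equal(unname(p$per_side$step_length), c(0, 0))
  expect_equal(unname(p$per_side$step_width), c(0, 0))
})

test_that("too few complete events raises an error naming the side", {
  ev <- data.frame(side = c("left", "right", "left"),
                   contact_time = c(1, 1.5, 2),
                   liftoff_time = c(1.8, 2.3, 2.8),
                   x = 0, z = 3:1, start_index = 1:3, end_index = 2:4,
                   complete = TRUE)
  w <- structure(list(entry_time = 0, exit_time = 4), class = "gap_window")
  expect_error(gait_spatiotemporal(ev, w), "right")
})

test_that("sway is the windowed peak-to-peak of the hip midpoint", {
  tt <- seq(0, 6, by = 0.02)
  com <- structure(list(time = tt,
                        pos = cbind(0, 1, 3), kind = "COM_HIP"),
                   class = "com_trajectory")
  com$pos <- com$pos[rep(1, length(tt)), ]
  w <- structure(list(entry_index = 1L, exit_index = length(tt)),
                 class = "gap_window")
  expect_equal(unname(com_sway(com, w)), c(0, 0))

  com$pos[, 1] <- 0.05 * sin(2 * pi * tt / 1.2)
  com$pos[, 2] <- 1 + 0.02 * sin(4 * pi * tt / 1.2)
  sw <- com_sway(com, w, cycle_s = 1.2)
  expect_lt(abs(sw[["ml_sway"]] - 0.10), 0.005)
  expect_lt(abs(sw[["v_sway"]] - 0.04), 0.005)
  # drift in x must not masquerade as sway
  com$pos[, 1] <- com$pos[, 1] + 0.05 * tt
  sw2 <- com_sway(com, w, cycle_s = 1.2)
  expect_lt(abs(sw2[["ml_sway"]] - 0.10), 0.005)
})

test_that("commanded sways are recovered through the full pipeline", {
  cmd <- gait_preset("ps_table2", noise_sd = 0)
  p <- analyze_gait(generate_gait(cmd, seed = 10)$sequence)$params
  expect_lt(abs(p$overall$ml_sway - 0.10), 0.005)
  expect_lt(abs(p$overall$v_sway - 0.04), 0.005)
})

test_that("radar normalization maps anchors to 0/1 and respects direction", {
  best <- c(step_length = 0.65, stance_pct = 60)
  worst <- c(step_length = 0.25, stance_pct = 80)
  r <- radar_normalize(best, best, worst)
  expect_equal(unname(r$normalized), c(1, 1))
  r0 <- radar_normalize(worst, best, worst)
  expect_equal(unname(r0$normalized), c(0, 0))
  mid <- c(step_length = 0.45, stance_pct = 70)
  expect_equal(unname(radar_normalize(mid, best, worst)$normalized),
               c(0.5, 0.5))
  # direct parameter: larger raw value lands closer to 0
  hi <- radar_normalize(c(stance_pct = 78), best, worst)
  lo <- radar_normalize(c(stance_pct = 62), best, worst)
  expect_lt(hi$normalized, lo$normalized)
  expect_error(radar_normalize(mid, worst, worst), "degenerate")
  clipped <- radar_normalize(c(step_length = 0.1), best, worst)
  expect_equal(clipped$normalized, 0)
})

test_that("mirroring a trial swaps the per-side parameters exactly", {
  sim <- generate_gait(gait_preset("ps_table2"), seed = 11)
  a <- analyze_gait(sim$sequence)$params
  b <- analyze_gait(mirror_skeleton(sim$sequence))$params
  for (f in c("step_length", "step_time", "mean_velocity", "stance_pct",
              "double_support_s", "step_width", "n_steps")) {
    expect_equal(b$per_side[[f]], a$per_side[c("right", "left"), f],
                 ignore_attr = TRUE)
  }
  expect_equal(b$overall, a$overall)
})

test_that("cadence, step length and progression speed are consistent", {
  cmd <- gait_command(0.5, 0.5, 0.62, 0.62, 63, 63)
  a <- analyze_gait(generate_gait(cmd, seed = 12)$sequence)
  p <- a$params
  speed <- p$overall$cadence / 60 * mean(p$per_side$step_length)
  expect_lt(abs(speed - cmd$stride_length / cmd$stride_time) /
              (cmd$stride_length / cmd$stride_time), 0.05)
})

test_that("the same settings recover both pathology presets untouched", {
  pd <- analyze_gait(generate_gait(gait_preset("pd_table2"), seed = 13)$sequence)
  ps <- analyze_gait(generate_gait(gait_preset("ps_table2"), seed = 13)$sequence)
  # short fast steps with low sway vs longer slower swaying gait
  expect_gt(pd$params$overall$cadence, ps$params$overall$cadence)
  expect_lt(pd$params$overall$ml_sway, ps$params$overall$ml_sway)
  expect_lt(pd$params$per_side["right", "step_length"],
            ps$params$per_side["right", "step_length"])
})

test_that("a standing trial fails with an insufficient-steps error", {
  tt <- seq(0, 6, by = 1 / 30)
  js <- stats::setNames(lapply(kinect_joints(), function(j) {
    cbind(0, 1, 4)[rep(1, length(tt)), ]
  }), kinect_joints())
  s <- skeleton_sequence(tt, js)
  expect_error(analyze_gait(s), "insufficient steps|never enters")
})
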