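test_that("ankle binarization follows the strict 2 cm convention", {
  expect_equal(binarize_ankle(rep(1.5, 10), 50)$active, rep(0L, 10))
  z <- 3 - 0.03 * (0:9)
  expect_equal(binarize_ankle(z, 50)$active, rep(1L, 10))
  z <- 3 - 0.02 * (0:9) # exactly at the threshold stays stationary
  expect_equal(binarize_ankle(z, 50)$active, rep(0L, 10))
  expect_error(binarize_ankle(1.0, 50), "at least 2")
  # last frame copies its predecessor
  z <- c(1, 1, 1, 0.9, 0.8)
  a <- binarize_ankle(z, 50)$active
  expect_equal(a[5], a[4])
})

test_that("debouncing removes spikes, keeps fixpoints and matches the oracle", {
  mk <- function(a) structure(list(active = a, rate_hz = 50,
                                   threshold_m = 0.02),
                              class = "ankle_activity")
  spiky <- c(rep(0L, 20), 1L, rep(0L, 20))
  expect_equal(clean_activity(mk(spiky), 100)$active, rep(0L, 41))
  ok <- c(rep(0L, 10), rep(1L, 10), rep(0L, 10))
  expect_equal(clean_activity(mk(ok), 100)$active, ok)
  expect_equal(clean_activity(mk(spiky), 0)$active, spiky)

  set.seed(21)
  for (i in 1:300) {
    a <- sample(0:1, sample(10:80, 1), replace = TRUE)
    min_frames <- 50 * 100 / 1000
    expect_identical(clean_activity(mk(a), 100)$active,
                     oracle_clean(a, min_frames))
  }
})

test_that("step extraction equals a brute-force run scanner", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(c(60, 150, 400), 1)
    a_l <- oracle_clean(sample(0:1, n, replace = TRUE), 5)
    a_r <- oracle_clean(sample(0:1, n, replace = TRUE), 5)
    tt <- (0:(n - 1)) / 50
    # depth series whose binarization reproduces the arrays exactly
    z_of <- function(a) cumsum(c(5, -0.05 * a[-n]))
    js <- stats::setNames(rep(list(cbind(0, 0.1, 5)[rep(1, n), ]), 25),
                          kinect_joints())
    js$AnkleLeft <- cbind(0.1, 0.1, z_of(a_l))
    js$AnkleRight <- cbind(-0.1, 0.1, z_of(a_r))
    u <- skeleton_sequence(tt, js)
    attr(u, "rate_hz") <- 50
    class(u) <- c("uniform_skeleton", class(u))
    mk <- function(a) structure(list(active = a, rate_hz = 50,
                                     threshold_m = 0.02),
                                class = "ankle_activity")
    window <- structure(list(entry_index = 1L, exit_index = n,
                             entry_time = tt[1], exit_time = tt[n],
                             gap_start_m = 99, gap_end_m = 0),
                        class = "gap_window")
    ev <- suppressWarnings(extract_steps(mk(a_l), mk(a_r), u, window))
    for (side in c("left", "right")) {
      runs <- oracle_runs(if (side == "left") a_l else a_r)
      here <- ev[ev$side == side, ]
      expect_equal(nrow(here), if (is.null(runs)) 0L else nrow(runs))
      if (!is.null(runs)) {
        expect_equal(here$start_index[order(here$start_index)], runs[, 1])
        # refined timings stay within one frame of the raw run boundaries
        expect_true(all(abs(here$contact_time - tt[runs[, 1]]) <= 1 / 50 + 1e-9))
        expect_true(all(abs(here$liftoff_time -
                              tt[pmin(runs[, 2] + 1, n)]) <= 1 / 50 + 1e-9))
      }
    }
    expect_false(is.unsorted(ev$contact_time))
  }
})

test_that("generated walks yield one event per commanded placement in the GAP", {
  cmd <- gait_preset("pd_table2")
  sim <- generate_gait(cmd, seed = 6)
  a <- analyze_gait(sim$sequence)
  w <- a$window
  truth <- sim$truth$steps
  expected <- truth[truth$contact_time >= w$entry_time &
                      truth$contact_time <= w$exit_time, ]
  got <- a$events
  expect_equal(nrow(got), nrow(expected))
  expect_equal(got$side, expected$side)
  expect_true(all(abs(got$contact_time - expected$contact_time) <= 0.02))
  expect_true(all(abs(got$z - expected$z) <= 0.01))
})

test_that("standing and single-sided inputs segment sensibly", {
  tt <- seq(0, 4, by = 0.02)
  n <- length(tt)
  js <- stats::setNames(rep(list(cbind(0, 1, 3)[rep(1, n), ]), 25),
                        kinect_joints())
  js$AnkleLeft <- cbind(0.1, 0.1, 3)[rep(1, n), ]
  js$AnkleRight <- cbind(-0.1, 0.1, 3)[rep(1, n), ]
  u <- skeleton_sequence(tt, js)
  attr(u, "rate_hz") <- 50
  class(u) <- c("uniform_skeleton", class(u))
  window <- structure(list(entry_index = 1L, exit_index = n,
                           entry_time = 0, exit_time = 4,
                           gap_start_m = 99, gap_end_m = 0),
                      class = "gap_window")
  bin <- function(j) clean_activity(binarize_ankle(joint_xyz(u, j)[, "z"], 50))
  ev <- extract_steps(bin("AnkleLeft"), bin("AnkleRight"), u, window)
  expect_lte(sum(ev$side == "left"), 1)
  expect_lte(sum(ev$side == "right"), 1)

  # oscillating left ankle only: right stays planted
  js$AnkleLeft <- cbind(0.1, 0.1, 3 - 0.3 * sin(2 * pi * tt))
  u2 <- skeleton_sequence(tt, js)
  attr(u2, "rate_hz") <- 50
  class(u2) <- c("uniform_skeleton", class(u2))
  bin2 <- function(j) clean_activity(binarize_ankle(joint_xyz(u2, j)[, "z"], 50))
  ev2 <- extract_steps(bin2("AnkleLeft"), bin2("AnkleRight"), u2, window)
  expect_gt(sum(ev2$side == "left"), 1)
  expect_lte(sum(ev2$side == "right"), 1)
})

test_that("boundary-clipped steps are excluded from the complete set", {
  ev <- data.frame(side = c("left", "right", "left", "right"),
                   contact_time = c(1.0, 1.5, 2.0, 2.5),
                   liftoff_time = c(1.8, 2.3, 2.8, 3.3),
                   x = 0, z = 4:1, start_index = 1:4, end_index = 2:5,
                   complete = TRUE)
  w <- structure(list(entry_time = 1.2, exit_time = 3.0), class = "gap_window")
  out <- exclude_boundary_steps(ev, w)
  expect_equal(out$complete, c(FALSE, TRUE, TRUE, FALSE))
  w2 <- structure(list(entry_time = 0.5, exit_time = 3.5), class = "gap_window")
  expect_true(all(exclude_boundary_steps(ev, w2)$complete))
})

test_that("a placement just outside the start line drops one event", {
  cmd <- gait_preset("ps_table2", noise_sd = 0.001)
  sim <- generate_gait(cmd, seed = 8)
  a <- analyze_gait(sim$sequence)
  # move the window entry just past the first complete contact: exactly one
  # event flips to incomplete
  first <- min(a$events$contact_time[a$events$complete])
  w2 <- a$window
  w2$entry_time <- first + 0.01
  again <- exclude_boundary_steps(a$events, w2)
  expect_equal(sum(a$events$complete) - sum(again$complete), 1L)
})

test_that("event counts and timings are stable under 3 mm ankle noise", {
  cmd <- gait_preset("pd_table2", noise_sd = 0)
  ref <- analyze_gait(generate_gait(cmd, seed = 1)$sequence)
  ref_ev <- ref$events[ref$events$complete, ]
  for (seed in 1:30) {
    noisy <- generate_gait(gait_preset("pd_table2", noise_sd = 0.003),
                           seed = seed)
    a <- analyze_gait(noisy$sequence)
    ev <- a$events[a$events$complete, ]
    common <- min(nrow(ev), nrow(ref_ev))
    expect_lte(abs(nrow(ev) - nrow(ref_ev)), 1)
    # match events by nearest contact; timing within one frame
    for (i in seq_len(nrow(ev))) {
      d <- min(abs(ref_ev$contact_time - ev$contact_time[i]))
      expect_lte(d, 0.02 + 1e-9)
    }
  }
})
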