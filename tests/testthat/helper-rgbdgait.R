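# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles are written as plainly as possible (explicit loops, textbook
# formulas) and never call the implementation they check.

# minimal skeleton with every joint glued to a single trajectory
make_seq <- function(time, xyz, joints = kinect_joints()) {
  js <- stats::setNames(rep(list(xyz), length(joints)), joints)
  skeleton_sequence(time, js)
}

# random valid skeleton sequence for round-trip properties
random_seq <- function(n = 20, with_state = FALSE) {
  time <- cumsum(runif(n, 0.02, 0.05))
  js <- lapply(kinect_joints(), function(j) {
    matrix(rnorm(n * 3, 0, 2), n, 3)
  })
  names(js) <- kinect_joints()
  st <- NULL
  if (with_state) {
    st <- lapply(js, function(m) {
      sample(c("tracked", "inferred"), n, replace = TRUE)
    })
  }
  skeleton_sequence(time, js, st)
}

# patient-range admissible command sampler used by the recovery properties
draw_command <- function(...) {
  repeat {
    L <- runif(2, 0.25, 0.60)
    Tm <- runif(2, 0.5, 0.8)
    if ((sum(L) / sum(Tm)) > 0.95) next
    st <- runif(2, 58, 80)
    cmd <- try(gait_command(L[1], L[2], Tm[1], Tm[2], st[1], st[2],
                            step_width_left = runif(1, 0.08, 0.22),
                            step_width_right = runif(1, 0.08, 0.22),
                            ml_sway_amp = runif(1, 0.015, 0.05),
                            v_sway_amp = runif(1, 0.01, 0.025), ...),
               silent = TRUE)
    if (!inherits(cmd, "try-error")) return(cmd)
  }
}

recovery_errors <- function(sim, analysis) {
  p <- analysis$params
  tp <- sim$truth$params
  sides <- c("left", "right")
  c(step_length = max(abs(p$per_side$step_length - tp$step_length[sides])),
    cadence = abs(p$overall$cadence - tp$cadence),
    stance_pct = max(abs(p$per_side$stance_pct - tp$stance_pct[sides])),
    double_support_s = max(abs(p$per_side$double_support_s -
                                 tp$double_support_s)),
    step_width = max(abs(p$per_side$step_width - tp$step_width[sides])),
    ml_sway = abs(p$overall$ml_sway - tp$ml_sway),
    v_sway = abs(p$overall$v_sway - tp$v_sway))
}

recovery_tol <- c(step_length = 0.02, cadence = 2, stance_pct = 2,
                  double_support_s = 0.04, step_width = 0.02,
                  ml_sway = 0.01, v_sway = 0.01)

# ---- oracles ---------------------------------------------------------------

# debouncing oracle: repeatedly flip the shortest run (first of ties) below
# the minimum length until none remain, element by element
oracle_clean <- function(a, min_frames) {
  repeat {
    runs <- list()
    i <- 1
    while (i <= length(a)) {
      j <- i
      while (j < length(a) && a[j + 1] == a[i]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    }
    if (length(runs) <= 1) break
    lens <- vapply(runs, function(r) r[2] - r[1] + 1, 0)
    short <- which(lens < min_frames)
    if (length(short) == 0) break
    k <- short[which.min(lens[short])]
    r <- runs[[k]]
    a[r[1]:r[2]] <- 1L - a[r[1]:r[2]]
  }
  a
}

# run scanner: stationary runs of a binary array as start/end frame indices
oracle_runs <- function(a) {
  out <- NULL
  i <- 1
  while (i <= length(a)) {
    j <- i
    while (j < length(a) && a[j + 1] == a[i]) j <- j + 1
    if (a[i] == 0) out <- rbind(out, c(i, j))
    i <- j + 1
  }
  out
}

# exact paired Wilcoxon p by enumerating all 2^n sign assignments
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  vs <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[1:n]
    vs[mask + 1] <- sum(r[signs == 1])
  }
  mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-12)
}

# ICC(2,1) from explicit sums of squares (textbook two-way layout)
oracle_icc21 <- function(a, b) {
  m <- cbind(a, b)
  n <- nrow(m)
  k <- 2
  grand <- mean(m)
  ssr <- ssc <- sse <- 0
  for (i in 1:n) ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  for (j in 1:k) ssc <- ssc + n * (mean(m[, j]) - grand)^2
  for (i in 1:n) for (j in 1:k) {
    sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  unname((msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse)))
}

# mixed two-way ANOVA (between group, within system) from explicit cell and
# marginal means; returns F and partial eta squared per effect
oracle_mixed_anova <- function(subject, group, y1, y2) {
  n <- length(subject)
  grand <- mean(c(y1, y2))
  groups <- unique(group)
  subj_mean <- (y1 + y2) / 2
  # between stratum
  ss_group <- 0
  for (g in groups) {
    idx <- group == g
    ss_group <- ss_group + 2 * sum(idx) * (mean(subj_mean[idx]) - grand)^2
  }
  ss_subj_within <- 0
  for (i in 1:n) {
    g <- group[i]
    ss_subj_within <- ss_subj_within +
      2 * (subj_mean[i] - mean(subj_mean[group == g]))^2
  }
  # within stratum
  sys_mean <- c(mean(y1), mean(y2))
  ss_system <- n * sum((sys_mean - grand)^2)
  ss_gs <- 0
  for (g in groups) {
    idx <- group == g
    for (s in 1:2) {
      cell <- mean(if (s == 1) y1[idx] else y2[idx])
      ss_gs <- ss_gs + sum(idx) *
        (cell - mean(subj_mean[idx]) - sys_mean[s] + grand)^2
    }
  }
  ss_tot <- sum((c(y1, y2) - grand)^2)
  ss_err_within <- ss_tot - ss_group - ss_subj_within - ss_system - ss_gs
  df_g <- length(groups) - 1
  df_sw <- n - length(groups)
  df_s <- 1
  df_gs <- df_g
  df_ew <- df_sw
  list(
    F = c(Group = (ss_group / df_g) / (ss_subj_within / df_sw),
          System = (ss_system / df_s) / (ss_err_within / df_ew),
          GxS = (ss_gs / df_gs) / (ss_err_within / df_ew)),
    eta = c(Group = ss_group / (ss_group + ss_subj_within),
            System = ss_system / (ss_system + ss_err_within),
            GxS = ss_gs / (ss_gs + ss_err_within)))
}

# synthetic 21-subject two-system paired table in the long format
synth_paired_table <- function(seed = 1, n_ps = 11, n_pd = 10,
                               system_bias = 0, group_shift = 0) {
  set.seed(seed)
  pars <- c("step_length", "stance_pct", "double_support_s", "mean_velocity",
            "cadence", "step_width", "ml_sway", "v_sway")
  base <- c(0.45, 67, 0.5, 0.75, 97, 0.2, 0.09, 0.05)
  rows <- NULL
  subjects <- c(paste0("PS", seq_len(n_ps)), paste0("PD", seq_len(n_pd)))
  groups <- c(rep("PS", n_ps), rep("PD", n_pd))
  for (i in seq_along(subjects)) {
    for (k in seq_along(pars)) {
      true <- base[k] * (1 + rnorm(1, 0, 0.15)) +
        (groups[i] == "PD") * group_shift * base[k]
      rows <- rbind(rows,
                    data.frame(subject = subjects[i], group = groups[i],
                               parameter = pars[k], system = "RGBD",
                               value = true * (1 + rnorm(1, 0, 0.03))),
                    data.frame(subject = subjects[i], group = groups[i],
                               parameter = pars[k], system = "3DGA",
                               value = true * (1 + rnorm(1, 0, 0.03)) +
                                 system_bias * base[k]))
    }
  }
  read_paired_table(rows)
}
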