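#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' Tests a sample against a normal distribution with mean and SD estimated
#' from the sample. Because the parameters are estimated, the Lilliefors
#' correction is used by default (a naive KS test against the fitted normal
#' would be badly conservative); set `lilliefors = FALSE` for the naive
#' variant.
#'
#' @param x Numeric sample, `n >= 5`.
#' @param lilliefors Use Lilliefors critical values (default `TRUE`).
#' @return List with `statistic` and `p.value`.
#' @export
ks_normality <- function(x, lilliefors = TRUE) {
  x <- x[is.finite(x)]
  if (length(x) < 5L) {
    stop("need at least 5 observations, got ", length(x), call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate input: all values identical", call. = FALSE)
  }
  if (lilliefors) {
    res <- nortest::lillie.test(x)
  } else {
    res <- suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Paired Wilcoxon signed-rank test
#'
#' Compares paired measurements from two systems. Zero differences are
#' dropped (Wilcoxon's original treatment); the exact null distribution is
#' used for up to 25 nonzero untied differences, otherwise the normal
#' approximation with continuity correction.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return List with `statistic` (V), `p.value`, `n` (nonzero pairs),
#'   `exact` (whether the exact distribution was used).
#' @export
wilcoxon_paired <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("no variation: all paired differences are zero", call. = FALSE)
  }
  exact <- n <= 25L && !anyDuplicated(abs(d))
  res <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p.value = res$p.value,
       n = n, exact = exact)
}

#' Spearman rank-order correlation
#'
#' Rank correlation with average ranks for ties; the p-value comes from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param a,b Numeric vectors of equal length, `n >= 4`.
#' @return List with `rho` and `p.value`.
#' @export
spearman_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 4L) stop("need at least 4 pairs, got ", n, call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  rho <- stats::cor(rank(a), rank(b))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, p.value = p)
}

# Two-way mean squares for n subjects x k raters, from the classic
# ANOVA decomposition (rows = subjects, columns = raters/systems).
twoway_ms <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation between two measurement systems
#'
#' Absolute-agreement ICC computed from the two-way ANOVA mean squares of
#' the subjects-by-systems table. The default form is ICC(2,1) (two-way
#' random effects, absolute agreement, single measurement):
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' Forms ICC(3,1) (two-way mixed, consistency) and ICC(2,k) (average of the
#' k measurements) are available via `form`.
#'
#' @param a,b Paired numeric vectors (system A and system B), `n >= 5`.
#' @param form `"ICC2_1"` (default), `"ICC3_1"` or `"ICC2_k"`.
#' @return The ICC value (scalar).
#' @export
icc_agreement <- function(a, b, form = c("ICC2_1", "ICC3_1", "ICC2_k")) {
  form <- match.arg(form)
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  m <- cbind(a[ok], b[ok])
  if (nrow(m) < 5L) {
    stop("need at least 5 paired observations", call. = FALSE)
  }
  if (sum((m - mean(m))^2) == 0) {
    stop("degenerate input: zero total variance", call. = FALSE)
  }
  ms <- twoway_ms(m)
  with(ms, switch(form,
    ICC2_1 = (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse)),
    ICC3_1 = (msr - mse) / (msr + (k - 1) * mse),
    ICC2_k = (msr - mse) / (msr + (msc - mse) / n)))
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b` against pair means, with the mean difference (bias)
#' and the 95% limits of agreement `mean +/- 1.96 SD`.
#'
#' @param a,b Paired numeric vectors, `n >= 2`.
#' @return List with `mean_diff`, `sd_diff`, `loa_low`, `loa_high` and a
#'   `points` data frame (`mean`, `diff`) for plotting.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  list(mean_diff = md, sd_diff = sdd,
       loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
       points = data.frame(mean = (a + b) / 2, diff = d))
}

#' Read or validate a paired-measurements table
#'
#' Long format with columns `subject`, `group`, `parameter`, `system`,
#' `value`: one value per subject x parameter x system (per-subject trial
#' means, sides already averaged where applicable).
#'
#' @param x A data frame in that shape, or a path to a CSV file.
#' @return The validated data frame (class `paired_table`).
#' @export
read_paired_table <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x)
  need <- c("subject", "group", "parameter", "system", "value")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("paired table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(x$value))) stop("non-finite values", call. = FALSE)
  dup <- duplicated(x[c("subject", "parameter", "system")])
  if (any(dup)) {
    stop("duplicate rows for subject/parameter/system: ",
         paste(utils::head(x$subject[dup]), collapse = ", "), call. = FALSE)
  }
  systems <- sort(unique(x$system))
  if (length(systems) != 2L) {
    stop("expected exactly 2 systems, found ", length(systems), call. = FALSE)
  }
  class(x) <- c("paired_table", "data.frame")
  x
}

# subjects-by-systems wide slice of one parameter; errors on missing cells
paired_wide <- function(table, parameter) {
  sub <- table[table$parameter == parameter, , drop = FALSE]
  systems <- sort(unique(table$system))
  wide <- stats::reshape(sub[c("subject", "group", "system", "value")],
                         idvar = c("subject", "group"),
                         timevar = "system", direction = "wide")
  vals <- wide[paste0("value.", systems)]
  if (any(!stats::complete.cases(vals))) {
    bad <- wide$subject[!stats::complete.cases(vals)]
    stop("subject(s) missing one system for '", parameter, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  names(vals) <- systems
  cbind(wide[c("subject", "group")], vals)
}

#' Mixed repeated-measures ANOVA: within-subject System, between-subject Group
#'
#' Two-way mixed ANOVA for one parameter of a paired table: measurement
#' System (2 levels) is the within-subject factor, patient Group (2 levels)
#' the between-subject factor. Returns F, p and partial eta squared
#' (`SS_effect / (SS_effect + SS_error_of_that_effect)`) for Group, System
#' and the Group x System interaction. Fitting uses `stats::aov` with a
#' subject error stratum.
#'
#' @param table A [read_paired_table()] data frame.
#' @param parameter Which parameter to analyze.
#' @return An `anova_result` data frame with columns `effect`, `df1`, `df2`,
#'   `F`, `p.value`, `partial_eta_sq`.
#' @export
rm_anova <- function(table, parameter) {
  wide <- paired_wide(table, parameter)
  groups <- unique(wide$group)
  if (length(groups) != 2L) {
    stop("expected exactly 2 groups, found ", length(groups), call. = FALSE)
  }
  cnt <- table(wide$group)
  if (any(cnt < 2L)) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  systems <- setdiff(names(wide), c("subject", "group"))
  long <- data.frame(
    subject = factor(rep(wide$subject, 2L)),
    group = factor(rep(wide$group, 2L)),
    system = factor(rep(systems, each = nrow(wide))),
    value = c(wide[[systems[1L]]], wide[[systems[2L]]]))
  fit <- stats::aov(value ~ group * system + Error(subject), data = long)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1L]])
  within <- as.data.frame(sm[["Error: Within"]][[1L]])
  row_of <- function(tab, label) {
    i <- which(trimws(rownames(tab)) == label)
    tab[i, , drop = FALSE]
  }
  mk <- function(tab, label, err_label = "Residuals") {
    eff <- row_of(tab, label)
    err <- row_of(tab, err_label)
    f <- eff[["F value"]]
    p <- eff[["Pr(>F)"]]
    eta <- eff[["Sum Sq"]] / (eff[["Sum Sq"]] + err[["Sum Sq"]])
    if (eff[["Sum Sq"]] <= 1e-12 * max(1, abs(mean(long$value)))) {
      # no effect variance (e.g. identical values everywhere): F is 0, not
      # the 0/0 NaN the raw table carries
      f <- 0
      p <- 1
      eta <- 0
    }
    data.frame(effect = label,
               df1 = eff[["Df"]], df2 = err[["Df"]],
               F = f, p.value = p, partial_eta_sq = eta)
  }
  out <- rbind(mk(between, "group"),
               mk(within, "system"),
               mk(within, "group:system"))
  out$effect <- c("Group", "System", "Group x System")
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Per-group median summaries for every parameter and system
#'
#' Median and first/third quartiles of each parameter, split by patient
#' group and measurement system — the per-cohort descriptive companion to
#' [agreement_table()].
#'
#' @param table A [read_paired_table()] data frame.
#' @return A data frame with one row per parameter x group x system and
#'   columns `median`, `q1`, `q3`.
#' @export
group_summary_table <- function(table) {
  rows <- expand.grid(parameter = unique(table$parameter),
                      group = unique(table$group),
                      system = unique(table$system),
                      stringsAsFactors = FALSE)
  qs <- t(apply(rows, 1L, function(r) {
    v <- table$value[table$parameter == r[["parameter"]] &
                       table$group == r[["group"]] &
                       table$system == r[["system"]]]
    stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE)
  }))
  rows$median <- qs[, 1L]
  rows$q1 <- qs[, 2L]
  rows$q3 <- qs[, 3L]
  rows
}

#' System-agreement summary for every parameter of a paired table
#'
#' For each parameter: median and quartiles per system, paired Wilcoxon p,
#' Spearman rho and p, ICC and Bland-Altman bias with limits of agreement —
#' the usual method-comparison battery for two measurement systems.
#'
#' @param table A [read_paired_table()] data frame.
#' @param icc_form ICC variant, see [icc_agreement()].
#' @return An `agreement_result` data frame, one row per parameter.
#' @export
agreement_table <- function(table, icc_form = "ICC2_1") {
  systems <- sort(unique(table$system))
  rows <- lapply(unique(table$parameter), function(p) {
    wide <- paired_wide(table, p)
    a <- wide[[systems[1L]]]
    b <- wide[[systems[2L]]]
    qa <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
    qb <- stats::quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
    wil <- tryCatch(wilcoxon_paired(a, b)$p.value, error = function(e) NA_real_)
    sp <- spearman_rank(a, b)
    ba <- bland_altman(a, b)
    data.frame(parameter = p,
               median_A = qa[2L], q1_A = qa[1L], q3_A = qa[3L],
               median_B = qb[2L], q1_B = qb[1L], q3_B = qb[3L],
               wilcoxon_p = wil, spearman_rho = sp$rho, spearman_p = sp$p.value,
               icc = icc_agreement(a, b, icc_form),
               mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
               loa_low = ba$loa_low, loa_high = ba$loa_high)
  })
  out <- do.call(rbind, rows)
  attr(out, "systems") <- systems
  rownames(out) <- NULL
  class(out) <- c("agreement_result", "data.frame")
  out
}
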