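test_that("normality screening behaves at its edges", {
  expect_error(ks_normality(c(1, 2, 3)), "at least 5")
  expect_error(ks_normality(rep(2, 10)), "degenerate")
  set.seed(41)
  bimodal <- c(rnorm(100, -3), rnorm(100, 3))
  expect_lt(ks_normality(bimodal)$p.value, 0.01)
  # the naive variant exists and is more conservative on normal data
  x <- rnorm(50)
  expect_gte(ks_normality(x, lilliefors = FALSE)$p.value,
             ks_normality(x)$p.value - 1e-9)
})

test_that("paired Wilcoxon matches exhaustive sign enumeration", {
  set.seed(42)
  for (n in c(6, 8, 10)) {
    for (rep in 1:20) {
      a <- round(rnorm(n), 3)
      b <- round(rnorm(n), 3)
      d <- a - b
      if (any(d == 0) || anyDuplicated(abs(d[d != 0]))) next
      got <- wilcoxon_paired(a, b)
      expect_true(got$exact)
      expect_equal(got$p.value, oracle_wilcoxon_p(d), tolerance = 1e-12)
    }
  }
  expect_error(wilcoxon_paired(1:5, 1:5), "no variation")
  a <- rnorm(10)
  expect_lt(wilcoxon_paired(a, a + 5)$p.value, 0.05)
})

test_that("Spearman correlation uses midranks and the t approximation", {
  a <- c(1, 4, 9, 16, 25, 36)
  expect_equal(spearman_rank(a, exp(a))$rho, 1)
  expect_equal(spearman_rank(a, -a)$rho, -1)
  expect_error(spearman_rank(1:3, 1:3), "at least 4")
  expect_error(spearman_rank(rep(1, 6), 1:6), "undefined")
  # ties: rho equals the correlation of explicitly computed midranks
  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6, 6)
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
  }
  expect_equal(spearman_rank(x, y)$rho, stats::cor(midrank(x), midrank(y)))
  # invariance under shared monotone maps
  set.seed(43)
  p <- rnorm(20)
  q <- p + rnorm(20, 0, 0.5)
  expect_equal(spearman_rank(exp(p), exp(q))$rho, spearman_rank(p, q)$rho)
})

test_that("ICC(2,1) equals the explicit sums-of-squares oracle", {
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  expect_equal(icc_agreement(a, b), oracle_icc21(a, b), tolerance = 1e-12)
  set.seed(44)
  for (i in 1:20) {
    x <- rnorm(8, 10, 3)
    y <- x + rnorm(8, 0.5, 1)
    expect_equal(icc_agreement(x, y), oracle_icc21(x, y), tolerance = 1e-12)
  }
  z <- rnorm(12)
  expect_equal(icc_agreement(z, z), 1)
  set.seed(45)
  expect_lt(abs(icc_agreement(rnorm(200), rnorm(200))), 0.15)
  expect_error(icc_agreement(rep(1, 6), rep(1, 6)), "degenerate")
  expect_error(icc_agreement(1:4, 2:5), "at least 5")
  # shared affine rescaling leaves ICC unchanged
  x <- rnorm(15)
  y <- x + rnorm(15, 0, 0.4)
  expect_equal(icc_agreement(3 * x + 2, 3 * y + 2), icc_agreement(x, y),
               tolerance = 1e-9)
  # consistency form ignores a constant offset, agreement form does not
  expect_gt(icc_agreement(x, x + 1, form = "ICC3_1"),
            icc_agreement(x, x + 1, form = "ICC2_1"))
})

test_that("Bland-Altman bias and limits follow their definitions", {
  a <- rnorm(10)
  ba <- bland_altman(a, a)
  expect_equal(ba$mean_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))
  ba2 <- bland_altman(a, a - 1)
  expect_equal(ba2$mean_diff, 1)
  expect_equal(ba2$sd_diff, 0)
  set.seed(46)
  x <- rnorm(1000)
  y <- x + rnorm(1000, 0, 0.2)
  ba3 <- bland_altman(x, y)
  inside <- mean(ba3$points$diff >= ba3$loa_low &
                   ba3$points$diff <= ba3$loa_high)
  expect_lt(abs(inside - 0.95), 0.02)
  expect_equal(ba3$points$mean, (x + y) / 2)
})

test_that("the mixed ANOVA matches the explicit sums-of-squares oracle", {
  tab <- data.frame(
    subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("PD", "PD", "PS", "PS"), each = 2),
    parameter = "step_length",
    system = rep(c("A", "B"), 4),
    value = c(0.42, 0.45, 0.38, 0.36, 0.55, 0.52, 0.61, 0.64))
  res <- rm_anova(read_paired_table(tab), "step_length")
  wide <- data.frame(subject = c("s1", "s2", "s3", "s4"),
                     group = c("PD", "PD", "PS", "PS"),
                     y1 = c(0.42, 0.38, 0.55, 0.61),
                     y2 = c(0.45, 0.36, 0.52, 0.64))
  orc <- oracle_mixed_anova(wide$subject, wide$group, wide$y1, wide$y2)
  expect_equal(res$F, unname(orc$F), tolerance = 1e-10)
  expect_equal(res$partial_eta_sq, unname(orc$eta), tolerance = 1e-10)
  # partial eta squared identity from F and the dfs
  expect_equal(res$partial_eta_sq,
               res$F * res$df1 / (res$F * res$df1 + res$df2),
               tolerance = 1e-10)
})

test_that("the mixed ANOVA separates group and system effects", {
  set.seed(47)
  n <- 10
  subj <- c(paste0("a", 1:n), paste0("b", 1:n))
  grp <- rep(c("PD", "PS"), each = n)
  base <- rnorm(2 * n, 0, 0.3) + ifelse(grp == "PS", 1.0, 0)
  tab <- data.frame(subject = rep(subj, 2), group = rep(grp, 2),
                    parameter = "p",
                    system = rep(c("A", "B"), each = 2 * n),
                    value = c(base + rnorm(2 * n, 0, 0.1),
                              base + rnorm(2 * n, 0, 0.1)))
  res <- rm_anova(read_paired_table(tab), "p")
  expect_lt(res$p.value[res$effect == "Group"], 0.01)
  expect_lt(res$F[res$effect == "System"], 2)

  # identical values everywhere: all F are zero
  tab$value <- 1
  res0 <- rm_anova(read_paired_table(tab), "p")
  expect_equal(res0$F, c(0, 0, 0))
})

test_that("paired tables are validated row by row", {
  tab <- data.frame(subject = c("s1", "s1", "s2"), group = "PD",
                    parameter = "p", system = c("A", "B", "A"),
                    value = c(1, 2, 3))
  expect_error(rm_anova(read_paired_table(tab), "p"), "s2")
  expect_error(read_paired_table(data.frame(subject = 1, value = 2)),
               "lacks column")
  tab2 <- rbind(tab, data.frame(subject = "s1", group = "PD", parameter = "p",
                                system = "A", value = 9))
  expect_error(read_paired_table(tab2), "duplicate")
})

test_that("the agreement battery summarizes every parameter", {
  tab <- synth_paired_table(seed = 2)
  res <- agreement_table(tab)
  expect_equal(nrow(res), 8)
  expect_true(all(res$icc > 0.8)) # 3% measurement scatter on both systems
  expect_true(all(res$spearman_rho > 0.7))
  expect_true(all(is.finite(res$wilcoxon_p)))
  expect_equal(res$loa_high - res$mean_diff, 1.96 * res$sd_diff)
})
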