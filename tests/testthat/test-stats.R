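test_that("Pearson regression matches closed-form arithmetic", {
  out <- pearson_regression(c(1, 2, 3), c(1, 2, 4))
  expect_equal(out$slope, 1.5)
  expect_equal(out$intercept, -2 / 3)   # ybar - 1.5 * xbar = 7/3 - 3
  expect_equal(out$r.squared, 27 / 28)
  exact <- pearson_regression(1:10, 2 * (1:10) + 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r.squared, 1)
  expect_error(pearson_regression(rep(1, 5), 1:5), "variance")
  # independent variables: r^2 near zero
  set.seed(3)
  expect_lt(pearson_regression(rnorm(1000), rnorm(1000))$r.squared, 0.02)
})

test_that("Bland-Altman differences behave as defined", {
  x <- c(1, 2, 3, 4)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(unname(ba$loa), c(0, 0))
  # exact linear relation is fully removed by regression correction
  ba2 <- bland_altman(x, 2 * x, regression_correct = TRUE)
  expect_equal(ba2$mean_diff, 0, tolerance = 1e-12)
  expect_equal(ba2$sd_diff, 0, tolerance = 1e-12)
  ba3 <- bland_altman(x, c(1.1, 2.2, 2.9, 4.3))
  expect_equal(unname(ba3$loa),
               ba3$mean_diff + c(-1.96, 1.96) * ba3$sd_diff)
  expect_error(bland_altman(1:4, 1:5), "length")
})

test_that("the Pitman-Morgan test flags the noisier method pair", {
  set.seed(21)
  n <- 500
  base <- rnorm(n)
  d1 <- base + rnorm(n, sd = 0.1)
  d2 <- base + rnorm(n, sd = 0.2)   # double added noise
  pm <- pitman_morgan_test(d2, d1)
  expect_gt(pm$var_ratio, 1)
  expect_lt(pm$p.value, 0.05)
  # symmetric null: equal variances are not flagged
  pm0 <- pitman_morgan_test(base + rnorm(n, sd = 0.1),
                            base + rnorm(n, sd = 0.1))
  expect_gt(pm0$p.value, 0.01)
})

test_that("group comparisons separate the configured contrasts", {
  mk <- function(vals, grp) data.frame(
    subject = sprintf("%s%02d", grp, seq_along(vals)), group = grp,
    region = "pcc", metric = "DVR_L", value = vals)
  set.seed(8)
  tab <- rbind(mk(rnorm(16, 1.2, 0.15), "CTL"), mk(rnorm(19, 2.1, 0.15), "eAD"))
  out <- group_test(tab, "pcc", "DVR_L")
  expect_lt(out$p.value, 1e-5)
  expect_lt(out$ctl_mean, out$ead_mean)
  # identical distributions with equal means: p = 1 at exact equality
  same <- rbind(mk(c(1, 1.1, 1.2, 1.3), "CTL"), mk(c(1, 1.1, 1.2, 1.3), "eAD"))
  expect_equal(group_test(same, "pcc", "DVR_L")$p.value, 1)
  expect_error(group_test(mk(1, "CTL"), "pcc", "DVR_L"), "at least 2")
})

test_that("Welch p agrees with a permutation oracle at moderate effects", {
  set.seed(17)
  a <- rnorm(10, 0, 1); b <- rnorm(10, 0.8, 1)
  p_welch <- t.test(a, b)$p.value
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  perm <- replicate(4000, {
    s <- sample(20, 10)
    abs(mean(pooled[s]) - mean(pooled[-s]))
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_perm - p_welch), 0.05)
})

test_that("paired region-vs-PCC contrasts work within a group", {
  subj <- sprintf("S%02d", 1:6)
  tab <- rbind(
    data.frame(subject = subj, group = "eAD", region = "frontal_l",
               metric = "DVR_L", value = c(2.0, 2.1, 1.9, 2.2, 2.0, 2.05)),
    data.frame(subject = subj, group = "eAD", region = "pcc",
               metric = "DVR_L", value = c(2.4, 2.5, 2.2, 2.6, 2.35, 2.5)))
  out <- paired_vs_pcc(tab, "frontal_l", "DVR_L", "eAD")
  expect_lt(out$mean_diff, 0)
  expect_lt(out$p.value, 0.01)
  expect_equal(out$n, 6L)
})

test_that("ROC analysis matches brute-force enumeration on small instances", {
  r <- roc_analysis(c(1, 2, 3, 4), c("CTL", "CTL", "eAD", "eAD"))
  expect_equal(r$auc, 1)
  expect_gt(r$threshold, 2)
  expect_lte(r$threshold, 3)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # perfectly separated wider example: threshold between class extremes
  r2 <- roc_analysis(c(1, 1.2, 1.4, 2.2, 2.6, 3), rep(c("CTL", "eAD"), each = 3))
  expect_equal(r2$auc, 1)
  expect_gt(r2$threshold, 1.4)
  expect_lte(r2$threshold, 2.2)
  expect_error(roc_analysis(1:4, rep("CTL", 4)), "both classes")
})

test_that("trapezoid AUC equals all-pairs concordance on random instances", {
  set.seed(33)
  for (i in 1:30) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    # rounding induces ties both within and across groups
    v <- round(c(rnorm(n1, 0), rnorm(n2, 0.6)), 1)
    g <- c(rep("CTL", n1), rep("eAD", n2))
    r <- roc_analysis(v, g)
    expect_equal(r$auc, tt_concordance_auc(v, g), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    r_t <- roc_analysis(exp(v), g)
    expect_equal(r_t$auc, r$auc, tolerance = 1e-12)
  }
  # identical class distributions: AUC near 1/2
  set.seed(12)
  v0 <- rnorm(400)
  g0 <- rep(c("CTL", "eAD"), each = 200)
  expect_lt(abs(roc_analysis(v0, g0)$auc - 0.5), 0.08)
})

test_that("empirical AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  v <- c(rnorm(30, 0), rnorm(25, 0.9))
  g <- c(rep("CTL", 30), rep("eAD", 25))
  ours <- roc_analysis(v, g)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(g, v, levels = c("CTL", "eAD"),
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})
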