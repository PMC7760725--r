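#' Pearson regression between two metrics
#'
#' Ordinary least-squares regression of `y` on `x` with the Pearson
#' r-squared, as used to compare regional DVR and SUVR values for linearity.
#'
#' @param x,y paired finite values, at least 3.
#' @return List with `slope`, `intercept`, `r.squared`, `p.value` (of the
#'   correlation), `n`.
#' @export
#' @examples
#' pearson_regression(1:3, c(1, 2, 4))   # slope 1.5, r^2 = 27/28
pearson_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be the same length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 finite pairs are required")
  if (var(x) <= 0) stop("x has zero variance")
  fit <- lsfit(x, y)
  ct <- stats::cor.test(x, y)
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       r.squared = unname(ct$estimate)^2,
       p.value = ct$p.value, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Computes the mean difference, SD of differences and 95% limits of
#' agreement (mean +/- 1.96 SD) for a pair of metrics.  With
#' `regression_correct = TRUE` the second metric is first mapped onto the
#' first's scale through the inverse of the fitted `y`-on-`x` line
#' (`y' = (y - intercept)/slope`), so a purely linear relationship leaves no
#' systematic difference — the "plots after correction with equations of
#' linear regression" convention.
#'
#' @param x,y paired values (at least 3); `x` is the reference scale.
#' @param regression_correct map `y` onto `x`'s scale before differencing.
#' @return An object of class `bland_altman`: list with `mean_diff`,
#'   `sd_diff`, `loa` (limits of agreement), `differences`, `means`,
#'   `correction` (slope/intercept used, or NULL) and `n`.
#' @export
bland_altman <- function(x, y, regression_correct = FALSE) {
  if (length(x) != length(y)) stop("x and y must be the same length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 finite pairs are required")
  correction <- NULL
  if (regression_correct) {
    fit <- lsfit(x, y)
    b <- unname(fit$coefficients[2L]); a <- unname(fit$coefficients[1L])
    if (abs(b) < 1e-12) stop("degenerate regression: slope ~ 0")
    y <- (y - a) / b
    correction <- c(slope = b, intercept = a)
  }
  d <- y - x
  m <- mean(d); s <- sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
                 differences = d, means = (x + y) / 2,
                 correction = correction, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman agreement (n = %d%s)\n  mean difference %.4f, SD %.4f, limits [%.4f, %.4f]\n",
    x$n, if (is.null(x$correction)) "" else ", regression-corrected",
    x$mean_diff, x$sd_diff, x$loa[1], x$loa[2]))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of methods",
                              ylab = "Difference", ...) {
  plot(x$means, x$differences, xlab = xlab, ylab = ylab, ...)
  abline(h = c(x$mean_diff, x$loa), lty = c(1, 2, 2))
  invisible(x)
}

#' Pitman-Morgan test for equality of correlated variances
#'
#' Compares the variances of two paired sets of differences (e.g. the
#' Bland-Altman differences of two method pairs computed on the same
#' subjects/regions).  The test exploits that `var(a) = var(b)` iff
#' `cor(a + b, a - b) = 0` for paired observations, giving a t-statistic
#' with `n - 2` degrees of freedom.
#'
#' @param a,b paired numeric vectors.
#' @return List with `statistic`, `p.value`, `df` and `var_ratio`
#'   (`var(a)/var(b)`).
#' @export
pitman_morgan_test <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) stop("at least 3 pairs are required")
  r <- cor(a + b, a - b)
  stat <- r * sqrt((n - 2) / (1 - r^2))
  list(statistic = stat, p.value = 2 * pt(-abs(stat), n - 2), df = n - 2,
       var_ratio = var(a) / var(b))
}

#' Group comparison of a regional metric
#'
#' Welch two-sample comparison of a metric in one region between the CTL and
#' eAD groups of a cohort table.
#'
#' @param table long table with columns `subject`, `group`, `region`,
#'   `metric`, `value`.
#' @param region region name.
#' @param metric metric name (e.g. `"DVR_L"`).
#' @return List with `ctl_mean`, `ctl_sd`, `ead_mean`, `ead_sd`, `p.value`,
#'   `n_ctl`, `n_ead`.
#' @export
group_test <- function(table, region, metric) {
  sub <- table[table$region == region & table$metric == metric, ]
  a <- sub$value[sub$group == "CTL"]
  b <- sub$value[sub$group == "eAD"]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 subjects with values in ", region)
  tt <- if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b))
    list(p.value = 1) else t.test(a, b)
  list(ctl_mean = mean(a), ctl_sd = sd(a),
       ead_mean = mean(b), ead_sd = sd(b),
       p.value = tt$p.value, n_ctl = length(a), n_ead = length(b))
}

#' Paired comparison of a region against the posterior cingulate
#'
#' Within-subject paired t-test of a region's metric values against the PCC
#' values of the same subjects, within one group.
#'
#' @inheritParams group_test
#' @param group `"CTL"` or `"eAD"`.
#' @return List with `mean_diff` (region minus PCC), `p.value`, `n`.
#' @export
paired_vs_pcc <- function(table, region, metric, group) {
  sub <- table[table$metric == metric & table$group == group, ]
  a <- sub[sub$region == region, c("subject", "value")]
  b <- sub[sub$region == "pcc", c("subject", "value")]
  m <- merge(a, b, by = "subject", suffixes = c("_region", "_pcc"))
  if (nrow(m) < 2L) stop("need at least 2 paired subjects")
  d <- m$value_region - m$value_pcc
  tt <- if (sd(d) == 0) list(p.value = if (mean(d) == 0) 1 else 0)
        else t.test(m$value_region, m$value_pcc, paired = TRUE)
  list(mean_diff = mean(d), p.value = tt$p.value, n = nrow(m))
}

#' ROC analysis with a Youden-optimal threshold
#'
#' Empirical ROC over all observed values as candidate thresholds (a subject
#' is called positive when its value is at or above the threshold), with the
#' area under the curve by the trapezoid rule and the optimal threshold
#' maximizing Youden's J (sensitivity + specificity - 1; ties resolved in
#' favour of the lowest threshold).
#'
#' @param values per-subject metric values.
#' @param groups factor/character vector of group labels, same length.
#' @param positive label of the positive (diseased) class, default `"eAD"`.
#' @return An object of class `roc_result`: list with `auc`, `threshold`,
#'   `sensitivity`, `specificity`, `youden`, and `points` (a data frame of
#'   threshold/FPR/TPR defining the curve).
#' @export
#' @examples
#' roc_analysis(c(1, 2, 3, 4), c("CTL", "CTL", "eAD", "eAD"))
roc_analysis <- function(values, groups, positive = "eAD") {
  if (length(values) != length(groups))
    stop("values and groups must be the same length")
  ok <- is.finite(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  is_pos <- groups == positive
  if (!any(is_pos) || all(is_pos))
    stop("both classes must be present")
  pos <- values[is_pos]; neg <- values[!is_pos]
  thr <- sort(unique(values))
  tpr <- vapply(thr, function(k) mean(pos >= k), numeric(1))
  fpr <- vapply(thr, function(k) mean(neg >= k), numeric(1))
  # close the curve at (0,0) and (1,1)
  pts <- data.frame(threshold = c(Inf, rev(thr), -Inf),
                    fpr = c(0, rev(fpr), 1), tpr = c(0, rev(tpr), 1))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  j <- tpr + (1 - fpr) - 1
  best <- which(j == max(j))
  best <- best[which.min(thr[best])]
  structure(list(auc = auc, threshold = thr[best],
                 sensitivity = tpr[best], specificity = 1 - fpr[best],
                 youden = j[best], points = pts,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.4f (n+ = %d, n- = %d); Youden threshold %.4g (sens %.3f, spec %.3f)\n",
    x$auc, x$n_pos, x$n_neg, x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, xlab = "False positive rate",
                            ylab = "True positive rate", type = "s", ...) {
  plot(x$points$fpr, x$points$tpr, xlab = xlab, ylab = ylab, type = type,
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}
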