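#' Area under the ROC curve
#'
#' Nonparametric AUC as the Mann-Whitney probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counting one
#' half. Computed from midranks, so it equals the exhaustive pair-counting
#' estimator exactly.
#'
#' @param scores numeric vector of finite scores (higher = more abnormal).
#' @param labels binary vector (logical, or 0/1) of true class membership,
#'   same length as `scores`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  m <- sum(labels); n <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

check_binary_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (anyNA(scores) || any(!is.finite(scores))) stop("scores must be finite")
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be binary (0/1 or logical)")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  labels
}

# DeLong structural components for one score vector: list(theta, v10, v01),
# where v10 has one entry per positive and v01 one per negative.
delong_components <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  list(theta = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' Paired comparison of two correlated AUCs (DeLong)
#'
#' Compares the AUCs of two scores measured on the same subjects using
#' DeLong's structural-components estimate of the covariance between the two
#' Mann-Whitney statistics. The reported AUCs equal [roc_auc()] on each
#' score.
#'
#' @param scores_a,scores_b numeric score vectors for the two methods, same
#'   subjects in the same order.
#' @param labels binary truth vector.
#' @param conf_level confidence level for the AUC intervals (default 0.95).
#' @return An object of class `roc_comparison`: list with `auc_a`, `auc_b`,
#'   `se_a`, `se_b`, `ci95_a`, `ci95_b`, `auc_diff` (a - b), `se_diff`, `z`,
#'   `p_value` (two-tailed normal) and `degenerate` (TRUE when the variance
#'   of the difference is zero, in which case `p_value = 1` with a warning).
#' @export
delong_paired_test <- function(scores_a, scores_b, labels, conf_level = 0.95) {
  labels <- check_binary_labels(scores_a, labels)
  if (length(scores_b) != length(scores_a)) {
    stop("scores_a and scores_b must cover the same subjects")
  }
  if (anyNA(scores_b) || any(!is.finite(scores_b))) stop("scores must be finite")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- ca$m; n <- ca$n
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_a <- s10[1, 1] / m + s01[1, 1] / n
  var_b <- s10[2, 2] / m + s01[2, 2] / n
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_a <- sqrt(max(0, var_a)); se_b <- sqrt(max(0, var_b))
  diff <- ca$theta - cb$theta
  degenerate <- var_diff <= .Machine$double.eps
  if (degenerate) {
    if (abs(diff) > 1e-12) {
      warning("zero DeLong variance with non-zero AUC difference")
    } else {
      warning("degenerate (zero-variance) AUC difference; p set to 1")
    }
    z <- 0; p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(auc_a = ca$theta, auc_b = cb$theta, se_a = se_a, se_b = se_b,
         ci95_a = pmin(1, pmax(0, ca$theta + c(-1, 1) * zq * se_a)),
         ci95_b = pmin(1, pmax(0, cb$theta + c(-1, 1) * zq * se_b)),
         auc_diff = diff, se_diff = sqrt(max(0, var_diff)), z = z,
         p_value = p, degenerate = degenerate),
    class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf(
    "<roc_comparison> AUC %.3f (SE %.3f) vs %.3f (SE %.3f); diff %+.3f, p = %.3g\n",
    x$auc_a, x$se_a, x$auc_b, x$se_b, x$auc_diff, x$p_value))
  invisible(x)
}

#' Youden-optimal decision threshold
#'
#' Scans the observed score values as candidate thresholds for the decision
#' rule `score >= threshold` and returns the one maximizing Youden's
#' J = sensitivity + specificity - 1. Ties are broken toward the lower
#' threshold.
#'
#' @inheritParams roc_auc
#' @return the optimal threshold (one of the observed score values).
#' @export
optimal_cutoff <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  cand <- sort(unique(scores))
  pos <- scores[labels]; neg <- scores[!labels]
  j <- vapply(cand, function(t) {
    mean(pos >= t) + mean(neg < t) - 1
  }, numeric(1L))
  cand[which.max(j)]  # which.max takes the first (lowest) maximizer
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' Positivity rule is `score >= cutoff` (inclusive).
#'
#' @inheritParams roc_auc
#' @param cutoff decision threshold.
#' @return list with `sensitivity`, `specificity` (both in `[0, 1]`).
#' @export
sens_spec <- function(scores, labels, cutoff) {
  labels <- check_binary_labels(scores, labels)
  list(sensitivity = mean(scores[labels] >= cutoff),
       specificity = mean(scores[!labels] < cutoff))
}

#' McNemar's paired test on discordant counts
#'
#' Exact two-tailed binomial test on the discordant pairs when
#' `n01 + n10 < 25`; chi-squared with continuity correction otherwise.
#' With no discordant pairs, `p = 1`.
#'
#' @param n01,n10 non-negative integer discordant counts (method A only /
#'   method B only).
#' @return list with `p_value`, `method` (`"exact"` or `"chisq"`), and
#'   `statistic` (the chi-squared statistic, `NA` for the exact branch).
#' @export
mcnemar_test <- function(n01, n10) {
  if (n01 < 0 || n10 < 0 || n01 != round(n01) || n10 != round(n10)) {
    stop("n01 and n10 must be non-negative integers")
  }
  n <- n01 + n10
  if (n == 0) {
    return(list(p_value = 1, method = "exact", statistic = NA_real_))
  }
  if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(n01, n10), n, 0.5))
    list(p_value = p, method = "exact", statistic = NA_real_)
  } else {
    stat <- (abs(n01 - n10) - 1)^2 / n
    list(p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         method = "chisq", statistic = stat)
  }
}

#' Bland-Altman agreement analysis
#'
#' Paired-difference agreement between two measurements of the same quantity.
#' Differences are `b - a` (second method minus first), bias is their mean,
#' the 95% limits of agreement are `bias +/- 1.96 * SD(diff)`, the bias CI
#' uses the t-distribution and `bias_p` is the two-tailed paired t-test
#' p-value. A zero-SD (identical-pairs) input degenerates gracefully to
#' `p = 1` and zero-width limits.
#'
#' @param a,b numeric vectors of paired measurements (at least 3 pairs).
#' @param conf_level confidence level for the bias CI (default 0.95).
#' @return An object of class `bland_altman`: list with `n`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `bias_ci95`, `bias_p`.
#' @export
bland_altman <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3L) stop("need at least 3 pairs")
  d <- b - a
  n <- length(d)
  bias <- mean(d)
  sd_d <- stats::sd(d)
  se <- sd_d / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  p <- if (sd_d == 0) {
    if (bias == 0) 1 else 0
  } else {
    2 * stats::pt(-abs(bias / se), df = n - 1)
  }
  structure(
    list(n = n, bias = bias, sd_diff = sd_d,
         loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
         bias_ci95 = c(bias - tq * se, bias + tq * se), bias_p = p),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> bias %+.2f%% (95%% CI %.2f to %.2f), LoA %.2f to %.2f, p = %.3g\n",
    x$bias, x$bias_ci95[1], x$bias_ci95[2], x$loa_low, x$loa_high, x$bias_p))
  invisible(x)
}

#' Paired categorization agreement at a threshold
#'
#' Cross-tabulates two paired scores at a common positivity threshold
#' (`score >= threshold`) and reports the observed agreement percentage.
#'
#' @param a,b numeric vectors of paired scores.
#' @param threshold positivity threshold (default 3).
#' @return list with `counts` (named: `both_pos`, `both_neg`, `a_only`,
#'   `b_only`), `n` and `observed_agreement` (percent).
#' @export
concordance_at_threshold <- function(a, b, threshold = 3) {
  if (threshold <= 0) stop("threshold must be positive")
  if (length(a) != length(b)) stop("a and b must have equal length")
  pa <- a >= threshold; pb <- b >= threshold
  counts <- c(both_pos = sum(pa & pb), both_neg = sum(!pa & !pb),
              a_only = sum(pa & !pb), b_only = sum(!pa & pb))
  list(counts = counts, n = length(a),
       observed_agreement = 100 * (counts[["both_pos"]] + counts[["both_neg"]]) /
         length(a))
}

#' Ordinary least squares with intercept confidence interval
#'
#' Simple linear regression of `y` on `x` with the t-based confidence
#' interval of the intercept and R-squared (= squared Pearson correlation).
#'
#' @param x,y numeric vectors (n >= 3; `x` must not be constant).
#' @param conf_level confidence level (default 0.95).
#' @return list with `slope`, `intercept`, `intercept_ci95`, `slope_ci95`,
#'   `r_squared`.
#' @export
linreg_with_ci <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x is constant; regression undefined")
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, level = conf_level)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       intercept_ci95 = unname(ci[1L, ]),
       slope_ci95 = unname(ci[2L, ]),
       r_squared = stats::cor(x, y)^2)
}
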