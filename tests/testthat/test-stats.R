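test_that("roc_auc equals exhaustive pair counting", {
  # anchors
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(5, 8), rep(c(0, 1), 4)), 0.5)
  # 6-point toy with a tie across classes
  s <- c(0.2, 0.5, 0.5, 0.7, 0.9, 0.3)
  l <- c(0, 0, 1, 1, 1, 0)
  expect_equal(roc_auc(s, l), auc_oracle(s, l))
  # randomized property, including heavy ties
  set.seed(61)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    s <- sample(seq(0, 2, by = 0.25), n, replace = TRUE)
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(s, l), auc_oracle(s, l))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  expect_error(roc_auc(c(1, NA), c(0, 1)), "finite")
})

test_that("delong_paired_test: self-comparison, shared estimator, bootstrap", {
  set.seed(19)
  s <- rnorm(30)
  l <- rep(c(0, 1), 15)
  expect_warning(res <- delong_paired_test(s, s, l), "degenerate")
  expect_equal(res$auc_diff, 0)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)

  # the paired test's AUCs are exactly roc_auc's Mann-Whitney values
  for (i in 1:10) {
    a <- rnorm(40); b <- rnorm(40)
    l <- c(rep(1, 20), rep(0, 20))
    res <- delong_paired_test(a, b, l)
    expect_equal(res$auc_a, roc_auc(a, l))
    expect_equal(res$auc_b, roc_auc(b, l))
    expect_true(res$ci95_a[1] <= res$auc_a && res$auc_a <= res$ci95_a[2])
    expect_gte(res$p_value, 0); expect_lte(res$p_value, 1)
  }

  # variance of the AUC difference agrees with a nonparametric bootstrap
  set.seed(11)
  x <- c(rnorm(20, 1), rnorm(20))
  lab <- rep(c(TRUE, FALSE), each = 20)
  y <- x + rnorm(40, 0, 0.5)
  dl <- delong_paired_test(x, y, lab)
  boot <- replicate(10000, {
    idx <- c(sample(which(lab), replace = TRUE),
             sample(which(!lab), replace = TRUE))
    roc_auc(x[idx], lab[idx]) - roc_auc(y[idx], lab[idx])
  })
  expect_equal(dl$se_diff^2, stats::var(boot), tolerance = 0.1)
})

test_that("delong_paired_test holds its type-I error near 5% on null data", {
  # scores carry no class signal; method B is method A plus a perturbation of
  # 0.25 score-SD units. (Much smaller perturbations make the paired z
  # conservative because the AUC difference becomes nearly discrete.)
  set.seed(42)
  B <- 1000
  rej <- 0
  lab <- rep(c(TRUE, FALSE), each = 50)
  for (i in seq_len(B)) {
    a <- rnorm(100)
    b <- a + rnorm(100, 0, 0.25)
    rej <- rej + (delong_paired_test(a, b, lab)$p_value < 0.05)
  }
  expect_gte(rej / B, 0.03)
  expect_lte(rej / B, 0.07)
})

test_that("optimal_cutoff maximizes Youden's J with low-threshold ties", {
  # full separation with gap (2, 5): the rule score >= t returns 5
  s <- c(1, 2, 5, 6); l <- c(0, 0, 1, 1)
  expect_equal(optimal_cutoff(s, l), 5)
  # 8-score toy against an exhaustive scan
  s <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.45, 0.2, 0.9)
  l <- c(0, 0, 1, 1, 1, 0, 0, 1)
  scan <- sapply(sort(unique(s)), function(t) {
    mean(s[l == 1] >= t) + mean(s[l == 0] < t) - 1
  })
  expect_equal(optimal_cutoff(s, l), sort(unique(s))[which.max(scan)])
  # tie broken toward the lower threshold
  expect_equal(optimal_cutoff(c(1, 2, 3, 4), c(0, 1, 0, 1)), 2)
  # randomized agreement with the exhaustive scan
  set.seed(83)
  for (i in 1:15) {
    s <- round(runif(20), 2)
    l <- c(0, 1, sample(0:1, 18, replace = TRUE))
    cand <- sort(unique(s))
    scan <- sapply(cand, function(t) {
      mean(s[l == 1] >= t) + mean(s[l == 0] < t) - 1
    })
    expect_equal(optimal_cutoff(s, l), cand[which.max(scan)])
  }
})

test_that("sens_spec applies the inclusive >= rule", {
  r <- sens_spec(c(1, 3, 3, 5), c(0, 0, 1, 1), 3)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 0.5)
})

test_that("mcnemar_test: exact and chi-squared branches", {
  expect_equal(mcnemar_test(5, 5)$p_value, 1)
  expect_equal(mcnemar_test(0, 0)$p_value, 1)
  # (7, 1): exact two-tailed p = 2 * P(Bin(8, 1/2) <= 1) by direct summation
  expect_equal(mcnemar_test(7, 1)$p_value,
               2 * sum(stats::dbinom(0:1, 8, 0.5)))
  expect_identical(mcnemar_test(7, 1)$method, "exact")
  # discordant counts from the clinical sensitivity comparison
  res <- mcnemar_test(26, 4)
  expect_identical(res$method, "chisq")
  expect_lt(res$p_value, 0.01)
  # swap invariance
  for (pair in list(c(7, 1), c(26, 4), c(12, 12), c(3, 0))) {
    expect_equal(mcnemar_test(pair[1], pair[2])$p_value,
                 mcnemar_test(pair[2], pair[1])$p_value)
  }
  expect_error(mcnemar_test(-1, 2), "non-negative")
})

test_that("bland_altman reproduces the closed-form fixture", {
  # identical pairs degenerate cleanly
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))
  expect_equal(ident$bias_p, 1)

  # differences {-2, 0, 2, 4}: bias 1, SD = sqrt(20/3)
  a <- c(10, 10, 10, 10)
  b <- a + c(-2, 0, 2, 4)
  ba <- bland_altman(a, b)
  sd_hand <- sqrt(((-3)^2 + (-1)^2 + 1^2 + 3^2) / 3)
  expect_equal(ba$bias, 1)
  expect_equal(ba$sd_diff, sd_hand)
  expect_equal(ba$loa_low, 1 - 1.96 * sd_hand)
  expect_equal(ba$loa_high, 1 + 1.96 * sd_hand)
  expect_true(ba$bias_ci95[1] < 1 && 1 < ba$bias_ci95[2])

  # swapping the pair order flips the bias and keeps the LoA width
  sw <- bland_altman(b, a)
  expect_equal(sw$bias, -ba$bias)
  expect_equal(sw$loa_high - sw$loa_low, ba$loa_high - ba$loa_low)

  expect_error(bland_altman(1:2, 1:2), "3 pairs")
})

test_that("concordance_at_threshold counts match brute force", {
  set.seed(29)
  a <- runif(20, 0, 6); b <- runif(20, 0, 6)
  got <- concordance_at_threshold(a, b, 3)
  manual <- c(both_pos = 0, both_neg = 0, a_only = 0, b_only = 0)
  for (i in 1:20) {
    pa <- a[i] >= 3; pb <- b[i] >= 3
    key <- if (pa && pb) "both_pos" else if (!pa && !pb) "both_neg"
           else if (pa) "a_only" else "b_only"
    manual[key] <- manual[key] + 1
  }
  expect_equal(got$counts, manual)
  expect_equal(got$observed_agreement,
               100 * (manual["both_pos"] + manual["both_neg"]) / 20,
               ignore_attr = TRUE)
  # all below threshold -> perfect agreement
  expect_equal(concordance_at_threshold(runif(5), runif(5), 3)$observed_agreement,
               100)
})

test_that("linreg_with_ci matches the normal-equations solution", {
  # exact line (lm warns about the perfect fit; the values are still exact)
  x <- 0:5
  fit <- suppressWarnings(linreg_with_ci(x, 2 * x + 1))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)

  # 5-point fixture solved independently via solve(t(X) X) t(X) y
  x <- c(0, 1, 2, 3, 4)
  y <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fit <- linreg_with_ci(x, y)
  expect_equal(fit$intercept, beta[1], ignore_attr = TRUE)
  expect_equal(fit$slope, beta[2], ignore_attr = TRUE)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / 3
  se_int <- sqrt(s2 * solve(t(X) %*% X)[1, 1])
  expect_equal(fit$intercept_ci95,
               beta[1] + c(-1, 1) * stats::qt(0.975, 3) * se_int,
               ignore_attr = TRUE)
  expect_equal(fit$r_squared, stats::cor(x, y)^2)

  expect_error(linreg_with_ci(rep(2, 5), 1:5), "constant")
})
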