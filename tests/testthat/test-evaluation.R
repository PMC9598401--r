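test_that("confusion counts match enumeration and a random tally oracle", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cc)[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  yp <- c(1, 0, 1); expect_equal(confusion_counts(yp, yp)$FP, 0L)
  expect_equal(confusion_counts(yp, yp)$FN, 0L)

  set.seed(1)
  yt <- rbinom(100, 1, 0.4); pr <- rbinom(100, 1, 0.5)
  cc2 <- confusion_counts(yt, pr)
  brute <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in 1:100) {
    key <- if (yt[i] == 1 && pr[i] == 1) "TP" else if (yt[i] == 0 && pr[i] == 1)
      "FP" else if (yt[i] == 0) "TN" else "FN"
    brute[key] <- brute[key] + 1
  }
  expect_equal(cc2$TP + cc2$FP + cc2$TN + cc2$FN, 100)
  expect_equal(unname(unlist(cc2[c("TP", "FP", "TN", "FN")])),
               unname(brute))
  expect_error(confusion_counts(c(1, 2), c(0, 1)), "0/1")
})

test_that("sensitivity and specificity follow their definitions", {
  cc <- structure(list(TP = 5L, FP = 1L, TN = 3L, FN = 0L),
                  class = "confusion_counts")
  expect_equal(sensitivity(cc), 1.0)
  expect_equal(specificity(cc), 0.75)
  # FPR = 1 - specificity
  expect_equal(1 - specificity(cc), 1 / 4)
  cc0 <- structure(list(TP = 0L, FP = 2L, TN = 3L, FN = 0L),
                   class = "confusion_counts")
  expect_warning(s <- sensitivity(cc0), "undefined")
  expect_true(is.na(s))
})

test_that("AUC equals the pairwise Mann-Whitney statistic", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.8, 0.7, 0.6, 0.2))$auc, 0.75)

  set.seed(2)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(roc_auc(y, s)$auc, auc_brute(y, s))
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("ROC curve is a valid nondecreasing sweep whose area is the AUC", {
  set.seed(3)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(40)
  r <- roc_auc(y, s)
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  expect_equal(r$tpr[1], 0); expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_equal(r$fpr[length(r$fpr)], 1)
  trap <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-12)
})

test_that("AUC is invariant to monotone transforms and complements on flip", {
  set.seed(4)
  y <- c(0, 1, rbinom(30, 1, 0.5))
  s <- rnorm(32)
  a <- roc_auc(y, s)$auc
  expect_equal(roc_auc(y, exp(2 * s + 1))$auc, a)
  expect_equal(roc_auc(y, rank(s))$auc, a)
  expect_equal(roc_auc(y, -s)$auc, 1 - a)  # tie-free scores
})

test_that("per-fold AUC aggregation returns mean and sample variance", {
  expect_equal(aggregate_cv_auc(c(1, 1, 1, 1)), list(mean = 1, variance = 0))
  expect_equal(aggregate_cv_auc(c(0.9, 0.7)), list(mean = 0.8, variance = 0.02))
  expect_error(aggregate_cv_auc(0.9), "at least 2")
})

test_that("Friedman statistic matches closed cases and stats::friedman.test", {
  # identical AUCs everywhere: all mean ranks tie, statistic 0
  expect_equal(friedman_test(matrix(0.8, 3, 4))$statistic, 0)

  # perfectly consistent ordering of 3 methods over 4 datasets
  m <- rbind(a = c(0.9, 0.8, 0.95, 0.85),
             b = c(0.8, 0.7, 0.85, 0.75),
             c = c(0.7, 0.6, 0.75, 0.65))
  fr <- friedman_test(m)
  expect_equal(fr$statistic, 8.0)
  expect_equal(fr$p_value, pchisq(8, df = 2, lower.tail = FALSE))

  # tie-free random matrices agree with the base-R implementation
  set.seed(5)
  for (i in 1:5) {
    mm <- matrix(rnorm(21), 3, 7)
    ours <- friedman_test(mm)
    base <- stats::friedman.test(t(mm))
    expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, base$p.value, tolerance = 1e-12)
  }
  expect_error(friedman_test(matrix(1, 1, 4)), ">= 2 methods")
})

test_that("Friedman null distribution matches a permutation oracle", {
  set.seed(6)
  B <- 10000
  # distribution of the statistic on random 3x5 matrices (the null)
  stat_rand <- replicate(B, friedman_test(matrix(rnorm(15), 3, 5))$statistic)
  # permutation oracle: shuffle values within datasets, independent
  # rank-sum implementation
  base_m <- matrix(rnorm(15), 3, 5)
  stat_perm <- replicate(B, {
    perm <- apply(base_m, 2, sample)
    friedman_brute(perm)
  })
  ks <- suppressWarnings(stats::ks.test(stat_rand, stat_perm)$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("Nemenyi post-hoc flags the extreme pair and is symmetric", {
  m <- matrix(0.8, 4, 4, dimnames = list(letters[1:4], NULL))
  P <- nemenyi_posthoc(m)
  expect_true(all(P[upper.tri(P)] == 1))
  expect_equal(P, t(P))
  expect_true(all(diag(P) == 1))

  # 7 methods, 4 datasets; method "worst" always last, "best" always first
  set.seed(7)
  mm <- matrix(runif(28, 0.5, 0.6), 7, 4,
               dimnames = list(c("best", paste0("mid", 1:5), "worst"), NULL))
  mm["best", ] <- 0.99
  mm["worst", ] <- 0.01
  P2 <- nemenyi_posthoc(mm)
  off <- P2; diag(off) <- NA
  expect_equal(which(off == min(off, na.rm = TRUE), arr.ind = TRUE)[1, ],
               c(row = 7, col = 1), ignore_attr = TRUE)
  expect_equal(P2, t(P2))
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:5) {
    y <- c(0, 1, rbinom(40, 1, 0.5))
    s <- round(rnorm(42), 1)
    ours <- roc_auc(y, s)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(y, s, direction = "<",
                                                 levels = c(0, 1))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})
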