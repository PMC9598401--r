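#' Confusion counts for a binary prediction
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return list of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop2("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop2("inputs must be 0/1")
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 FP = sum(y_true == 0 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Sensitivity (true positive rate)
#'
#' `TP / (TP + FN)`. An empty positive class makes the metric undefined:
#' `NA` is returned with a warning, never silently 0.
#'
#' @param c a [confusion_counts()].
#' @return numeric in `[0, 1]` or `NA`.
#' @export
sensitivity <- function(c) {
  if (c$TP + c$FN == 0) {
    warning("sensitivity undefined: no positive cases", call. = FALSE)
    return(NA_real_)
  }
  c$TP / (c$TP + c$FN)
}

#' Specificity (true negative rate)
#'
#' `TN / (FP + TN)`; the false positive rate is its complement
#' `FPR = 1 - specificity`. An empty negative class returns `NA` with a
#' warning.
#'
#' @param c a [confusion_counts()].
#' @return numeric in `[0, 1]` or `NA`.
#' @export
specificity <- function(c) {
  if (c$FP + c$TN == 0) {
    warning("specificity undefined: no negative cases", call. = FALSE)
    return(NA_real_)
  }
  c$TN / (c$FP + c$TN)
}

#' ROC curve and AUC of a real-valued score
#'
#' The AUC is the Mann-Whitney pairwise statistic: the proportion of
#' (positive, negative) pairs in which the positive scores higher, with half
#' credit for ties (computed via midranks). The curve itself is a threshold
#' sweep over the observed scores; its trapezoidal area equals the pairwise
#' statistic.
#'
#' @param y_true 0/1 vector; both classes must be present.
#' @param scores numeric ranking scores (higher = more class-1).
#' @return list of class `roc_result` with `thresholds`, `tpr`, `fpr`,
#'   `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop2("length mismatch")
  if (!all(y_true %in% c(0, 1))) stop2("y_true must be 0/1")
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop2("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]; ss <- scores[ord]
  # collapse tied scores into single thresholds
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- !duplicated(grp, fromLast = TRUE)
  structure(list(thresholds = c(Inf, ss[last]),
                 tpr = c(0, tp[last] / n1),
                 fpr = c(0, fp[last] / n0),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d thresholds, AUC = %.4f\n", length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "FPR (1 - specificity)",
                 ylab = "TPR (sensitivity)", ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Aggregate per-fold AUC into a cross-validated summary
#'
#' @param per_fold_auc numeric vector of per-fold AUCs, length >= 2.
#' @return list with `mean` and `variance` (sample variance across folds).
#' @export
aggregate_cv_auc <- function(per_fold_auc) {
  if (length(per_fold_auc) < 2)
    stop2("need at least 2 folds to aggregate")
  list(mean = mean(per_fold_auc), variance = stats::var(per_fold_auc))
}

#' Friedman rank test across methods and datasets
#'
#' Ranks the methods within every dataset (ties receive mean ranks) and
#' computes the chi-square statistic
#' `12/(n k (k+1)) * sum(R_j^2) - 3 n (k+1)` over the rank sums `R_j` of the
#' `k` methods across `n` datasets, referred to a chi-square distribution
#' with `k - 1` degrees of freedom.
#'
#' @param auc methods x datasets matrix of scores (higher = better).
#' @return list with `statistic`, `p_value`, `mean_ranks` (per method).
#' @export
friedman_test <- function(auc) {
  auc <- as.matrix(auc)
  k <- nrow(auc); n <- ncol(auc)
  if (k < 2 || n < 2) stop2("need >= 2 methods and >= 2 datasets")
  ranks <- apply(-auc, 2, rank, ties.method = "average")  # rank 1 = best
  Rj <- rowSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       mean_ranks = Rj / n)
}

#' Nemenyi post-hoc pairwise comparison of methods
#'
#' Compares the mean ranks of all method pairs against critical values of
#' the studentized-range distribution:
#' `q = |Rbar_i - Rbar_j| / sqrt(k (k+1) / (12 n))`, with p-value
#' `P(Q_{k,Inf} >= q * sqrt(2))`.
#'
#' @param auc methods x datasets matrix of scores.
#' @return symmetric matrix of pairwise p-values with unit diagonal.
#' @export
nemenyi_posthoc <- function(auc) {
  auc <- as.matrix(auc)
  k <- nrow(auc); n <- ncol(auc)
  if (k < 2 || n < 2) stop2("need >= 2 methods and >= 2 datasets")
  ranks <- apply(-auc, 2, rank, ties.method = "average")
  rbar <- rowSums(ranks) / n
  se <- sqrt(k * (k + 1) / (12 * n))
  P <- matrix(1, k, k, dimnames = list(rownames(auc), rownames(auc)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      q <- abs(rbar[i] - rbar[j]) / se
      p <- stats::ptukey(q * sqrt(2), nmeans = k, df = Inf,
                         lower.tail = FALSE)
      P[i, j] <- P[j, i] <- p
    }
  }
  P
}
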