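#' Compute a geometric lambda path starting at the null-model threshold
#'
#' `lambda_max` is the smallest penalty at which the fitted model is entirely
#' zero: for lasso/elastic net `(2/n) max_j |x_j' y| / alpha`; for the group
#' lasso `max_j ||(2/n) X_j' y||_2 / sqrt(p_j)`; for the sparse group lasso
#' the smallest lambda at which every group-zero test holds, located by
#' per-group bisection (tolerance 1e-8). Values are geometrically spaced from
#' `lambda_max` down to `ratio * lambda_max`.
#'
#' @param X standardized design matrix.
#' @param y centered response.
#' @param kind `"lasso"`, `"enet"`, `"biglasso"`, `"grouplasso"` or `"sgl"`.
#'   Pure ridge (`alpha_mix = 0` for an L1 path) is an error: the ridge
#'   solution is never exactly zero, and its cross-validation grid is built
#'   separately on a fixed geometric scale.
#' @param alpha_mix mixing parameter (must be > 0 for L1-containing paths).
#' @param grouping a [gene_grouping()] (grouplasso/sgl only).
#' @param n_values path length `m` (default 100).
#' @param ratio `lambda_min / lambda_max`; default 1e-3, or 1e-2 when
#'   `n < p`.
#' @return an object of class `lambda_path`: list with decreasing `values`,
#'   `lambda_max` and `ratio`.
#' @export
compute_lambda_path <- function(X, y, kind = "lasso", alpha_mix = 1,
                                grouping = NULL, n_values = 100, ratio = NULL) {
  X <- check_xy(X, y)
  n <- nrow(X)
  kind <- match.arg(kind, c("lasso", "enet", "biglasso", "grouplasso", "sgl"))
  if (kind %in% c("lasso", "biglasso")) alpha_mix <- 1
  if (kind == "grouplasso") alpha_mix <- 0
  if (kind %in% c("lasso", "enet", "biglasso") && alpha_mix <= 0)
    stop2("an L1 path needs alpha_mix > 0; the ridge grid is built separately")
  if (is.null(ratio)) ratio <- if (n < ncol(X)) 1e-2 else 1e-3
  g <- abs(crossprod(X, y))[, 1] * 2 / n          # (2/n) |X'y|

  lambda_max <-
    if (kind %in% c("lasso", "enet", "biglasso")) {
      max(g) / alpha_mix
    } else {
      lay <- group_layout(grouping, ncol(X))
      Xo <- X[, lay$ord, drop = FALSE]
      J <- length(lay$gstart)
      per_group <- numeric(J)
      for (j in seq_len(J)) {
        idx <- (lay$gstart[j] + 1):(lay$gend[j] + 1)
        cj <- crossprod(Xo[, idx, drop = FALSE], y)[, 1] * 2 / n
        if (kind == "grouplasso" || alpha_mix == 0) {
          per_group[j] <- sqrt(sum(cj^2)) / lay$wj[j]
        } else if (alpha_mix == 1) {
          per_group[j] <- max(abs(cj))
        } else {
          # smallest L with ||soft(cj, alpha*L)|| <= (1-alpha)*L*wj (bisection)
          f <- function(L)
            sqrt(sum(soft_threshold(cj, alpha_mix * L)^2)) -
              (1 - alpha_mix) * L * lay$wj[j]
          hi <- max(abs(cj)) / alpha_mix
          lo <- 0
          if (f(hi) > 0) stop2("lambda_max bisection bracket failed")
          while (hi - lo > 1e-8 * max(1, hi)) {
            mid <- (lo + hi) / 2
            if (f(mid) <= 0) hi <- mid else lo <- mid
          }
          per_group[j] <- hi
        }
      }
      max(per_group)
    }
  if (lambda_max <= 0) stop2("lambda_max is zero: X'y vanishes")
  values <- exp(seq(log(lambda_max), log(lambda_max * ratio),
                    length.out = n_values))
  values[1] <- lambda_max
  values[n_values] <- lambda_max * ratio
  structure(list(values = values, lambda_max = lambda_max, ratio = ratio),
            class = "lambda_path")
}

# Ridge cross-validation grid: geometric, anchored at the lasso-scale
# gradient magnitude so the grid brackets both near-OLS and heavy shrinkage.
ridge_lambda_grid <- function(X, y, n_values = 100) {
  n <- nrow(X)
  ref <- max(abs(crossprod(X, y))) * 2 / n
  structure(list(values = exp(seq(log(ref * 1e3), log(ref * 1e-4),
                                  length.out = n_values)),
                 lambda_max = ref * 1e3, ratio = 1e-7),
            class = "lambda_path")
}

# fit a whole path on (standardized) Xs, ys; returns p x m coefficient matrix
fit_path_matrix <- function(Xs, ys, spec, values, tol = 1e-7, max_iter = 1e5,
                            seed = 1) {
  out <- fit_path_matrix_(Xs, ys, spec, values, tol, max_iter, seed)
  matrix(out, nrow = ncol(Xs), ncol = length(values))
}

fit_path_matrix_ <- function(Xs, ys, spec, values, tol = 1e-7, max_iter = 1e5,
                             seed = 1) {
  kind <- spec$kind
  if (kind == "ridge") {
    n <- nrow(Xs)
    if (n < ncol(Xs)) {
      eg <- eigen(tcrossprod(Xs), symmetric = TRUE)
      Xty <- crossprod(eg$vectors, ys)
      sapply(values, function(l) {
        crossprod(Xs, eg$vectors %*% (Xty / (eg$values + n * l)))[, 1]
      })
    } else {
      eg <- eigen(crossprod(Xs), symmetric = TRUE)
      Xty <- crossprod(eg$vectors, crossprod(Xs, ys))
      sapply(values, function(l) {
        (eg$vectors %*% (Xty / (eg$values + n * l)))[, 1]
      })
    }
  } else if (kind %in% c("lasso", "biglasso")) {
    cpp_enet_path(Xs, ys, values, rep(0, length(values)), tol,
                  as.integer(max_iter), FALSE)$beta
  } else if (kind == "enet") {
    a <- spec$alpha_mix %||% 0.5
    cpp_enet_path(Xs, ys, a * values, (1 - a) * values / 2, tol,
                  as.integer(max_iter), FALSE)$beta
  } else if (kind == "grouplasso") {
    lay <- group_layout(spec$grouping, ncol(Xs))
    b <- cpp_grouplasso_path(Xs[, lay$ord, drop = FALSE], ys, lay$gstart,
                             lay$gend, lay$wj, values, tol,
                             as.integer(max_iter), FALSE)$beta
    b[lay$inv, , drop = FALSE]
  } else if (kind == "sgl") {
    lay <- group_layout(spec$grouping, ncol(Xs))
    b <- cpp_sgl_path(Xs[, lay$ord, drop = FALSE], ys, lay$gstart, lay$gend,
                      lay$wj, values, spec$alpha_mix %||% 0.95, tol,
                      as.integer(max_iter), 100L, FALSE)$beta
    b[lay$inv, , drop = FALSE]
  } else if (kind == "droplasso") {
    sapply(seq_along(values), function(i) {
      fit_droplasso(Xs, ys, values[i], keep_prob = spec$keep_prob,
                    seed = seed + i)$coefficients
    })
  } else stop2("unknown penalty kind: ", kind)
}

# rule logic shared by cv_select_lambda; values are descending
select_lambda_index <- function(cv_mean, cv_se, rule) {
  i_min <- which(cv_mean <= min(cv_mean))[1]   # first = largest lambda on ties
  if (rule == "min") return(i_min)
  band <- min(cv_mean) + cv_se[i_min]
  which(cv_mean <= band)[1]
}

#' Cross-validated lambda selection
#'
#' Runs k-fold cross-validation over a lambda path: each training fold is
#' standardized on its own rows (columns constant within the fold are dropped
#' for that fold), the path is fitted warm-started, and held-out squared error
#' is recorded per lambda. The per-lambda CV error is the mean over folds and
#' its standard error the across-fold standard deviation divided by
#' `sqrt(k)`. `rule = "min"` selects the error-minimizing lambda (largest on
#' ties); `rule = "1se"` the largest lambda whose error is within one standard
#' error of the minimum. The model is refitted on the full data at the
#' selected lambda, and held-out prediction scores at that lambda are kept
#' per fold for downstream ROC/AUC evaluation.
#'
#' @param X raw (unstandardized) design matrix, cells x genes.
#' @param y response (0/1 labels or numeric).
#' @param spec a [penalty_spec()] naming the penalty; its `lambda` slot is
#'   ignored in favour of the path.
#' @param folds a `fold_spec` from [make_stratified_folds()]; built
#'   automatically from `k` and `seed` when `NULL` and `y` is binary.
#' @param rule `"min"` or `"1se"`.
#' @param k,seed fold construction when `folds` is `NULL`.
#' @param n_values,ratio path construction, see [compute_lambda_path()].
#' @param tol,max_iter solver controls.
#' @return an object of class `cv_penreg`: `path`, `cv_error_mean`,
#'   `cv_error_se`, `selected_lambda`, `rule`, `per_fold_predictions` (list
#'   of `score`, `y`, `index` per fold at the selected lambda), and `fit`
#'   (the full-data refit, standardized scale) plus the scaling parameters.
#' @export
cv_select_lambda <- function(X, y, spec, folds = NULL, rule = c("min", "1se"),
                             k = 10, seed = 1, n_values = 100, ratio = NULL,
                             tol = 1e-7, max_iter = 1e5) {
  rule <- match.arg(rule)
  X <- check_xy(X, y)
  if (is.null(folds)) {
    if (!all(y %in% c(0, 1)))
      stop2("folds must be supplied explicitly for a non-binary response")
    folds <- make_stratified_folds(y, k = k, seed = seed)
  }
  if (folds$k < 2) stop2("cross-validation needs at least 2 folds")
  if (length(folds$assignments) != nrow(X))
    stop2("fold assignments do not match X")

  std_full <- standardize_train_apply_test(X, NULL, y)
  path <- if (spec$kind == "ridge")
    ridge_lambda_grid(std_full$train_x, std_full$train_y, n_values)
  else
    compute_lambda_path(std_full$train_x, std_full$train_y, kind = spec$kind,
                        alpha_mix = spec$alpha_mix %||% 1,
                        grouping = spec$grouping, n_values = n_values,
                        ratio = ratio)

  m <- length(path$values)
  kk <- folds$k
  err <- matrix(NA_real_, m, kk)
  fold_scores <- vector("list", kk)

  for (f in seq_len(kk)) {
    te <- which(folds$assignments == f)
    tr <- which(folds$assignments != f)
    Xtr <- X[tr, , drop = FALSE]
    keep <- col_sd_pop(Xtr) > 0
    sub_spec <- spec
    if (!all(keep) && !is.null(spec$grouping))
      sub_spec$grouping <- subset_grouping(spec$grouping, keep)
    std <- standardize_train_apply_test(Xtr[, keep, drop = FALSE],
                                        X[te, keep, drop = FALSE], y[tr])
    B <- fit_path_matrix(std$train_x, std$train_y, sub_spec, path$values,
                         tol, max_iter, seed = seed + f)
    S <- std$test_x %*% B                       # n_test x m score matrix
    yte <- (y[te] - std$y_center) / std$y_scale
    err[, f] <- colMeans((yte - S)^2)
    fold_scores[[f]] <- list(scores = S, index = te, y = y[te])
  }

  cv_mean <- rowMeans(err)
  cv_se <- apply(err, 1, stats::sd) / sqrt(kk)
  sel <- select_lambda_index(cv_mean, cv_se, rule)
  selected_lambda <- path$values[sel]

  per_fold <- lapply(fold_scores, function(fs)
    list(score = fs$scores[, sel], y = fs$y, index = fs$index))

  refit_spec <- spec
  refit_spec$lambda <- selected_lambda
  B_full <- fit_path_matrix(std_full$train_x, std_full$train_y, spec,
                            path$values[seq_len(sel)], tol, max_iter,
                            seed = seed)
  beta_std <- B_full[, sel]
  names(beta_std) <- colnames(X)

  structure(list(path = path, cv_error_mean = cv_mean, cv_error_se = cv_se,
                 selected_lambda = selected_lambda, selected_index = sel,
                 rule = rule, per_fold_predictions = per_fold,
                 fit = new_fit_result(beta_std, colnames(X), NA_real_,
                                      NA_integer_, TRUE, refit_spec),
                 center = std_full$center, scale = std_full$scale,
                 y_center = std_full$y_center, y_scale = std_full$y_scale,
                 folds = folds),
            class = "cv_penreg")
}

#' @export
print.cv_penreg <- function(x, ...) {
  cat(sprintf("cross-validated %s: %d lambdas, rule '%s' -> lambda = %.5g (CV error %.4f)\n",
              x$fit$spec$kind, length(x$path$values), x$rule,
              x$selected_lambda, x$cv_error_mean[x$selected_index]))
  cat(sprintf("  nonzero coefficients at selection: %d/%d\n",
              sum(x$fit$coefficients != 0), length(x$fit$coefficients)))
  invisible(x)
}

#' @export
plot.cv_penreg <- function(x, ...) {
  lv <- log(x$path$values)
  graphics::plot(lv, x$cv_error_mean, type = "l", xlab = "log(lambda)",
                 ylab = "CV squared error", ...)
  graphics::arrows(lv, x$cv_error_mean - x$cv_error_se,
                   lv, x$cv_error_mean + x$cv_error_se,
                   angle = 90, code = 3, length = 0.02, col = "grey60")
  graphics::abline(v = log(x$selected_lambda), lty = 2)
  invisible(x)
}

# restrict a grouping to the columns flagged TRUE in `keep`
subset_grouping <- function(grouping, keep) {
  gene_grouping(grouping$group_of_gene[keep])
}
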