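#' Fit a penalized linear model
#'
#' Unified fitting front-end over the package's solvers. The design is
#' standardized internally (columns to mean 0, population sd 1; response
#' centered and scaled), the requested penalty is fitted on the standardized
#' scale, and coefficients are reported back on the original scale with an
#' intercept. All objectives use the `1/n` squared-error loss
#' `(1/n) ||y - X b||^2` plus the penalty.
#'
#' @param x numeric predictor matrix (cells x genes).
#' @param y numeric response; for classification use 0/1 labels (the linear
#'   predictor is then a ranking score for ROC/AUC).
#' @param penalty one of `"lasso"`, `"ridge"`, `"enet"`, `"droplasso"`,
#'   `"grouplasso"`, `"sgl"`, `"biglasso"`.
#' @param lambda penalty strength (on the standardized scale).
#' @param alpha mixing parameter for `enet`/`sgl`.
#' @param grouping a [gene_grouping()] for the grouped penalties.
#' @param keep_prob,n_epochs,seed drop-lasso controls.
#' @param tol,max_iter solver controls.
#' @return an object of class `penreg` with `coefficients` (original scale),
#'   `intercept`, the standardized-scale `fit` and the scaling parameters.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("g", 1:10)))
#' y <- rbinom(20, 1, plogis(x[, 1] - x[, 2]))
#' fit <- penreg(x, y, penalty = "lasso", lambda = 0.1)
#' coef(fit)
#' head(predict(fit, x))
#' @export
penreg <- function(x, y, penalty = c("lasso", "ridge", "enet", "droplasso",
                                     "grouplasso", "sgl", "biglasso"),
                   lambda, alpha = NULL, grouping = NULL, keep_prob = 0.5,
                   n_epochs = 3000, seed = 1, tol = 1e-7, max_iter = 1e5) {
  penalty <- match.arg(penalty)
  x <- check_xy(x, y)
  std <- standardize_train_apply_test(x, NULL, y)
  Xs <- std$train_x; ys <- std$train_y
  fit <- switch(penalty,
    lasso = fit_enet(Xs, ys, lambda, alpha_mix = 1, tol = tol,
                     max_iter = max_iter),
    enet = fit_enet(Xs, ys, lambda, alpha_mix = alpha %||% 0.5, tol = tol,
                    max_iter = max_iter),
    ridge = {
      beta <- ridge_closed_form(Xs, ys, lambda)
      new_fit_result(beta, colnames(Xs),
                     enet_objective(Xs, ys, beta, 0, lambda), 1L, TRUE,
                     penalty_spec("ridge", lambda = lambda, alpha_mix = 0))
    },
    droplasso = fit_droplasso(Xs, ys, lambda, keep_prob = keep_prob,
                              n_epochs = n_epochs, seed = seed, tol = tol),
    grouplasso = fit_group_lasso(Xs, ys, grouping, lambda, tol = tol,
                                 max_iter = max_iter),
    sgl = fit_sgl(Xs, ys, grouping, lambda, alpha_mix = alpha %||% 0.95,
                  tol = tol, max_iter = max_iter),
    biglasso = fit_biglasso_objective(Xs, ys, lambda, tol = tol,
                                      max_iter = max_iter))
  beta_orig <- fit$coefficients * std$y_scale / std$scale
  intercept <- std$y_center - sum(beta_orig * std$center)
  structure(list(coefficients = beta_orig, intercept = intercept,
                 fit = fit, penalty = penalty, lambda = lambda,
                 center = std$center, scale = std$scale,
                 y_center = std$y_center, y_scale = std$y_scale,
                 call = match.call()),
            class = "penreg")
}

#' @export
print.penreg <- function(x, ...) {
  cat(sprintf("penalized linear model (%s, lambda = %.5g)\n",
              x$penalty, x$lambda))
  cat(sprintf("  %d/%d nonzero coefficients; intercept %.4f\n",
              sum(x$coefficients != 0), length(x$coefficients), x$intercept))
  invisible(x)
}

#' @export
#' @param standardized return coefficients on the standardized scale.
#' @rdname penreg
coef.penreg <- function(object, standardized = FALSE, ...) {
  if (standardized) object$fit$coefficients else object$coefficients
}

#' @export
predict.penreg <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(newdata %*% object$coefficients) + object$intercept
}

#' @export
fitted.penreg <- function(object, ...) {
  stop2("penreg objects do not store the training data; use predict(object, x)")
}

#' @export
residuals.penreg <- function(object, x, y, ...) {
  y - predict(object, x)
}

#' @export
summary.penreg <- function(object, ...) {
  print(object)
  nz <- object$coefficients[object$coefficients != 0]
  if (length(nz)) {
    cat("\nlargest coefficients (original scale):\n")
    print(utils::head(sort(abs(nz), decreasing = TRUE), 10))
  }
  invisible(object)
}
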