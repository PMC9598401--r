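#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - t, 0)`, the proximal operator of the L1 norm and the
#' elementary update of every L1-penalized solver in the package.
#'
#' @param z numeric vector.
#' @param t nonnegative threshold.
#' @return numeric vector of the same length as `z`.
#' @export
soft_threshold <- function(z, t) {
  if (any(t < 0)) stop2("threshold must be nonnegative")
  sign(z) * pmax(abs(z) - t, 0)
}

#' Penalty configuration
#'
#' Collects the penalty kind and its tuning parameters. For the elastic net
#' the pair (`lambda1`, `lambda2`) is derived from (`lambda`, `alpha_mix`) by
#' the glmnet-style convention `lambda1 = alpha * lambda`,
#' `lambda2 = (1 - alpha) * lambda / 2` unless given explicitly.
#'
#' @param kind one of `"ridge"`, `"lasso"`, `"enet"`, `"droplasso"`,
#'   `"grouplasso"`, `"sgl"`, `"biglasso"`.
#' @param lambda nonnegative penalty strength.
#' @param alpha_mix mixing parameter in `[0, 1]` (elastic net / SGL).
#' @param lambda1,lambda2 explicit elastic-net L1/L2 weights (optional).
#' @param keep_prob drop-lasso mask retention probability in `(0, 1]`.
#' @param grouping a [gene_grouping()]; required for `grouplasso` and `sgl`.
#' @return an object of class `penalty_spec`.
#' @export
penalty_spec <- function(kind, lambda = NULL, alpha_mix = NULL,
                         lambda1 = NULL, lambda2 = NULL,
                         keep_prob = 0.5, grouping = NULL) {
  kind <- match.arg(kind, c("ridge", "lasso", "enet", "droplasso",
                            "grouplasso", "sgl", "biglasso"))
  if (kind %in% c("grouplasso", "sgl") && is.null(grouping))
    stop2(kind, " requires a gene grouping")
  if (!kind %in% c("grouplasso", "sgl") && !is.null(grouping))
    stop2("grouping is only meaningful for grouplasso/sgl")
  if (!is.null(alpha_mix) && (alpha_mix < 0 || alpha_mix > 1))
    stop2("alpha_mix must lie in [0, 1]")
  if (!is.null(lambda) && any(lambda < 0)) stop2("lambda must be nonnegative")
  if (keep_prob <= 0 || keep_prob > 1) stop2("keep_prob must lie in (0, 1]")
  if (kind == "enet" && !is.null(lambda) && !is.null(alpha_mix) &&
      is.null(lambda1) && is.null(lambda2)) {
    lambda1 <- alpha_mix * lambda
    lambda2 <- (1 - alpha_mix) * lambda / 2
  }
  structure(list(kind = kind, lambda = lambda, alpha_mix = alpha_mix,
                 lambda1 = lambda1, lambda2 = lambda2,
                 keep_prob = keep_prob, grouping = grouping),
            class = "penalty_spec")
}

new_fit_result <- function(beta, gene_ids, objective, n_iter, converged, spec) {
  beta <- as.numeric(beta)
  if (!all(is.finite(beta))) stop2("solver produced non-finite coefficients")
  if (!is.null(gene_ids)) names(beta) <- gene_ids
  structure(list(coefficients = beta, intercept = 0,
                 objective_value = objective, n_iterations = n_iter,
                 converged = converged, spec = spec),
            class = "penreg_fit")
}

#' @export
print.penreg_fit <- function(x, ...) {
  cat(sprintf("penalized fit (%s): %d/%d nonzero coefficients, objective %.6g, %s in %d sweeps\n",
              x$spec$kind, sum(x$coefficients != 0), length(x$coefficients),
              x$objective_value,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' @export
coef.penreg_fit <- function(object, ...) object$coefficients

enet_objective <- function(X, y, beta, lambda1, lambda2) {
  r <- y - X %*% beta
  sum(r^2) / length(y) + lambda1 * sum(abs(beta)) + lambda2 * sum(beta^2)
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop2("nrow(X) must equal length(y)")
  if (anyNA(X) || anyNA(y)) stop2("X and y must not contain missing values")
  X
}

#' Ridge regression by its closed form
#'
#' Solves `argmin (1/n)||y - X b||^2 + lambda ||b||_2^2` exactly through the
#' stationarity system `(X'X + n lambda I) b = X'y`. When `n < p` the
#' equivalent kernel form `b = X'(XX' + n lambda I)^{-1} y` is used so the
#' linear solve is n x n.
#'
#' @param X standardized design matrix.
#' @param y centered response.
#' @param lambda nonnegative penalty; at `lambda = 0` the Gram matrix must be
#'   nonsingular.
#' @return the coefficient vector.
#' @export
ridge_closed_form <- function(X, y, lambda) {
  X <- check_xy(X, y)
  if (lambda < 0) stop2("lambda must be nonnegative")
  n <- nrow(X); p <- ncol(X)
  beta <- tryCatch({
    if (n < p) {
      as.numeric(crossprod(X, solve(tcrossprod(X) + n * lambda * diag(n), y)))
    } else {
      as.numeric(solve(crossprod(X) + n * lambda * diag(p), crossprod(X, y)))
    }
  }, error = function(e)
    stop2("ridge system is singular (lambda = ", lambda, "): ",
          conditionMessage(e)))
  names(beta) <- colnames(X)
  beta
}

#' Fit the elastic net (and its lasso/ridge special cases)
#'
#' Cyclic coordinate descent on
#' `(1/n)||y - X b||^2 + lambda1 ||b||_1 + lambda2 ||b||_2^2`
#' with `(lambda1, lambda2) = (alpha*lambda, (1-alpha)*lambda/2)`. Each
#' coordinate update is a soft-threshold; convergence is declared when the
#' largest absolute coefficient change in a sweep drops below `tol`.
#' `alpha_mix = 1` is the lasso, `alpha_mix = 0` pure ridge.
#'
#' @param X standardized design matrix (columns mean 0, population sd 1).
#' @param y centered response.
#' @param lambda nonnegative penalty strength.
#' @param alpha_mix mixing parameter in `[0, 1]` (default 1, lasso).
#' @param tol convergence tolerance on coefficient changes (default 1e-7).
#' @param max_iter maximum coordinate-descent sweeps (default 1e5).
#' @param track_objective record the objective after every sweep (for
#'   monotonicity diagnostics); stored as `objective_path`.
#' @return a `penreg_fit`.
#' @export
fit_enet <- function(X, y, lambda, alpha_mix = 1, tol = 1e-7, max_iter = 1e5,
                     track_objective = FALSE) {
  X <- check_xy(X, y)
  spec <- penalty_spec("enet", lambda = lambda, alpha_mix = alpha_mix)
  res <- cpp_enet_path(X, y, spec$lambda1, spec$lambda2, tol,
                       as.integer(max_iter), track_objective)
  if (!res$converged[1])
    warning("fit_enet: max_iter reached before convergence", call. = FALSE)
  out <- new_fit_result(res$beta[, 1], colnames(X),
                        enet_objective(X, y, res$beta[, 1],
                                       spec$lambda1, spec$lambda2),
                        res$iters[1], res$converged[1], spec)
  if (track_objective) out$objective_path <- res$objective[[1]]
  out
}

#' Lasso objective fitted for the big-lasso benchmark row
#'
#' The big-lasso objective is the lasso objective; this delegate exists so
#' benchmark tables can report it as its own method row. The out-of-core
#' machinery of big-lasso implementations is out of scope here.
#'
#' @inheritParams fit_enet
#' @return a `penreg_fit` with `spec$kind == "biglasso"`.
#' @export
fit_biglasso_objective <- function(X, y, lambda, tol = 1e-7, max_iter = 1e5) {
  fit <- fit_enet(X, y, lambda, alpha_mix = 1, tol = tol, max_iter = max_iter)
  fit$spec$kind <- "biglasso"
  fit
}

#' Fit the drop lasso
#'
#' Optimizes the dropout-augmented lasso objective
#' `(1/n)||y - X_drop b||^2 + lambda ||b||_1` by proximal (stochastic)
#' gradient descent: each epoch permutes the rows, draws an independent
#' Bernoulli(`keep_prob`) mask per row, scales retained entries by
#' `1/keep_prob` (so the masked design is unbiased for `X`), takes a
#' full-batch gradient step and applies the soft-threshold prox. With
#' `keep_prob = 1` this is exact proximal gradient descent on the lasso. For
#' `keep_prob < 1` the step size decays across epochs and the returned
#' coefficients are the average of the last quarter of iterates.
#'
#' @inheritParams fit_enet
#' @param keep_prob probability of retaining an entry, in `(0, 1]`.
#' @param n_epochs number of passes (default 3000).
#' @param seed integer seed driving the permutations and masks.
#' @param step0 initial step size; default `keep_prob / L` with
#'   `L = (2/n) * sigma_max(X)^2`.
#' @param decay per-epoch step decay rate (default 0.02 when masking, 0 when
#'   `keep_prob = 1`).
#' @return a `penreg_fit` (objective reported on the unmasked lasso scale).
#' @export
fit_droplasso <- function(X, y, lambda, keep_prob = 0.5, n_epochs = 3000,
                          seed = 1, tol = 1e-7, step0 = NULL, decay = NULL) {
  X <- check_xy(X, y)
  spec <- penalty_spec("droplasso", lambda = lambda, keep_prob = keep_prob)
  L <- 2 * norm(X, "2")^2 / nrow(X)
  if (is.null(step0)) step0 <- keep_prob / L
  if (is.null(decay)) decay <- if (keep_prob < 1) 0.02 else 0
  if (step0 <= 0) stop2("step size must be positive")
  res <- with_seed(seed,
                   cpp_droplasso(X, y, lambda, keep_prob,
                                 as.integer(n_epochs), step0, decay, tol,
                                 keep_prob < 1))
  new_fit_result(res$beta, colnames(X),
                 enet_objective(X, y, res$beta, lambda, 0),
                 res$iters, res$converged || keep_prob < 1, spec)
}

# reorder columns so groups are contiguous; returns index bookkeeping
group_layout <- function(grouping, p) {
  g <- grouping$group_of_gene
  if (length(g) != p)
    stop2("grouping covers ", length(g), " genes but X has ", p, " columns")
  ord <- order(g, seq_along(g))
  gs <- g[ord]
  starts <- which(!duplicated(gs))
  ends <- c(starts[-1] - 1L, length(gs))
  sizes <- ends - starts + 1L
  list(ord = ord, inv = order(ord), gstart = starts - 1L, gend = ends - 1L,
       wj = sqrt(sizes))
}

#' Fit the group lasso
#'
#' Block coordinate descent on
#' `(1/n)||y - sum_j X_j b_j||^2 + lambda * sum_j sqrt(p_j) ||b_j||_2`,
#' the grouped penalty with kernel `K_j = p_j I`. A block is set to zero when
#' `||(2/n) X_j' r_j||_2 <= lambda sqrt(p_j)` (partial residual `r_j`);
#' nonzero blocks are solved exactly per sweep through the eigendecomposition
#' of the block Gram matrix and a one-dimensional root solve on the block
#' norm.
#'
#' @inheritParams fit_enet
#' @param grouping a [gene_grouping()] partitioning all columns of `X`.
#' @return a `penreg_fit`.
#' @export
fit_group_lasso <- function(X, y, grouping, lambda, tol = 1e-7,
                            max_iter = 1e5, track_objective = FALSE) {
  X <- check_xy(X, y)
  lay <- group_layout(grouping, ncol(X))
  res <- cpp_grouplasso_path(X[, lay$ord, drop = FALSE], y, lay$gstart,
                             lay$gend, lay$wj, lambda, tol,
                             as.integer(max_iter), track_objective)
  if (!res$converged[1])
    warning("fit_group_lasso: max_iter reached before convergence", call. = FALSE)
  beta <- res$beta[, 1][lay$inv]
  spec <- penalty_spec("grouplasso", lambda = lambda, grouping = grouping)
  out <- new_fit_result(beta, colnames(X),
                        sgl_objective(X, y, beta, lambda, 0, grouping),
                        res$iters[1], res$converged[1], spec)
  if (track_objective) out$objective_path <- res$objective[[1]]
  out
}

sgl_objective <- function(X, y, beta, lambda, alpha_mix, grouping) {
  r <- y - X %*% beta
  gnorm <- vapply(split(beta, grouping$group_of_gene),
                  function(b) sqrt(sum(b^2)), numeric(1))
  sizes <- vapply(split(beta, grouping$group_of_gene), length, numeric(1))
  sum(r^2) / length(y) +
    (1 - alpha_mix) * lambda * sum(sqrt(sizes) * gnorm) +
    alpha_mix * lambda * sum(abs(beta))
}

#' Fit the sparse group lasso
#'
#' Block coordinate descent on
#' `(1/n)||y - sum_j X_j b_j||^2 +
#'   (1-alpha) lambda sum_j sqrt(p_j) ||b_j||_2 + alpha lambda ||b||_1`,
#' sparse both across and within groups. The mixing convention carries the
#' `(1-alpha)` factor on the group term so that `alpha_mix = 1` recovers the
#' lasso exactly and `alpha_mix = 0` the group lasso. A block is zeroed when
#' the soft-thresholded block gradient satisfies
#' `||S(2/n X_j' r_j, alpha*lambda)||_2 <= (1-alpha) lambda sqrt(p_j)`;
#' surviving blocks are updated by proximal gradient steps (elementwise
#' soft-threshold followed by group shrinkage).
#'
#' @inheritParams fit_group_lasso
#' @param alpha_mix mixing parameter in `[0, 1]` (default 0.95).
#' @param inner_max maximum proximal steps per block update (default 100).
#' @return a `penreg_fit`.
#' @export
fit_sgl <- function(X, y, grouping, lambda, alpha_mix = 0.95, tol = 1e-7,
                    max_iter = 1e5, inner_max = 100, track_objective = FALSE) {
  X <- check_xy(X, y)
  if (alpha_mix < 0 || alpha_mix > 1) stop2("alpha_mix must lie in [0, 1]")
  lay <- group_layout(grouping, ncol(X))
  res <- cpp_sgl_path(X[, lay$ord, drop = FALSE], y, lay$gstart, lay$gend,
                      lay$wj, lambda, alpha_mix, tol, as.integer(max_iter),
                      as.integer(inner_max), track_objective)
  if (!res$converged[1])
    warning("fit_sgl: max_iter reached before convergence", call. = FALSE)
  beta <- res$beta[, 1][lay$inv]
  spec <- penalty_spec("sgl", lambda = lambda, alpha_mix = alpha_mix,
                       grouping = grouping)
  out <- new_fit_result(beta, colnames(X),
                        sgl_objective(X, y, beta, lambda, alpha_mix, grouping),
                        res$iters[1], res$converged[1], spec)
  if (track_objective) out$objective_path <- res$objective[[1]]
  out
}
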