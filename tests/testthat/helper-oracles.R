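# Shared fixtures and independent oracles used across test files.

# random instance with standardized columns (mean 0, population sd 1) and
# centered/scaled response, as the solvers expect
std_instance <- function(n, p, seed = 1, signal = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("g%03d", 1:p)))
  y <- if (is.null(signal)) rnorm(n) else as.numeric(X %*% signal + rnorm(n))
  std <- standardize_train_apply_test(X, NULL, y)
  list(X = std$train_x, y = std$train_y)
}

# design with X'X = n I so the lasso/ridge closed forms are exact
orthonormal_instance <- function(n, p, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)
  colnames(Q) <- sprintf("g%03d", 1:p)
  list(X = Q, y = rnorm(n))
}

# dense grid + Nelder-Mead polish minimizer for p <= 3 objectives
grid_polish <- function(obj, p, lim = 2, step = 0.1) {
  grid <- do.call(expand.grid, rep(list(seq(-lim, lim, by = step)), p))
  vals <- apply(grid, 1, function(b) obj(as.numeric(b)))
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 50000))
  # second polish from the first solution (Nelder-Mead on nonsmooth objectives)
  opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 50000))
  opt2$par
}

# brute-force pairwise Mann-Whitney AUC
auc_brute <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# independent Friedman statistic: explicit rank sums, loops only
friedman_brute <- function(m) {
  k <- nrow(m); n <- ncol(m)
  R <- numeric(k)
  for (d in seq_len(n)) {
    r <- rank(-m[, d], ties.method = "average")
    for (j in seq_len(k)) R[j] <- R[j] + r[j]
  }
  12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
}

# subgradient stationarity residual of the elastic-net objective
enet_stationarity <- function(X, y, beta, lambda1, lambda2) {
  n <- nrow(X)
  g <- as.numeric(-2 / n * crossprod(X, y - X %*% beta)) + 2 * lambda2 * beta
  res <- numeric(length(beta))
  for (j in seq_along(beta)) {
    if (beta[j] != 0) res[j] <- abs(g[j] + lambda1 * sign(beta[j]))
    else res[j] <- max(0, abs(g[j]) - lambda1)
  }
  max(res)
}

# subgradient stationarity residual of the SGL objective (group lasso at a=0)
sgl_stationarity <- function(X, y, beta, lambda, alpha, grouping) {
  n <- nrow(X)
  g <- as.numeric(-2 / n * crossprod(X, y - X %*% beta))
  res <- 0
  for (j in seq_len(grouping$J)) {
    idx <- which(grouping$group_of_gene == j)
    w <- sqrt(length(idx))
    bj <- beta[idx]; gj <- g[idx]
    if (any(bj != 0)) {
      grp <- (1 - alpha) * lambda * w * bj / sqrt(sum(bj^2))
      for (i in seq_along(idx)) {
        vi <- gj[i] + grp[i]
        ri <- if (bj[i] != 0) abs(vi + alpha * lambda * sign(bj[i]))
              else max(0, abs(vi) - alpha * lambda)
        res <- max(res, ri)
      }
    } else {
      v <- soft_threshold(gj, alpha * lambda)
      res <- max(res, max(0, sqrt(sum(v^2)) - (1 - alpha) * lambda * w))
    }
  }
  res
}

# adjusted Rand index between two partitions (Hubert-Arabie)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# small labeled dataset for pipeline-level tests (fast defaults)
small_sim <- function(seed = 7, n = 40, p = 200, n_de = 10) {
  generate_dataset(sim_params(
    n_per_class = c(n, n), p_genes = p, n_de = n_de, effect = 2,
    n_invariant = 3, dropout_prob = 0.3, seed = seed,
    group_blocks = c(rep(list(c(5, 0.6)), 2), rep(list(c(10, 0.4)), 3))))
}

fast_config <- function(...) {
  do.call(pipeline_config, utils::modifyList(
    list(seed = 1, k_folds = 5, inner_folds = 4, n_lambda = 30,
         droplasso_epochs = 400),
    list(...)))
}
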