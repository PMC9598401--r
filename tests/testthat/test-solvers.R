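test_that("soft threshold follows its definition", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(c(-2, 0.3, 5), 0), c(-2, 0.3, 5))
  expect_equal(soft_threshold(c(-2, 2), 1.5), c(-0.5, 0.5))
  expect_error(soft_threshold(1, -1), "nonnegative")
})

test_that("ridge closed form solves the stationarity system", {
  # 2x2 identity design, n = 2: beta_i = y_i / (1 + n*lambda)
  b <- ridge_closed_form(diag(2), c(1, 0), 0.5)
  expect_equal(unname(b), c(0.5, 0))

  # lambda = 0 on invertible square X is OLS
  set.seed(2)
  X <- matrix(rnorm(9), 3, 3)
  y <- rnorm(3)
  expect_equal(ridge_closed_form(X, y, 0), solve(X, y), tolerance = 1e-8)

  # huge lambda shrinks essentially to zero
  inst <- std_instance(10, 5, seed = 3)
  expect_lt(max(abs(ridge_closed_form(inst$X, inst$y, 1e6))), 1e-4)

  # stationarity residual: (2/n) X'(Xb - y) + 2*lambda*b = 0
  b2 <- ridge_closed_form(inst$X, inst$y, 0.3)
  g <- 2 / 10 * crossprod(inst$X, inst$X %*% b2 - inst$y) + 2 * 0.3 * b2
  expect_lt(max(abs(g)), 1e-10)

  # n < p kernel route agrees with the primal system
  inst2 <- std_instance(8, 12, seed = 4)
  b3 <- ridge_closed_form(inst2$X, inst2$y, 0.2)
  prim <- solve(crossprod(inst2$X) + 8 * 0.2 * diag(12),
                crossprod(inst2$X, inst2$y))
  expect_equal(unname(b3), as.numeric(prim), tolerance = 1e-8)
})

test_that("elastic net matches orthonormal-design closed forms", {
  # identity design, n = 2: per-coordinate minimizer is soft(y_j, lambda/2)/(1/2+..)
  f <- fit_enet(diag(2), c(1, 0.4), lambda = 0.5, alpha_mix = 1)
  expect_equal(unname(coef(f)), c(0.5, 0))

  # X'X = n I: lasso closed form soft(x_j'y/n, lambda/2)
  inst <- orthonormal_instance(12, 6, seed = 5)
  for (lam in c(0.05, 0.3, 1)) {
    fit <- fit_enet(inst$X, inst$y, lam, alpha_mix = 1)
    oracle <- soft_threshold(crossprod(inst$X, inst$y) / 12, lam / 2)
    expect_equal(unname(coef(fit)), as.numeric(oracle), tolerance = 1e-8)
  }
})

test_that("elastic net limits recover ridge, and lambda_max nulls the model", {
  for (s in 1:3) {
    inst <- std_instance(20, 10, seed = s)
    # alpha 0 at lambda matches the closed-form ridge at lambda/2 (the
    # (1-alpha)/2 convention)
    f0 <- fit_enet(inst$X, inst$y, 0.7, alpha_mix = 0, tol = 1e-11)
    expect_equal(coef(f0), ridge_closed_form(inst$X, inst$y, 0.35),
                 tolerance = 1e-8)
  }
  inst <- std_instance(30, 20, seed = 9)
  lam_max <- compute_lambda_path(inst$X, inst$y, "lasso")$lambda_max
  expect_true(all(coef(fit_enet(inst$X, inst$y, lam_max * 1.000001, 1)) == 0))
})

test_that("coordinate descent satisfies stationarity and decreases the objective", {
  for (s in 1:3) {
    inst <- std_instance(25, 15, seed = s + 10)
    for (a in c(1, 0.5)) {
      fit <- fit_enet(inst$X, inst$y, 0.15, alpha_mix = a, tol = 1e-9,
                      track_objective = TRUE)
      spec <- fit$spec
      expect_true(fit$converged)
      expect_lt(enet_stationarity(inst$X, inst$y, coef(fit),
                                  spec$lambda1, spec$lambda2), 1e-7)
      expect_true(all(diff(fit$objective_path) <= 1e-12))
    }
  }
})

test_that("group lasso zero test, unpenalized limit and singleton reduction hold", {
  # one group of 2, identity design: ||(1, .4)|| = 1.077 <= lambda*sqrt(2)
  g2 <- gene_grouping(c(1, 1))
  f <- fit_group_lasso(diag(2), c(1, 0.4), g2, lambda = 1)
  expect_true(all(coef(f) == 0))
  # just below the group threshold the block activates
  thr <- sqrt(sum(c(1, 0.4)^2)) / sqrt(2)
  f2 <- fit_group_lasso(diag(2), c(1, 0.4), g2, lambda = thr * 0.98)
  expect_true(any(coef(f2) != 0))

  # lambda = 0 on a well-conditioned instance is OLS
  inst <- std_instance(30, 5, seed = 21)
  fols <- fit_group_lasso(inst$X, inst$y, gene_grouping(c(1, 1, 2, 2, 2)), 0)
  ols <- solve(crossprod(inst$X), crossprod(inst$X, inst$y))
  expect_equal(unname(coef(fols)), as.numeric(ols), tolerance = 1e-6)

  # singleton groups reduce to the lasso
  inst2 <- std_instance(30, 20, seed = 22)
  fl <- fit_enet(inst2$X, inst2$y, 0.2, alpha_mix = 1)
  fg <- fit_group_lasso(inst2$X, inst2$y, gene_grouping(1:20), 0.2)
  expect_equal(coef(fg), coef(fl), tolerance = 1e-6)
})

test_that("SGL interpolates between lasso and group lasso and is stationary", {
  for (s in 1:3) {
    inst <- std_instance(30, 20, seed = s + 30)
    g <- gene_grouping(rep(1:4, each = 5))
    f1 <- fit_sgl(inst$X, inst$y, g, 0.2, alpha_mix = 1)
    expect_equal(coef(f1), coef(fit_enet(inst$X, inst$y, 0.2, 1)),
                 tolerance = 1e-4)
    f0 <- fit_sgl(inst$X, inst$y, g, 0.2, alpha_mix = 0)
    expect_equal(coef(f0), coef(fit_group_lasso(inst$X, inst$y, g, 0.2)),
                 tolerance = 1e-4)
    fm <- fit_sgl(inst$X, inst$y, g, 0.25, alpha_mix = 0.95, tol = 1e-9,
                  track_objective = TRUE)
    expect_lt(sgl_stationarity(inst$X, inst$y, coef(fm), 0.25, 0.95, g), 1e-6)
    expect_true(all(diff(fm$objective_path) <= 1e-12))
  }

  # large lambda gives the null model
  inst <- std_instance(30, 20, seed = 41)
  g <- gene_grouping(rep(1:4, each = 5))
  expect_true(all(coef(fit_sgl(inst$X, inst$y, g, 50, 0.95)) == 0))

  expect_error(fit_sgl(std_instance(10, 4)$X, std_instance(10, 4)$y,
                       gene_grouping(c(1, 1, 2)), 0.1),
               "grouping covers 3 genes")
})

test_that("group lasso per-sweep objective is monotone", {
  inst <- std_instance(40, 12, seed = 51, signal = c(rep(1, 3), rep(0, 9)))
  g <- gene_grouping(rep(1:4, each = 3))
  fit <- fit_group_lasso(inst$X, inst$y, g, 0.3, track_objective = TRUE)
  expect_true(all(diff(fit$objective_path) <= 1e-12))
})

test_that("drop lasso reduces to the lasso without masking and is seed-stable", {
  inst <- std_instance(30, 20, seed = 61)
  fl <- fit_enet(inst$X, inst$y, 0.2, 1)
  fd <- fit_droplasso(inst$X, inst$y, 0.2, keep_prob = 1, n_epochs = 20000)
  expect_equal(coef(fd), coef(fl), tolerance = 1e-4)

  lam_max <- compute_lambda_path(inst$X, inst$y, "lasso")$lambda_max
  fz <- fit_droplasso(inst$X, inst$y, lam_max * 10, keep_prob = 0.6,
                      n_epochs = 200, seed = 3)
  expect_true(all(coef(fz) == 0))

  fa <- fit_droplasso(inst$X, inst$y, 0.2, keep_prob = 0.5, seed = 7,
                      n_epochs = 300)
  fb <- fit_droplasso(inst$X, inst$y, 0.2, keep_prob = 0.5, seed = 7,
                      n_epochs = 300)
  expect_identical(coef(fa), coef(fb))
  expect_error(fit_droplasso(inst$X, inst$y, 0.2, step0 = -1), "positive")
})

test_that("big-lasso objective delegates exactly to the lasso", {
  inst <- std_instance(25, 10, seed = 71)
  fb <- fit_biglasso_objective(inst$X, inst$y, 0.15)
  fl <- fit_enet(inst$X, inst$y, 0.15, 1)
  expect_identical(unname(coef(fb)), unname(coef(fl)))
  expect_equal(fb$spec$kind, "biglasso")
  lam_max <- compute_lambda_path(inst$X, inst$y, "biglasso")$lambda_max
  expect_true(all(coef(fit_biglasso_objective(inst$X, inst$y, lam_max * 1.01)) == 0))
})

test_that("cross-penalty equivalences hold on grouped 30x20 instances", {
  for (s in 1:2) {
    inst <- std_instance(30, 20, seed = 100 + s,
                         signal = c(rep(0.8, 4), rep(0, 16)))
    g <- gene_grouping(rep(1:4, each = 5))
    lam <- 0.3
    lasso <- coef(fit_enet(inst$X, inst$y, lam, 1))
    expect_equal(coef(fit_sgl(inst$X, inst$y, g, lam, 1)), lasso,
                 tolerance = 1e-4)
    expect_equal(coef(fit_sgl(inst$X, inst$y, g, lam, 0)),
                 coef(fit_group_lasso(inst$X, inst$y, g, lam)),
                 tolerance = 1e-4)
    expect_equal(coef(fit_droplasso(inst$X, inst$y, lam, keep_prob = 1,
                                    n_epochs = 20000)),
                 lasso, tolerance = 1e-4)
    expect_equal(coef(fit_group_lasso(inst$X, inst$y, gene_grouping(1:20), lam)),
                 lasso, tolerance = 1e-4)
  }
})

test_that("coordinate descent agrees with glmnet under its loss convention", {
  skip_if_not_installed("glmnet")
  # glmnet minimizes 1/(2n)||y-Xb||^2 + lam_g (a||b||_1 + (1-a)/2 ||b||_2^2);
  # our (1/n) loss at (lambda, alpha) corresponds to lam_g = lambda/2 at the
  # same alpha
  for (s in 1:2) {
    inst <- std_instance(40, 15, seed = 80 + s,
                         signal = c(rep(1, 3), rep(0, 12)))
    for (a in c(1, 0.5)) {
      lam <- 0.3
      ours <- coef(fit_enet(inst$X, inst$y, lam, a, tol = 1e-10))
      gl <- glmnet::glmnet(inst$X, inst$y, alpha = a, lambda = lam / 2,
                           standardize = FALSE, intercept = FALSE,
                           thresh = 1e-14)
      expect_equal(unname(ours), as.numeric(gl$beta), tolerance = 1e-5)
    }
  }
})
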