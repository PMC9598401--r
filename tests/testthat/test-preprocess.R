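make_expr <- function(n, p, seed = 1, cells = sprintf("c%d", 1:n)) {
  set.seed(seed)
  expression_matrix(matrix(abs(rnorm(n * p)), n, p,
                           dimnames = list(cells, sprintf("g%d", 1:p))))
}

test_that("class assignment maps groups to labels and drops the rest", {
  em <- make_expr(5, 3)
  grp <- c(c1 = "a", c2 = "a", c3 = "b", c4 = "b", c5 = "c")
  ds <- assign_binary_classes(em, grp, class1_group = "a", class0_group = "b")
  expect_equal(nrow(ds$expr), 4)
  expect_equal(unname(ds$labels), c(1L, 1L, 0L, 0L))
  expect_equal(ds$class_names[["1"]], "a")

  expect_error(assign_binary_classes(em, grp, "a", "a"), "must differ")
  expect_error(assign_binary_classes(em, grp, "a", "zz"), "zero cells")

  # imbalanced group sizes carry through (183 vs 84 structure)
  em2 <- make_expr(267, 2, cells = sprintf("c%d", 1:267))
  grp2 <- setNames(rep(c("mesc", "ko"), c(183, 84)), rownames(em2))
  ds2 <- assign_binary_classes(em2, grp2, "mesc", "ko")
  expect_equal(sum(ds2$labels == 1), 183)
  expect_equal(sum(ds2$labels == 0), 84)
})

test_that("within-class shuffling permutes rows without crossing classes", {
  em <- make_expr(10, 4)
  ds <- labeled_dataset(em, rep(c(1, 0), each = 5))

  s1 <- shuffle_within_class(ds, seed = 42)
  s2 <- shuffle_within_class(ds, seed = 42)
  expect_identical(rownames(s1$expr), rownames(s2$expr))  # determinism

  # labels stay attached to their rows: multiset of (label, row) preserved
  for (cl in c(0, 1)) {
    orig <- unclass(ds$expr)[ds$labels == cl, ]
    shuf <- unclass(s1$expr)[s1$labels == cl, ]
    expect_equal(orig[order(rownames(orig)), ], shuf[order(rownames(shuf)), ])
  }

  # one cell per class is a fixed point
  ds1 <- labeled_dataset(make_expr(2, 3), c(1, 0))
  expect_identical(shuffle_within_class(ds1, 5)$labels, ds1$labels)
})

test_that("invariant-gene removal matches a brute-force variance scan", {
  set.seed(3)
  m <- matrix(rnorm(60), 6, 10, dimnames = list(sprintf("c%d", 1:6),
                                                sprintf("g%d", 1:10)))
  m[, c(2, 5, 9)] <- 5.0
  ds <- labeled_dataset(expression_matrix(abs(m) + 1e-3), rep(c(1, 0), 3))
  # force exact constancy after the abs transform
  x <- unclass(ds$expr); x[, c(2, 5, 9)] <- 5.0
  ds <- labeled_dataset(expression_matrix(x), ds$labels)

  out <- remove_invariant_genes(ds)
  brute <- colnames(x)[apply(x, 2, function(col) var(col) > 0)]
  expect_identical(colnames(out$dataset$expr), brute)
  expect_identical(out$removed, c("g2", "g5", "g9"))

  # identity case
  out2 <- remove_invariant_genes(out$dataset)
  expect_length(out2$removed, 0)
  expect_identical(out2$dataset$expr, out$dataset$expr)

  allflat <- labeled_dataset(expression_matrix(matrix(1, 4, 3,
      dimnames = list(letters[1:4], c("g1", "g2", "g3")))), c(1, 1, 0, 0))
  expect_error(remove_invariant_genes(allflat), "all genes")
})

test_that("majority-class subsampling balances classes deterministically", {
  em <- make_expr(130, 3)
  ds <- labeled_dataset(em, rep(c(1, 0), c(100, 30)))
  b <- balance_by_subsampling(ds, seed = 9)
  expect_equal(sum(b$labels == 1), 30)
  expect_equal(sum(b$labels == 0), 30)
  # kept majority cells are a subset of the originals
  expect_true(all(names(b$labels)[b$labels == 1] %in%
                    names(ds$labels)[ds$labels == 1]))
  expect_identical(names(balance_by_subsampling(ds, 9)$labels),
                   names(b$labels))
  # already balanced -> untouched
  ds2 <- labeled_dataset(make_expr(80, 3), rep(c(1, 0), each = 40))
  expect_identical(balance_by_subsampling(ds2, 1), ds2)
})

test_that("standardization uses train statistics and the population sd", {
  tr <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "g1"))
  te <- matrix(2, 1, 1, dimnames = list(NULL, "g1"))
  out <- standardize_train_apply_test(tr, te, c(0, 1, 1))
  # population sd of (1,2,3) is sqrt(2/3); (x - 2)/sd
  expect_equal(as.numeric(out$train_x), c(-1, 0, 1) / sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(as.numeric(out$train_x), c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)
  # test value equal to the train mean maps to 0
  expect_equal(as.numeric(out$test_x), 0)
  # standardized columns satisfy sum = 0, ||x||^2 = n
  expect_equal(sum(out$train_x), 0, tolerance = 1e-12)
  expect_equal(sum(out$train_x^2), 3, tolerance = 1e-12)
  # idempotence
  again <- standardize_train_apply_test(out$train_x, NULL, out$train_y)
  expect_equal(again$train_x, out$train_x, tolerance = 1e-12)

  expect_error(standardize_train_apply_test(cbind(tr, g2 = c(4, 4, 4)),
                                            NULL, c(0, 1, 1)),
               "zero-variance")
})

test_that("stratified folds balance both classes and enforce preconditions", {
  y <- rep(c(1, 0), each = 50)
  fs <- make_stratified_folds(y, k = 10, seed = 2)
  tab <- table(fs$assignments, y)
  expect_true(all(tab == 5))  # exactly 5 of each class per fold

  expect_error(make_stratified_folds(rep(c(1, 0), c(7, 93)), k = 10),
               "class 1")

  # 13 + 17 cells, k = 5: per-class fold sizes within one of each other
  y2 <- rep(c(0, 1), c(13, 17))
  fs2 <- make_stratified_folds(y2, k = 5, seed = 11)
  t2 <- table(fs2$assignments, y2)
  expect_true(all(t2[, "0"] %in% c(2, 3)))
  expect_true(all(t2[, "1"] %in% c(3, 4)))
  expect_equal(sum(t2), 30)
  # every cell in exactly one fold
  expect_length(fs2$assignments, 30)
  expect_setequal(unique(fs2$assignments), 1:5)
})

test_that("balanced subsampling plus stratified folds keep both classes per fold", {
  set.seed(4)
  for (s in 1:3) {
    ds <- labeled_dataset(make_expr(90, 3, seed = s), rep(c(1, 0), c(60, 30)))
    b <- balance_by_subsampling(ds, seed = s)
    fs <- make_stratified_folds(b$labels, k = 5, seed = s)
    tab <- table(fs$assignments, b$labels)
    expect_true(all(tab > 0))
  }
})
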