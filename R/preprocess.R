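#' Assign binary classes to two cell groups
#'
#' Builds a binary classification problem from a cell-to-group mapping: cells
#' in `class1_group` are labeled 1, cells in `class0_group` are labeled 0, and
#' every other cell is dropped.
#'
#' @param expr an [expression_matrix()].
#' @param group_of_cell named character vector (or two-column data frame of
#'   `cell_id`, `group`) mapping every cell id in `expr` to a group name.
#' @param class1_group,class0_group the two group names to keep.
#' @return a `labeled_dataset`: list with `expr` (subset of cells), `labels`
#'   (named 0/1 vector) and `class_names` (names of classes 0 and 1).
#' @export
assign_binary_classes <- function(expr, group_of_cell, class1_group, class0_group) {
  if (is.data.frame(group_of_cell)) {
    g <- as.character(group_of_cell[[2]])
    names(g) <- as.character(group_of_cell[[1]])
    group_of_cell <- g
  }
  if (identical(class1_group, class0_group))
    stop2("class1_group and class0_group must differ")
  cells <- rownames(expr)
  missing_cells <- setdiff(cells, names(group_of_cell))
  if (length(missing_cells))
    stop2("no group recorded for cells: ",
          paste(utils::head(missing_cells, 5), collapse = ", "))
  grp <- group_of_cell[cells]
  keep1 <- cells[grp == class1_group]
  keep0 <- cells[grp == class0_group]
  if (!length(keep1)) stop2("group '", class1_group, "' matches zero cells")
  if (!length(keep0)) stop2("group '", class0_group, "' matches zero cells")
  keep <- cells[grp %in% c(class1_group, class0_group)]
  labels <- as.integer(grp[keep] == class1_group)
  names(labels) <- keep
  labeled_dataset(expression_matrix(unclass(expr)[keep, , drop = FALSE]),
                  labels,
                  class_names = c(`0` = class0_group, `1` = class1_group))
}

#' Bundle an expression matrix with binary cell labels
#'
#' @param expr an [expression_matrix()].
#' @param labels 0/1 integer vector, one per cell (row of `expr`); both
#'   classes must be present.
#' @param class_names optional names of the two classes (`"0"`, `"1"`).
#' @return an object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(expr, labels, class_names = c(`0` = "0", `1` = "1")) {
  labels <- as.integer(labels)
  if (length(labels) != nrow(expr))
    stop2("labels length (", length(labels), ") != number of cells (", nrow(expr), ")")
  if (!all(labels %in% c(0L, 1L))) stop2("labels must be 0/1")
  if (!any(labels == 0L) || !any(labels == 1L))
    stop2("both classes must be present")
  if (is.null(names(labels))) names(labels) <- rownames(expr)
  structure(list(expr = expr, labels = labels, class_names = class_names),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled dataset: %d cells x %d genes (class 1 '%s': %d, class 0 '%s': %d)\n",
              nrow(x$expr), ncol(x$expr),
              x$class_names[["1"]], sum(x$labels == 1),
              x$class_names[["0"]], sum(x$labels == 0)))
  invisible(x)
}

#' Shuffle cells within each class
#'
#' Randomizes row order separately inside each class, so the multiset of
#' (label, expression row) pairs is unchanged and rows never cross classes.
#' Deterministic for a fixed seed.
#'
#' @param ds a [labeled_dataset()].
#' @param seed integer seed.
#' @return a shuffled `labeled_dataset`.
#' @export
shuffle_within_class <- function(ds, seed) {
  ord <- with_seed(seed, {
    idx <- seq_along(ds$labels)
    out <- idx
    for (cl in c(1L, 0L)) {
      w <- idx[ds$labels == cl]
      out[ds$labels == cl] <- if (length(w) > 1) sample(w) else w
    }
    out
  })
  labeled_dataset(expression_matrix(unclass(ds$expr)[ord, , drop = FALSE]),
                  ds$labels[ord], ds$class_names)
}

#' Remove genes with no expression variability
#'
#' Drops every gene whose expression is constant across all cells (sample
#' variance zero); retained gene order is preserved.
#'
#' @param ds a [labeled_dataset()].
#' @return list with `dataset` (filtered) and `removed` (dropped gene ids).
#' @export
remove_invariant_genes <- function(ds) {
  x <- unclass(ds$expr)
  v <- col_sd_pop(x)
  keep <- v > 0
  if (!any(keep)) stop2("all genes are invariant; nothing to model")
  list(dataset = labeled_dataset(
         expression_matrix(x[, keep, drop = FALSE]), ds$labels, ds$class_names),
       removed = colnames(x)[!keep])
}

#' Balance classes by subsampling the majority class
#'
#' The minority class is kept intact; the majority class is subsampled
#' without replacement down to the minority size. Deterministic for a fixed
#' seed; a no-op when classes are already balanced.
#'
#' @param ds a [labeled_dataset()].
#' @param seed integer seed.
#' @return a balanced `labeled_dataset`.
#' @export
balance_by_subsampling <- function(ds, seed) {
  n1 <- sum(ds$labels == 1L); n0 <- sum(ds$labels == 0L)
  if (n1 == n0) return(ds)
  maj <- if (n1 > n0) 1L else 0L
  target <- min(n1, n0)
  keep <- with_seed(seed, {
    idx_maj <- which(ds$labels == maj)
    sort(c(which(ds$labels != maj), sample(idx_maj, target)))
  })
  labeled_dataset(expression_matrix(unclass(ds$expr)[keep, , drop = FALSE]),
                  ds$labels[keep], ds$class_names)
}

#' Standardize training data and apply the transform to test data
#'
#' Centers and scales each training column to mean 0 and population (1/n)
#' standard deviation 1, then transforms the test block with the *training*
#' parameters; the response is centered and scaled by its training statistics
#' the same way. With this convention every standardized training column x
#' satisfies sum(x) = 0 and ||x||^2 = n, which the solvers' closed-form
#' thresholds assume.
#'
#' @param train_x,test_x numeric matrices with identical columns (`test_x`
#'   may be `NULL`).
#' @param train_y numeric response for the training rows.
#' @return list with `train_x`, `test_x`, `train_y` (standardized),
#'   `center`/`scale` per column and `y_center`/`y_scale`.
#' @export
standardize_train_apply_test <- function(train_x, test_x = NULL, train_y = NULL) {
  train_x <- as.matrix(train_x)
  ctr <- colMeans(train_x)
  scl <- col_sd_pop(train_x)
  if (any(scl == 0))
    stop2("zero-variance training column(s): ",
          paste(utils::head(colnames(train_x)[scl == 0] %||%
                              which(scl == 0), 5), collapse = ", "),
          "; run remove_invariant_genes on this fold first")
  tx <- sweep(sweep(train_x, 2, ctr), 2, scl, "/")
  sx <- if (!is.null(test_x))
    sweep(sweep(as.matrix(test_x), 2, ctr), 2, scl, "/") else NULL
  yc <- ys <- NULL; ty <- NULL
  if (!is.null(train_y)) {
    yc <- mean(train_y)
    ys <- sqrt(mean((train_y - yc)^2))
    if (ys == 0) stop2("training response is constant")
    ty <- (train_y - yc) / ys
  }
  list(train_x = tx, test_x = sx, train_y = ty,
       center = ctr, scale = scl, y_center = yc, y_scale = ys)
}

#' Build stratified cross-validation folds
#'
#' Assigns each cell to one of `k` folds such that, within each class, fold
#' sizes differ by at most one. Deterministic for a fixed seed.
#'
#' @param labels 0/1 vector.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return an object of class `fold_spec`: list with `k`, `assignments`
#'   (fold index 1..k per cell) and `seed`.
#' @export
make_stratified_folds <- function(labels, k = 10, seed = 1) {
  labels <- as.integer(labels)
  for (cl in c(0L, 1L)) {
    n_cl <- sum(labels == cl)
    if (n_cl < k)
      stop2("class ", cl, " has ", n_cl, " cells, fewer than k = ", k, " folds")
  }
  assignments <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      idx <- if (length(idx) > 1) sample(idx) else idx
      assignments[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = k, assignments = assignments, seed = seed),
            class = "fold_spec")
}
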