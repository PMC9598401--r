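#' Pipeline configuration
#'
#' Defaults mirror the benchmark hyperparameter conventions used throughout
#' the package: stage 1 fits ridge (`alpha = 0`), lasso (`alpha = 1`) and
#' elastic net (`alpha = 0.5`) with the one-standard-error lambda rule and
#' drop lasso at fixed `lambda = 0.001`; stage 2 fits the sparse group lasso
#' at `alpha = 0.95` with the minimum-error lambda rule on hierarchically
#' clustered gene groups.
#'
#' @param seed master seed; all fold splits, masks and restarts derive from it.
#' @param k_folds outer cross-validation folds (default 10).
#' @param inner_folds folds for nested lambda selection inside each outer
#'   training split (default 5).
#' @param n_lambda,ratio lambda path controls (see [compute_lambda_path()]).
#' @param enet_alpha elastic-net mixing (default 0.5).
#' @param droplasso_lambda fixed drop-lasso penalty (default 0.001).
#' @param keep_prob drop-lasso mask retention probability (default 0.5).
#' @param droplasso_epochs drop-lasso epochs (default 1500).
#' @param sgl_alpha SGL mixing (default 0.95).
#' @param sgl_rule lambda rule for SGL (default `"min"`).
#' @param stage1_rule lambda rule for ridge/lasso/enet (default `"1se"`).
#' @param n_groups hierarchical-clustering group count: `"auto"` for
#'   `round(sqrt(pool size))` clamped to `[2, pool size]`, or an integer.
#' @param linkage,metric gene clustering options (see [cluster_genes()]).
#' @param elbow `"auto"` or a manual override count.
#' @param kmeans_k,n_init final cell clustering options.
#' @param tol,max_iter solver controls.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, k_folds = 10, inner_folds = 5,
                            n_lambda = 100, ratio = NULL,
                            enet_alpha = 0.5, droplasso_lambda = 0.001,
                            keep_prob = 0.5, droplasso_epochs = 1500,
                            sgl_alpha = 0.95, sgl_rule = "min",
                            stage1_rule = "1se", n_groups = "auto",
                            linkage = "ward", metric = "euclidean",
                            elbow = "auto", kmeans_k = 2, n_init = 10,
                            tol = 1e-7, max_iter = 1e5) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Stage-1 gene pool: union of top genes from four penalized fits
#'
#' Fits ridge, lasso and elastic net with nested cross-validated lambda
#' selection (one-standard-error rule) and drop lasso at its fixed lambda on
#' one training split, takes each method's top genes by the
#' mean-absolute-coefficient cutoff, and unions them into a gene pool.
#'
#' @param X_train raw training expression matrix (cells x genes, no constant
#'   columns).
#' @param y_train 0/1 training labels.
#' @param config a [pipeline_config()].
#' @param seed seed for the inner fold split and drop-lasso masks.
#' @return list with `pool` (a [build_gene_pool()] result), `sets` (per-method
#'   top-gene sets) and `coefs` (per-method standardized coefficient vectors).
#' @export
build_stage1_pool <- function(X_train, y_train, config = pipeline_config(),
                              seed = config$seed) {
  X_train <- as.matrix(X_train)
  inner <- make_stratified_folds(y_train, k = config$inner_folds, seed = seed)
  coefs <- list()
  for (kind in c("ridge", "lasso", "enet")) {
    spec <- penalty_spec(kind, alpha_mix = switch(kind, ridge = 0,
                                                  lasso = 1, enet = config$enet_alpha))
    cv <- cv_select_lambda(X_train, y_train, spec, folds = inner,
                           rule = config$stage1_rule,
                           n_values = config$n_lambda, ratio = config$ratio,
                           tol = config$tol, max_iter = config$max_iter)
    coefs[[kind]] <- cv$fit$coefficients
  }
  std <- standardize_train_apply_test(X_train, NULL, y_train)
  dl <- fit_droplasso(std$train_x, std$train_y, config$droplasso_lambda,
                      keep_prob = config$keep_prob,
                      n_epochs = config$droplasso_epochs, seed = seed,
                      tol = config$tol)
  coefs[["droplasso"]] <- dl$coefficients
  sets <- lapply(coefs, select_top_genes)
  pool <- build_gene_pool(sets, gene_order = colnames(X_train))
  list(pool = pool, sets = sets, coefs = coefs)
}

#' Run the two-stage feature-selection pipeline
#'
#' End-to-end procedure on a labeled dataset: shuffle cells within class,
#' drop invariant genes, build stratified outer folds; within every outer
#' training split build the stage-1 gene pool ([build_stage1_pool()]), group
#' the pooled genes by hierarchical clustering, fit the sparse group lasso
#' with nested lambda selection, and score the held-out fold; finally average
#' the SGL coefficients per gene across folds (absent genes contribute zero),
#' rank by mean magnitude, cut at the automatic elbow, and cluster all cells
#' by K-means on the final genes.
#'
#' @param ds a [labeled_dataset()].
#' @param config a [pipeline_config()].
#' @return an object of class `sgl_selection` with the ranked gene table,
#'   elbow index, final gene set, per-fold AUC, pool bookkeeping and cell
#'   clusters.
#' @export
run_selection_pipeline <- function(ds, config = pipeline_config()) {
  stopifnot(inherits(ds, "labeled_dataset"))
  ds <- shuffle_within_class(ds, config$seed)
  ri <- remove_invariant_genes(ds)
  ds <- ri$dataset
  X <- unclass(ds$expr)
  y <- ds$labels
  p_var <- ncol(X)
  folds <- make_stratified_folds(y, k = config$k_folds, seed = config$seed)

  k <- folds$k
  fold_coefs <- vector("list", k)
  per_fold_auc <- numeric(k)
  pool_sizes <- integer(k)

  for (f in seq_len(k)) {
    te <- which(folds$assignments == f)
    tr <- which(folds$assignments != f)
    keep <- col_sd_pop(X[tr, , drop = FALSE]) > 0
    Xtr <- X[tr, keep, drop = FALSE]
    Xte <- X[te, keep, drop = FALSE]

    st1 <- build_stage1_pool(Xtr, y[tr], config,
                             seed = config$seed * 1000 + f)
    pool <- st1$pool$gene_ids
    if (!length(pool)) stop2("fold ", f, ": stage-1 gene pool is empty")
    pool_sizes[f] <- length(pool)

    Xtr_pool <- Xtr[, pool, drop = FALSE]
    J <- if (identical(config$n_groups, "auto"))
      min(max(2L, round(sqrt(length(pool)))), length(pool))
    else min(as.integer(config$n_groups), length(pool))
    grouping <- cluster_genes(Xtr_pool, J, linkage = config$linkage,
                              metric = config$metric)

    inner <- make_stratified_folds(y[tr], k = config$inner_folds,
                                   seed = config$seed * 1000 + f)
    cv <- cv_select_lambda(Xtr_pool, y[tr],
                           penalty_spec("sgl", alpha_mix = config$sgl_alpha,
                                        grouping = grouping),
                           folds = inner, rule = config$sgl_rule,
                           n_values = config$n_lambda, ratio = config$ratio,
                           tol = config$tol, max_iter = config$max_iter)

    Zte <- sweep(sweep(Xte[, pool, drop = FALSE], 2, cv$center), 2,
                 cv$scale, "/")
    scores <- as.numeric(Zte %*% cv$fit$coefficients)
    per_fold_auc[f] <- roc_auc(y[te], scores)$auc
    fold_coefs[[f]] <- cv$fit$coefficients
  }

  union_pool <- colnames(X)[colnames(X) %in%
                              unique(unlist(lapply(fold_coefs, names)))]
  aligned <- lapply(fold_coefs, function(v) {
    out <- stats::setNames(numeric(length(union_pool)), union_pool)
    out[names(v)] <- v
    out
  })
  ranked <- average_fold_coefficients(aligned)
  n_keep <- elbow_cutoff(abs(ranked$mean_coefficient),
                         override = if (identical(config$elbow, "auto")) NULL
                                    else as.integer(config$elbow))
  final_genes <- ranked$gene_id[seq_len(n_keep)]

  Zfin <- scale(X[, final_genes, drop = FALSE])
  clusters <- cluster_cells_kmeans(Zfin, k_clusters = config$kmeans_k,
                                   seed = config$seed, n_init = config$n_init)

  structure(list(ranked = ranked, elbow_index = n_keep,
                 final_genes = final_genes,
                 per_fold_auc = per_fold_auc,
                 auc = aggregate_cv_auc(per_fold_auc),
                 cell_clusters = clusters,
                 labels = y,
                 union_pool = union_pool,
                 pool_sizes = pool_sizes,
                 pool_fraction = pool_sizes / p_var,
                 n_variable_genes = p_var,
                 removed_invariant = ri$removed,
                 folds = folds, config = config),
            class = "sgl_selection")
}

#' @export
print.sgl_selection <- function(x, ...) {
  cat("two-stage penalized feature selection\n")
  cat(sprintf("  variable genes: %d; mean stage-1 pool: %.1f (%.1f%% of variable genes)\n",
              x$n_variable_genes, mean(x$pool_sizes),
              100 * mean(x$pool_fraction)))
  cat(sprintf("  ranked genes: %d; final set after elbow: %d\n",
              nrow(x$ranked), length(x$final_genes)))
  cat(sprintf("  CV-AUC: mean %.3f, variance %.4g over %d folds\n",
              x$auc$mean, x$auc$variance, length(x$per_fold_auc)))
  invisible(x)
}

#' @export
summary.sgl_selection <- function(object, n = 10, ...) {
  print(object)
  cat("\ntop ranked genes:\n")
  print(utils::head(object$ranked, n), row.names = FALSE)
  invisible(object)
}

#' @export
coef.sgl_selection <- function(object, ...) object$ranked

#' @export
plot.sgl_selection <- function(x, ...) {
  graphics::plot(x$ranked$rank, abs(x$ranked$mean_coefficient), type = "b",
                 pch = 20, xlab = "gene rank",
                 ylab = "|mean coefficient| across folds", ...)
  graphics::abline(v = x$elbow_index + 0.5, lty = 2, col = "red")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes (a) `ranked_genes.tsv` (gene_id, mean_coefficient, rank), (b)
#' `final_genes.txt` (one id per line), (c) `metrics.json` (per-fold AUC,
#' mean, variance) and (d) `coefficient_plot.csv` (rank vs magnitude, the
#' gene-versus-coefficient curve behind the elbow).
#'
#' @param result an `sgl_selection`.
#' @param out_dir output directory (created if missing).
#' @return character vector of the written file paths, invisibly.
#' @export
write_selection_result <- function(result, out_dir) {
  stopifnot(inherits(result, "sgl_selection"))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop2("cannot create output directory: ", out_dir)
  if (!length(result$final_genes))
    warning("final gene set is empty", call. = FALSE)
  paths <- file.path(out_dir, c("ranked_genes.tsv", "final_genes.txt",
                                "metrics.json", "coefficient_plot.csv"))
  utils::write.table(result$ranked, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(result$final_genes, paths[2])
  jsonlite::write_json(list(per_fold_auc = result$per_fold_auc,
                            mean_auc = result$auc$mean,
                            var_auc = result$auc$variance),
                       paths[3], auto_unbox = TRUE, digits = NA)
  utils::write.table(data.frame(rank = result$ranked$rank,
                                gene_id = result$ranked$gene_id,
                                magnitude = abs(result$ranked$mean_coefficient)),
                     paths[4], sep = ",", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Benchmark the seven penalized methods across datasets
#'
#' For each dataset and each of the seven methods (sgl, grouplasso,
#' droplasso, biglasso, lasso, enet, ridge) runs stratified k-fold
#' cross-validation with the method's lambda rule (minimum-error for
#' sgl/grouplasso/biglasso, one-standard-error for lasso/enet/ridge, fixed
#' lambda for droplasso) and records the mean and variance of per-fold
#' held-out AUC. Grouped penalties receive hierarchically clustered gene
#' groups (J = round(sqrt(p))). The resulting method x dataset AUC matrix is
#' compared by the Friedman test with Nemenyi post-hoc.
#'
#' @param datasets named list of [labeled_dataset()] objects (or
#'   [generate_dataset()] outputs).
#' @param config a [pipeline_config()].
#' @return object of class `penreg_benchmark`: `auc_mean`, `auc_var`,
#'   `seconds` (methods x datasets matrices), `friedman`, `nemenyi`,
#'   `failures`.
#' @export
run_benchmark <- function(datasets, config = pipeline_config()) {
  if (inherits(datasets, "labeled_dataset")) datasets <- list(datasets)
  datasets <- lapply(datasets, function(d)
    if (inherits(d, "labeled_dataset")) d else d$dataset)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  methods <- c("sgl", "grouplasso", "droplasso", "biglasso", "lasso",
               "enet", "ridge")
  D <- length(datasets)
  auc_mean <- auc_var <- secs <-
    matrix(NA_real_, length(methods), D,
           dimnames = list(methods, names(datasets)))
  failures <- list()

  for (d in seq_len(D)) {
    ds <- shuffle_within_class(datasets[[d]], config$seed)
    ds <- remove_invariant_genes(ds)$dataset
    X <- unclass(ds$expr); y <- ds$labels
    folds <- make_stratified_folds(y, k = config$k_folds, seed = config$seed)
    J <- min(max(2L, round(sqrt(ncol(X)))), ncol(X))
    grouping <- cluster_genes(X, J, linkage = config$linkage,
                              metric = config$metric)

    for (m in methods) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch({
        if (m == "droplasso") {
          aucs <- vapply(seq_len(folds$k), function(f) {
            te <- which(folds$assignments == f)
            tr <- which(folds$assignments != f)
            keep <- col_sd_pop(X[tr, , drop = FALSE]) > 0
            std <- standardize_train_apply_test(X[tr, keep, drop = FALSE],
                                                X[te, keep, drop = FALSE],
                                                y[tr])
            fit <- fit_droplasso(std$train_x, std$train_y,
                                 config$droplasso_lambda,
                                 keep_prob = config$keep_prob,
                                 n_epochs = config$droplasso_epochs,
                                 seed = config$seed * 100 + f,
                                 tol = config$tol)
            roc_auc(y[te], as.numeric(std$test_x %*% fit$coefficients))$auc
          }, numeric(1))
          aggregate_cv_auc(aucs)
        } else {
          spec <- switch(m,
            sgl = penalty_spec("sgl", alpha_mix = config$sgl_alpha,
                               grouping = grouping),
            grouplasso = penalty_spec("grouplasso", grouping = grouping),
            biglasso = penalty_spec("biglasso"),
            lasso = penalty_spec("lasso", alpha_mix = 1),
            enet = penalty_spec("enet", alpha_mix = config$enet_alpha),
            ridge = penalty_spec("ridge", alpha_mix = 0))
          rule <- if (m %in% c("sgl", "grouplasso", "biglasso")) "min" else "1se"
          cv <- cv_select_lambda(X, y, spec, folds = folds, rule = rule,
                                 n_values = config$n_lambda,
                                 ratio = config$ratio, tol = config$tol,
                                 max_iter = config$max_iter)
          aucs <- vapply(cv$per_fold_predictions, function(pf)
            roc_auc(pf$y, pf$score)$auc, numeric(1))
          aggregate_cv_auc(aucs)
        }
      }, error = function(e) e)
      secs[m, d] <- proc.time()[["elapsed"]] - t0
      if (inherits(res, "error")) {
        failures[[paste(m, names(datasets)[d], sep = "/")]] <-
          conditionMessage(res)
      } else {
        auc_mean[m, d] <- res$mean
        auc_var[m, d] <- res$variance
      }
    }
  }

  fr <- nem <- NULL
  if (D >= 2 && !anyNA(auc_mean)) {
    fr <- friedman_test(auc_mean)
    nem <- nemenyi_posthoc(auc_mean)
  }
  structure(list(auc_mean = auc_mean, auc_var = auc_var, seconds = secs,
                 friedman = fr, nemenyi = nem, failures = failures),
            class = "penreg_benchmark")
}

#' @export
print.penreg_benchmark <- function(x, digits = 3, ...) {
  cat("cross-validated AUC (mean over folds):\n")
  print(round(x$auc_mean, digits))
  if (!is.null(x$friedman))
    cat(sprintf("\nFriedman chi-square = %.3f, p = %.4f\n",
                x$friedman$statistic, x$friedman$p_value))
  if (length(x$failures)) {
    cat("\nfailures:\n")
    for (nm in names(x$failures))
      cat("  ", nm, ": ", x$failures[[nm]], "\n", sep = "")
  }
  invisible(x)
}
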