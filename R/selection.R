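#' Partition genes into groups for grouped penalties
#'
#' A grouping is a partition of the `p` genes into `J` nonempty groups; the
#' grouped penalties weight each group norm by the kernel weight
#' `sqrt(p_j)` (kernel `K_j = p_j I`).
#'
#' @param group_of_gene integer/factor vector assigning each gene to a group;
#'   optionally named by gene id.
#' @return an object of class `gene_grouping` with `group_of_gene` (integer
#'   1..J), `J`, `sizes` and `kernel_weight`.
#' @export
gene_grouping <- function(group_of_gene) {
  if (anyNA(group_of_gene)) stop2("grouping is incomplete: NA group indices")
  nm <- names(group_of_gene)
  g <- as.integer(factor(group_of_gene, levels = unique(group_of_gene)))
  names(g) <- nm
  sizes <- as.integer(table(g))
  structure(list(group_of_gene = g, J = length(sizes), sizes = sizes,
                 kernel_weight = sqrt(sizes)),
            class = "gene_grouping")
}

#' @export
print.gene_grouping <- function(x, ...) {
  cat(sprintf("gene grouping: %d genes in %d groups (sizes %s)\n",
              length(x$group_of_gene), x$J,
              paste(utils::head(sort(x$sizes, decreasing = TRUE), 8),
                    collapse = ", ")))
  invisible(x)
}

#' Select the top genes of a fitted model by the mean-magnitude cutoff
#'
#' Returns the genes whose coefficient magnitude strictly exceeds the mean of
#' all coefficient magnitudes. If no gene clears the cutoff but some
#' coefficient is nonzero (all magnitudes equal), the single largest-magnitude
#' gene (first in gene order on ties) is returned so downstream stages always
#' have input; an all-zero fit yields an empty set.
#'
#' @param coefficients named numeric vector of fitted coefficients.
#' @return character vector of selected gene ids.
#' @export
select_top_genes <- function(coefficients) {
  if (!length(coefficients)) stop2("empty coefficient vector")
  if (is.null(names(coefficients)))
    names(coefficients) <- paste0("g", seq_along(coefficients))
  a <- abs(coefficients)
  if (all(a == 0)) return(character(0))
  sel <- names(a)[a > mean(a)]
  if (!length(sel)) sel <- names(a)[which.max(a)]
  sel
}

#' Union the top genes of the four stage-1 methods into a gene pool
#'
#' The pool is the union (not the intersection, which can be empty) of the
#' per-method top-gene sets, in original gene order, with per-gene provenance
#' recording which methods nominated it.
#'
#' @param sets named list of character vectors (one per method).
#' @param gene_order optional character vector fixing the output order.
#' @return an object of class `gene_pool` with `gene_ids` and `provenance`
#'   (named list of method tags per gene).
#' @export
build_gene_pool <- function(sets, gene_order = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("method", seq_along(sets))
  pool <- unique(unlist(sets, use.names = FALSE))
  if (!is.null(gene_order)) pool <- gene_order[gene_order %in% pool]
  prov <- lapply(pool, function(g)
    names(sets)[vapply(sets, function(s) g %in% s, logical(1))])
  names(prov) <- pool
  structure(list(gene_ids = pool, provenance = prov), class = "gene_pool")
}

#' @export
print.gene_pool <- function(x, ...) {
  tab <- table(unlist(x$provenance))
  cat(sprintf("gene pool: %d genes (per-method counts: %s)\n",
              length(x$gene_ids),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Group pooled genes by hierarchical clustering of their expression profiles
#'
#' Agglomerative clustering of gene columns (each gene's profile across
#' cells, standardized internally), with the dendrogram cut at `n_groups`
#' groups. This supplies data-driven groups to the grouped penalties without
#' requiring prior pathway knowledge.
#'
#' @param X_pool cells x pooled-genes matrix.
#' @param n_groups number of groups `J`, `2 <= J <= ncol(X_pool)`; the
#'   pipeline default is `round(sqrt(p))` clamped to that range.
#' @param linkage `"ward"` (Ward D2), `"complete"` or `"average"`.
#' @param metric `"euclidean"` or `"correlation"` (distance `1 - r`).
#' @return a [gene_grouping()] named by gene id.
#' @export
cluster_genes <- function(X_pool, n_groups,
                          linkage = c("ward", "complete", "average"),
                          metric = c("euclidean", "correlation")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  X_pool <- as.matrix(X_pool)
  p <- ncol(X_pool)
  if (n_groups > p) stop2("n_groups (", n_groups, ") exceeds pool size (", p, ")")
  if (n_groups < 1) stop2("n_groups must be >= 1")
  s <- col_sd_pop(X_pool)
  Z <- sweep(sweep(X_pool, 2, colMeans(X_pool)), 2, pmax(s, 1e-12), "/")
  d <- if (metric == "euclidean") stats::dist(t(Z))
       else stats::as.dist(1 - stats::cor(Z))
  hc <- stats::hclust(d, method = switch(linkage, ward = "ward.D2",
                                         complete = "complete",
                                         average = "average"))
  grp <- stats::cutree(hc, k = n_groups)
  names(grp) <- colnames(X_pool)
  gene_grouping(grp)
}

#' Average per-fold coefficients over a shared gene pool and rank genes
#'
#' Takes the arithmetic mean of each gene's coefficient across folds (a gene
#' absent from a fold's model contributes zero) and ranks genes by decreasing
#' mean magnitude, ties broken by gene order. Signed averaging can cancel
#' coefficients of opposite sign across folds; set `use_magnitude = TRUE` to
#' average `|coefficient|` instead.
#'
#' @param per_fold list of named coefficient vectors, all aligned to the same
#'   pool (identical names in identical order).
#' @param use_magnitude average magnitudes rather than signed values.
#' @return data frame with `gene_id`, `mean_coefficient`, `rank`, sorted by
#'   `|mean_coefficient|` descending.
#' @export
average_fold_coefficients <- function(per_fold, use_magnitude = FALSE) {
  if (!length(per_fold)) stop2("no fold coefficients supplied")
  nms <- names(per_fold[[1]])
  if (is.null(nms)) stop2("fold coefficient vectors must be named")
  ok <- vapply(per_fold, function(v) identical(names(v), nms), logical(1))
  if (!all(ok)) stop2("fold coefficient vectors are misaligned")
  M <- do.call(rbind, per_fold)
  if (use_magnitude) M <- abs(M)
  mu <- colMeans(M)
  ord <- order(-abs(mu), seq_along(mu))
  data.frame(gene_id = nms[ord], mean_coefficient = unname(mu[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Locate the elbow of a decreasing magnitude curve
#'
#' Finds the point of maximum perpendicular distance *below* the chord
#' joining the first and last points of the sorted-magnitude curve
#' (kneedle-style). Genes ranked strictly before the elbow are kept. If no
#' point falls below the chord beyond `tol` (e.g. linear decay), the full set
#' is kept with a warning. A manual override index short-circuits the
#' geometry.
#'
#' @param sorted_magnitudes numeric vector, sorted decreasing.
#' @param override optional integer: keep exactly this many top genes.
#' @param tol minimal below-chord distance to count as an elbow.
#' @return the number of genes to keep (the elbow index).
#' @export
elbow_cutoff <- function(sorted_magnitudes, override = NULL, tol = 1e-9) {
  L <- length(sorted_magnitudes)
  if (!is.null(override)) {
    if (override < 1 || override > L) stop2("override out of range")
    return(as.integer(override))
  }
  if (L < 3) {
    warning("fewer than 3 magnitudes; keeping the full set", call. = FALSE)
    return(L)
  }
  v <- sorted_magnitudes
  x <- seq_len(L) - 1
  dx <- L - 1; dy <- v[L] - v[1]
  nrm <- sqrt(dx^2 + dy^2)
  # signed perpendicular distance below the chord (positive = below)
  d <- (dy * x - dx * (v - v[1])) / nrm
  i <- which.max(d)
  if (d[i] <= tol) {
    warning("no elbow detected below the chord; keeping the full set",
            call. = FALSE)
    return(L)
  }
  as.integer(i - 1)
}

#' Cluster cells by K-means on the final gene set
#'
#' Lloyd's algorithm with `n_init` seeded random restarts, keeping the
#' partition with the smallest within-cluster sum of squares. Deterministic
#' for a fixed seed.
#'
#' @param X_final cells x final-genes matrix.
#' @param k_clusters number of clusters (default 2).
#' @param seed integer seed.
#' @param n_init number of random restarts (default 10).
#' @return integer vector of cluster labels (1..k), named by cell id.
#' @export
cluster_cells_kmeans <- function(X_final, k_clusters = 2, seed = 1,
                                 n_init = 10) {
  X_final <- as.matrix(X_final)
  if (k_clusters < 1) stop2("k_clusters must be >= 1")
  if (k_clusters > nrow(X_final))
    stop2("k_clusters (", k_clusters, ") exceeds number of cells (",
          nrow(X_final), ")")
  km <- with_seed(seed,
                  stats::kmeans(X_final, centers = k_clusters,
                                nstart = n_init, iter.max = 100,
                                algorithm = "Lloyd"))
  out <- km$cluster
  names(out) <- rownames(X_final)
  out
}
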