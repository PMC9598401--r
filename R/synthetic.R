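#' Simulation parameters for synthetic scRNA-seq data
#'
#' Defines a two-class expression matrix with planted structure: lognormal
#' baseline expression, a set of differentially expressed (DE) marker genes
#' shifted upward in class 1 by `effect` within-class standard deviations,
#' blocks of correlated genes driven by shared latent factors, a set of
#' invariant (constant) genes, and dropout modeled as independent Bernoulli
#' zeroing of non-invariant entries.
#'
#' Defaults describe the package's reference condition: 150 cells per class,
#' 2000 genes of which 20 are DE at 2 SD with 30% dropout, the 20 DE genes
#' correlated in four blocks of five (rho = 0.6) plus six background blocks
#' of twenty (rho = 0.4), and 3 invariant genes.
#'
#' @param n_per_class integer vector of length 2: cells in class 1 and 0.
#' @param p_genes total number of genes.
#' @param n_de number of DE marker genes (placed first in gene order).
#' @param effect class-1 mean shift in units of within-class SD.
#' @param n_invariant number of constant genes (placed last).
#' @param group_blocks list of `c(size, rho)` pairs assigned to consecutive
#'   genes from the first column onward.
#' @param dropout_prob probability that a non-invariant entry is zeroed.
#' @param noise_sd lognormal shape (sd of the latent Gaussian; default 0.5).
#' @param seed integer seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_per_class = c(150, 150), p_genes = 2000, n_de = 20,
                       effect = 2, n_invariant = 3,
                       group_blocks = NULL,
                       dropout_prob = 0.3, noise_sd = 0.5, seed = 1) {
  if (is.null(group_blocks)) {
    group_blocks <- c(rep(list(c(5, 0.6)), if (n_de >= 20) 4 else 0),
                      rep(list(c(20, 0.4)), 6))
    total <- sum(vapply(group_blocks, `[`, numeric(1), 1))
    if (total > p_genes - n_invariant) group_blocks <- list()
  }
  if (n_de + n_invariant > p_genes)
    stop2("n_de + n_invariant exceeds p_genes")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop2("dropout_prob must lie in [0, 1)")
  for (b in group_blocks)
    if (b[2] < 0 || b[2] >= 1) stop2("block correlation must lie in [0, 1)")
  if (any(n_per_class < 1)) stop2("n_per_class must be positive")
  structure(list(n_per_class = n_per_class, p_genes = p_genes, n_de = n_de,
                 effect = effect, n_invariant = n_invariant,
                 group_blocks = group_blocks, dropout_prob = dropout_prob,
                 noise_sd = noise_sd, seed = seed),
            class = "sim_params")
}

#' Generate a synthetic labeled scRNA-seq dataset with known truth
#'
#' Expression of gene g in cell i is `b_g * exp(s * z - s^2/2)` with latent
#' `z = sqrt(rho) f + sqrt(1-rho) e` shared within correlated blocks
#' (`f` per cell and block, `e` independent), so each gene is marginally
#' lognormal with mean `b_g` and within-class SD `b_g * sqrt(exp(s^2)-1)`.
#' DE genes receive an additive class-1 shift of `effect` within-class SDs.
#' Invariant genes are constant; dropout zeroes non-invariant entries
#' independently. Deterministic for a fixed seed.
#'
#' @param params a [sim_params()].
#' @return list with `expr` ([expression_matrix()]), `labels` (0/1 named
#'   vector), `truth` (list: `de_gene_ids`, `invariant_gene_ids`,
#'   `block_of_gene`, `class_of_cell`) and `dataset` (a
#'   [labeled_dataset()]).
#' @export
generate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params$p_genes
  n1 <- params$n_per_class[1]; n0 <- params$n_per_class[2]
  n <- n1 + n0
  s <- params$noise_sd

  gene_ids <- sprintf("gene%04d", seq_len(p))
  cell_ids <- sprintf("cell%04d", seq_len(n))
  labels <- c(rep(1L, n1), rep(0L, n0))
  names(labels) <- cell_ids

  inv_idx <- if (params$n_invariant > 0)
    (p - params$n_invariant + 1):p else integer(0)

  block_of_gene <- rep(0L, p)
  pos <- 1L
  for (b in seq_along(params$group_blocks)) {
    size <- params$group_blocks[[b]][1]
    block_of_gene[pos:(pos + size - 1)] <- b
    pos <- pos + size
  }
  block_of_gene[inv_idx] <- 0L

  X <- with_seed(params$seed, {
    b_g <- exp(stats::rnorm(p, meanlog_baseline(), 0.5))
    Z <- matrix(stats::rnorm(n * p), n, p)
    for (b in seq_along(params$group_blocks)) {
      cols <- which(block_of_gene == b)
      rho <- params$group_blocks[[b]][2]
      if (length(cols) && rho > 0) {
        # calibrate the latent correlation so the lognormal expression-scale
        # correlation equals rho: corr(exp(sZ)) = (exp(rho_z s^2)-1)/(exp(s^2)-1)
        rho_z <- min(log1p(rho * (exp(s^2) - 1)) / s^2, 0.999)
        f <- stats::rnorm(n)
        Z[, cols] <- sqrt(rho_z) * f + sqrt(1 - rho_z) * Z[, cols]
      }
    }
    X <- sweep(exp(s * Z - s^2 / 2), 2, b_g, "*")
    sd_g <- b_g * sqrt(exp(s^2) - 1)
    if (params$n_de > 0) {
      de <- seq_len(params$n_de)
      X[labels == 1L, de] <- X[labels == 1L, de] +
        matrix(params$effect * sd_g[de], n1, params$n_de, byrow = TRUE)
    }
    if (length(inv_idx)) X[, inv_idx] <- 5
    if (params$dropout_prob > 0) {
      keep_cols <- setdiff(seq_len(p), inv_idx)
      mask <- matrix(stats::runif(n * length(keep_cols)) <
                       params$dropout_prob, n, length(keep_cols))
      X[, keep_cols][mask] <- 0
    }
    X
  })
  dimnames(X) <- list(cell_ids, gene_ids)

  expr <- expression_matrix(X)
  truth <- list(de_gene_ids = gene_ids[seq_len(params$n_de)],
                invariant_gene_ids = gene_ids[inv_idx],
                block_of_gene = stats::setNames(block_of_gene, gene_ids),
                class_of_cell = labels)
  list(expr = expr, labels = labels, truth = truth,
       dataset = labeled_dataset(expr, labels,
                                 class_names = c(`0` = "class0",
                                                 `1` = "class1")))
}

# baseline log-mean of gene expression (TPM-like scale)
meanlog_baseline <- function() 1

#' Four benchmark-style synthetic datasets of differing shape
#'
#' Generates four seeded datasets with distinct cell counts, gene counts,
#' class imbalance and dropout, emulating a small cross-dataset benchmark:
#' (150:80, p = 2000), (80:60, p = 2500), (300:300, p = 3000),
#' (120:90, p = 4000).
#'
#' @param seed integer master seed; dataset d uses `seed + d`.
#' @param scale multiplier applied to cell and gene counts (use < 1 for quick
#'   runs; counts are kept above solver minimums).
#' @return named list of four outputs of [generate_dataset()].
#' @export
default_benchmark_suite <- function(seed = 1, scale = 1) {
  shapes <- list(synthA = list(n = c(150, 80), p = 2000, drop = 0.3),
                 synthB = list(n = c(80, 60), p = 2500, drop = 0.4),
                 synthC = list(n = c(300, 300), p = 3000, drop = 0.2),
                 synthD = list(n = c(120, 90), p = 4000, drop = 0.35))
  out <- list()
  for (d in seq_along(shapes)) {
    sh <- shapes[[d]]
    n <- pmax(round(sh$n * scale), c(15, 12))
    p <- max(round(sh$p * scale), 60)
    out[[names(shapes)[d]]] <- generate_dataset(sim_params(
      n_per_class = n, p_genes = p,
      n_de = max(10, round(20 * scale)), effect = 2,
      n_invariant = 3, dropout_prob = sh$drop, seed = seed + d))
  }
  out
}
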