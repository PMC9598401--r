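# sgpool

Two-stage penalized-regression feature selection for binary cell-type
classification in single-cell RNA-seq expression matrices.

## What it does

Given a cells × genes expression matrix and a binary labeling of the cells,
`sgpool` finds a compact set of marker genes and scores how well they
separate the two populations. The model is penalized linear regression on
the standardized data,

    beta_hat = argmin_beta (1/n) ||y - X beta||^2 + lambda * P(beta),

with six interchangeable penalties P: ridge (L2), lasso (L1), elastic net
(convex L1/L2 mix), drop lasso (the lasso objective on a dropout-masked
design, robust to the excess zeros of scRNA-seq), group lasso
(`sum_j sqrt(p_j) ||beta_j||_2` over gene groups) and sparse group lasso
(SGL, `(1-alpha) * lambda * sum_j sqrt(p_j) ||beta_j||_2 +
alpha * lambda * ||beta||_1`).

The selection procedure runs in two stages inside a stratified k-fold
cross-validation:

1. **Nominate.** Ridge, lasso, elastic net (one-standard-error lambda rule,
   nested CV) and drop lasso (fixed lambda) are fitted on each training
   split; each method's top genes (coefficient magnitude above the mean
   magnitude) are unioned into a *gene pool* — typically well under half of
   the variable genes.
2. **Rank.** The pool is grouped by Ward hierarchical clustering of gene
   profiles and an SGL (alpha = 0.95, minimum-error lambda rule) is fitted
   on it; held-out AUC is recorded per fold.

Fold-averaged SGL coefficients are ranked by magnitude, cut at the
automatically detected elbow of the rank–magnitude curve, and the final
genes drive a K-means clustering of all cells.

The package also ships solver-level APIs (`fit_enet`, `fit_sgl`,
`fit_group_lasso`, `fit_droplasso`, `ridge_closed_form`,
`compute_lambda_path`, `cv_select_lambda`), a unified modelling front end
(`penreg()` with `coef`/`predict`/`print` methods), evaluation tools
(Mann–Whitney AUC, Friedman + Nemenyi cross-method comparison), a
dropout-aware synthetic data generator with planted ground truth, a
7-method benchmark (`run_benchmark()`), and a thin CLI
(`inst/cli/sgpool`).

## Worked example

```r
library(sgpool)

# synthetic two-class dataset: 150 cells/class, 2000 genes, 20 planted
# markers at 2 SD, 30% dropout
sim <- generate_dataset(sim_params(seed = 7))
res <- run_selection_pipeline(sim$dataset, pipeline_config(seed = 1))
print(res)
#> two-stage penalized feature selection
#>   variable genes: 1997; mean stage-1 pool: 854.0 (42.8% of variable genes)
#>   ranked genes: 1562; final set after elbow: 31
#>   CV-AUC: mean 0.980, variance 0.0004181 over 10 folds

# how many of the 20 planted markers made the final set?
mean(sim$truth$de_gene_ids %in% res$final_genes)
#> [1] 0.95
```

The printout reads as follows: of 1997 variable genes, the four stage-1
penalties nominated on average 854 genes per fold (42.8%) into the pool;
the SGL ranking covered 1562 genes across folds, the elbow kept the top 31,
and those genes achieved a mean held-out AUC of 0.980 over the 10 folds.
19 of the 20 planted markers are among the 31.

Single fits work through the modelling front end:

```r
ds <- remove_invariant_genes(sim$dataset)$dataset
fit <- penreg(unclass(ds$expr), ds$labels, "lasso", lambda = 0.05)
print(fit)
#> penalized linear model (lasso, lambda = 0.05)
#>   194/1997 nonzero coefficients; intercept -0.4522
```

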