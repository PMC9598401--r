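---
title: "Two-stage penalized feature selection for single-cell expression data"
author: "sgpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage penalized feature selection for single-cell expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgpool)
```

## The problem

Single-cell RNA-seq experiments measure thousands of genes on hundreds to
thousands of cells, and a recurring analysis task is to find a small set of
marker genes that separates two cell populations — wild type against
knockout, tumor against normal mucosa, one cortical cell type against
another. The setting is the classic large-p-small-n regime, aggravated by
two single-cell idiosyncrasies: *dropouts* (transcripts stochastically
undetected even when expressed, inflating the zero fraction) and blocks of
strongly co-expressed genes.

`sgpool` treats the task as penalized linear regression of a 0/1 class label
on the standardized expression matrix,

$$\hat\beta = \arg\min_\beta \tfrac1n \lVert y - X\beta \rVert_2^2
  + \lambda\,P(\beta),$$

and composes six penalties into a two-stage selection procedure in which
four single-gene penalties *nominate* a gene pool and a sparse group lasso
over hierarchically clustered gene groups *ranks* it.

## The penalties

All solvers share the $1/n$ squared-error loss above; the penalties are

* **ridge**: $\lambda\lVert\beta\rVert_2^2$ — solved exactly through the
  stationarity system $(X'X + n\lambda I)\beta = X'y$ (kernel form when
  $n < p$);
* **lasso**: $\lambda\lVert\beta\rVert_1$ — cyclic coordinate descent, each
  update a soft-threshold $S(z, t) = \mathrm{sign}(z)\max(|z|-t, 0)$;
* **elastic net**: $\lambda_1\lVert\beta\rVert_1 +
  \lambda_2\lVert\beta\rVert_2^2$ with $(\lambda_1, \lambda_2) =
  (\alpha\lambda, (1-\alpha)\lambda/2)$, so $\alpha$ interpolates lasso
  ($\alpha = 1$) and ridge-like shrinkage ($\alpha = 0$);
* **drop lasso**: the lasso objective evaluated on a dropout-augmented
  design — each epoch permutes rows and applies an elementwise
  Bernoulli($q$) mask scaled by $1/q$, so the masked design is unbiased for
  $X$ and the method is robust to the zero-inflation it emulates; optimized
  by proximal (stochastic) gradient descent;
* **group lasso**: $\lambda \sum_j \sqrt{p_j}\,\lVert\beta_j\rVert_2$ over
  a partition of genes into $J$ groups (kernel $K_j = p_j I$), selecting
  whole groups;
* **sparse group lasso (SGL)**:
  $(1-\alpha)\lambda \sum_j \sqrt{p_j}\lVert\beta_j\rVert_2 +
  \alpha\lambda\lVert\beta\rVert_1$, sparse both across and within groups.
* **big lasso**: the lasso objective kept as a separate benchmark row; its
  distinguishing feature in the literature is out-of-core computation,
  which is outside this package's scope.

The SGL mixing convention carries the $(1-\alpha)$ factor on the group term.
Written without it, the stated limits of the method do not hold; with it,
$\alpha = 1$ recovers the lasso exactly and $\alpha = 0$ the group lasso,
and both limits are enforced by tests to $10^{-4}$ in the sup norm.

Two deliberately distinct algorithms back the grouped penalties. SGL blocks
are updated by proximal gradient steps (elementwise soft-threshold, then
group shrinkage), while group lasso blocks are solved *exactly* per sweep
through the eigendecomposition of the block Gram matrix and a
one-dimensional root solve on the block norm. Because the two code paths are
independent, the $\alpha = 0$ equivalence test is a genuine cross-check
rather than a tautology.

### Standardization and its consequences

Columns are standardized to mean 0 and *population* (1/n) standard
deviation 1, and the response is centered and scaled the same way, so every
training column satisfies $\bar x = 0$, $\lVert x\rVert^2 = n$. This
convention makes the null-model threshold closed-form:
$\lambda_{\max} = (2/n)\max_j |x_j'y| / \alpha$ for L1 penalties,
$\max_j \lVert(2/n)X_j'y\rVert_2/\sqrt{p_j}$ for the group lasso, and for
SGL the smallest $\lambda$ passing every group-zero test, found by
per-group bisection to $10^{-8}$. Regularization paths are geometric over
100 values down to $10^{-3}\lambda_{\max}$ ($10^{-2}$ when $n < p$). Ridge
has no finite $\lambda_{\max}$; its cross-validation grid is a fixed
geometric ladder anchored at the same gradient magnitude, spanning seven
orders of magnitude.

Standardization is always computed on the training rows of a fold and
applied unchanged to its test rows, so no test information leaks into the
scaling. Since the label is 0/1, the held-out linear predictor serves as a
ranking score and AUC is invariant to the affine transform of $y$; squared
error on the centered/scaled label is the fitting loss throughout, matching
the linear-model formulation of every objective.

## The two-stage pipeline

`run_selection_pipeline()` executes, per outer fold of a stratified k-fold
split (default $k = 10$):

1. cells are shuffled within class (seeded) and invariant genes removed
   globally, then re-checked per training fold;
2. ridge, lasso and elastic net ($\alpha = 0.5$) are fitted on the training
   split with nested cross-validated $\lambda$ selection under the
   one-standard-error rule; drop lasso is fitted at its fixed
   $\lambda = 0.001$;
3. each method's *top genes* are those whose coefficient magnitude strictly
   exceeds the mean magnitude over all genes (with a never-empty fallback to
   the single largest coefficient, so the second stage always has input);
4. the union of the four top-gene sets forms the *gene pool* — a union
   rather than an intersection, because the four regularizers need not
   agree on any single gene;
5. pooled genes are grouped by Ward hierarchical clustering of their
   standardized expression profiles, cut at $J = \lceil\sqrt{|pool|}\rceil$
   groups (clamped to $[2, |pool|]$);
6. SGL ($\alpha = 0.95$) is fitted on the pool with nested minimum-error
   $\lambda$ selection, and its held-out fold scores are recorded.

After the folds, coefficients are averaged per gene across folds — a gene
absent from a fold's pool contributes zero — and ranked by mean magnitude.
The final gene set is cut at the *elbow* of the rank-magnitude curve: the
point of maximum perpendicular distance below the chord joining the curve's
endpoints (kneedle-style), with a manual override available since elbow
reading is traditionally visual. Finally, all cells are clustered by
K-means (Lloyd's algorithm, 10 seeded restarts) on the final genes.

Design choices made where the procedure was genuinely open:

* **Nesting.** Stage-1 $\lambda$ selection is nested inside each outer
  fold rather than fitted once globally; this is slightly more conservative
  but avoids test leakage into the pool.
* **Signed averaging.** Fold coefficients are averaged with sign, which can
  cancel a gene that flips sign across folds; `use_magnitude = TRUE`
  averages magnitudes instead. Cancellation is treated as informative (an
  unstable gene ranks low).
* **Group count.** No external grouping knowledge is assumed;
  $J \approx \sqrt{p}$ balances group granularity against group size and is
  exposed as a tunable.
* **Drop-lasso retention.** The mask retention probability defaults to
  $q = 0.5$ and is configurable; the inverted-dropout $1/q$ scaling is what
  makes the $q = 1$ limit coincide exactly with the lasso.
* **Numerical controls.** Solver tolerance $10^{-7}$ on the sup-norm
  coefficient change per sweep, at most $10^5$ sweeps; convergence is also
  verified in tests against explicit subgradient stationarity residuals and
  per-sweep objective monotonicity.

## The synthetic generator

`generate_dataset()` emulates the data challenges the pipeline is built
for, with known ground truth. Expression of gene $g$ in cell $i$ is
$b_g \exp(s z_{ig} - s^2/2)$ with $b_g$ lognormal across genes and
$z_{ig}$ standard normal, giving the positive, right-skewed marginals
typical of TPM-scale data. Correlated blocks share a per-cell latent factor
whose weight is calibrated so the *expression-scale* correlation equals the
requested $\rho$ (the lognormal transform would otherwise attenuate it).
Differentially expressed genes receive an additive class-1 shift of
`effect` within-class standard deviations; invariant genes are constant;
dropout zeroes non-invariant entries independently with fixed probability.

The reference condition used by the test suite is 150 cells per class,
2000 genes, 20 DE genes at 2 SD, 30% dropout, 3 invariant genes, with the
DE genes correlated in four blocks of five ($\rho = 0.6$) and six
background blocks of twenty ($\rho = 0.4$). Under this condition the
pipeline's planted-marker recall, cross-validated AUC and adjusted Rand
index of the final K-means partition are all asserted in
`tests/testthat/test-acceptance.R`, and a signal-free variant
(`n_de = 0`) is asserted to sit at chance-level AUC.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: count-level noise (no negative-binomial UMI
model), library-size variation, batch effects, expression-dependent dropout
(zeros here are missing completely at random), and biologically structured
correlation beyond block factors. Results on the synthetic reference are
evidence that the machinery works as specified, not that any particular
biological dataset will yield a given AUC.

## Evaluation machinery

Held-out performance is summarized by ROC/AUC, where AUC is computed as the
pairwise Mann–Whitney statistic (half credit for ties) — exactly the
trapezoidal area under the threshold-sweep ROC curve and invariant under
monotone transforms of the scores. Cross-validated AUC is the mean of
per-fold AUCs (with the across-fold sample variance reported), not the AUC
of pooled predictions. Cross-method comparison over several datasets uses
the Friedman rank test,
$\chi^2_F = \frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)$, with mean ranks on
ties, followed by the Nemenyi post-hoc test with studentized-range critical
values. Significance thresholds are left to the caller; the package reports
raw p-values.

## Problem sizes

The test-suite and acceptance runs use the reference condition above
(300 cells, 2000 genes, 10 outer folds, 5 inner folds, 100-value paths) for
the end-to-end checks, and 30-to-80-cell instances for solver-level
oracles; the benchmark contract is exercised on down-scaled suite members.
These sizes were chosen as the smallest at which the statistical properties
under test are stable across seeds.

## Known limitations

* Binary classification only; a multinomial extension would change the
  loss, the paths and the pool construction.
* Squared-error loss on 0/1 labels is a linear-probability model; it is the
  right companion to the closed-form thresholds and AUC ranking used here,
  but calibrated probabilities are out of scope.
* Drop lasso with $q < 1$ is a stochastic optimizer: results are
  deterministic for a fixed seed but carry Monte-Carlo variability across
  seeds, which the fixed benchmark $\lambda = 0.001$ inherits.
* The union pool can approach half of the variable genes when ridge (which
  never zeroes coefficients) nominates broadly; the mean-magnitude cutoff
  is what keeps it bounded in practice.
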