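// Solver cores for the 1/n squared-error penalized objectives.
//
// All routines assume the caller passes a column-standardized design X and a
// centered response y; lambda paths are fitted warm-started from the largest
// value downwards. Convergence is declared when the largest absolute
// coefficient change over a full sweep falls below `tol`.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// ---------------------------------------------------------------------------
// Elastic net (covers lasso lam2=0 and the L1 part of ridge-free paths):
// minimize (1/n)||y - X b||^2 + lam1 ||b||_1 + lam2 ||b||_2^2
// Cyclic coordinate descent with residual updates and an active-set cycle.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_enet_path(const arma::mat& X, const arma::vec& y,
                   const arma::vec& lam1, const arma::vec& lam2,
                   double tol, int max_iter, bool track_obj) {
  const int n = X.n_rows, p = X.n_cols, m = lam1.n_elem;
  arma::vec cn(p);             // ||x_j||^2 / n
  for (int j = 0; j < p; ++j) cn[j] = arma::dot(X.col(j), X.col(j)) / n;

  arma::mat B(p, m, arma::fill::zeros);
  arma::ivec iters(m, arma::fill::zeros);
  LogicalVector conv(m);
  List obj_hist(m);

  arma::vec beta(p, arma::fill::zeros);
  arma::vec r = y;

  for (int k = 0; k < m; ++k) {
    const double l1 = lam1[k] / 2.0, l2 = lam2[k];
    std::vector<double> objs;
    int it = 0;
    bool converged = false;

    auto sweep = [&](const std::vector<int>& idx) -> double {
      double maxd = 0.0;
      for (int j : idx) {
        if (cn[j] <= 0.0) continue;
        double bj = beta[j];
        double zj = arma::dot(X.col(j), r) / n + cn[j] * bj;
        double bn = soft(zj, l1) / (cn[j] + l2);
        if (bn != bj) {
          r -= X.col(j) * (bn - bj);
          beta[j] = bn;
          double d = std::abs(bn - bj);
          if (d > maxd) maxd = d;
        }
      }
      return maxd;
    };

    std::vector<int> all(p);
    for (int j = 0; j < p; ++j) all[j] = j;

    while (it < max_iter) {
      double maxd = sweep(all); ++it;
      if (track_obj)
        objs.push_back(arma::dot(r, r) / n +
                       2.0 * l1 * arma::norm(beta, 1) +
                       l2 * arma::dot(beta, beta));
      if (maxd < tol) { converged = true; break; }
      // active-set refinement
      std::vector<int> act;
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) act.push_back(j);
      while (it < max_iter) {
        double d = sweep(act); ++it;
        if (track_obj)
          objs.push_back(arma::dot(r, r) / n +
                         2.0 * l1 * arma::norm(beta, 1) +
                         l2 * arma::dot(beta, beta));
        if (d < tol) break;
      }
    }
    B.col(k) = beta;
    iters[k] = it;
    conv[k] = converged;
    if (track_obj) obj_hist[k] = NumericVector(objs.begin(), objs.end());
  }
  return List::create(_["beta"] = B, _["iters"] = iters,
                      _["converged"] = conv, _["objective"] = obj_hist);
}

// ---------------------------------------------------------------------------
// Sparse group lasso:
// minimize (1/n)||y - X b||^2 + (1-a) L sum_j w_j ||b_j|| + a L ||b||_1
// Block coordinate descent; blocks updated by proximal gradient steps with
// step 1/L_j, L_j = (2/n) sigma_max(X_j)^2.
// Groups must occupy contiguous column ranges [gstart[j], gend[j]] (0-based).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_sgl_path(const arma::mat& X, const arma::vec& y,
                  const arma::ivec& gstart, const arma::ivec& gend,
                  const arma::vec& wj, const arma::vec& lambda, double alpha,
                  double tol, int max_iter, int inner_max, bool track_obj) {
  const int n = X.n_rows, p = X.n_cols, m = lambda.n_elem, J = gstart.n_elem;

  // per-group Gram matrices (2/n) Xj'Xj, computed once; inner proximal
  // steps then cost p_j^2 instead of n p_j
  std::vector<arma::mat> G(J);
  arma::vec Lj(J);
  for (int j = 0; j < J; ++j) {
    arma::mat Xj = X.cols(gstart[j], gend[j]);
    G[j] = (2.0 / n) * (Xj.t() * Xj);
    arma::vec ev;
    arma::eig_sym(ev, G[j]);
    Lj[j] = ev.max();
  }

  arma::mat B(p, m, arma::fill::zeros);
  arma::ivec iters(m, arma::fill::zeros);
  LogicalVector conv(m);
  List obj_hist(m);

  arma::vec beta(p, arma::fill::zeros);
  arma::vec r = y;

  for (int k = 0; k < m; ++k) {
    const double L = lambda[k];
    std::vector<double> objs;
    int it = 0;
    bool converged = false;

    while (it < max_iter) {
      double maxd = 0.0;
      for (int j = 0; j < J; ++j) {
        const int a0 = gstart[j], a1 = gend[j];
        arma::vec bj = beta.subvec(a0, a1);
        const bool bj_zero = arma::all(bj == 0.0);
        arma::mat Xj = X.cols(a0, a1);
        // c = (2/n) Xj' rj with rj the residual excluding block j
        arma::vec c = (2.0 / n) * (Xj.t() * r);
        if (!bj_zero) c += G[j] * bj;
        // group-zero test on the soft-thresholded block gradient
        arma::vec cs(c.n_elem);
        for (arma::uword q = 0; q < c.n_elem; ++q) cs[q] = soft(c[q], alpha * L);
        arma::vec bnew;
        if (arma::norm(cs, 2) <= (1.0 - alpha) * L * wj[j] || Lj[j] <= 0.0) {
          bnew = arma::vec(bj.n_elem, arma::fill::zeros);
        } else {
          bnew = bj;
          const double t = 1.0 / Lj[j];
          for (int q = 0; q < inner_max; ++q) {
            arma::vec grad = G[j] * bnew - c;
            arma::vec u = bnew - t * grad;
            arma::vec v(u.n_elem);
            for (arma::uword h = 0; h < u.n_elem; ++h)
              v[h] = soft(u[h], t * alpha * L);
            double nv = arma::norm(v, 2);
            double thr = t * (1.0 - alpha) * L * wj[j];
            arma::vec bq = (nv > thr) ? arma::vec(v * (1.0 - thr / nv))
                                      : arma::vec(u.n_elem, arma::fill::zeros);
            double d = arma::norm(bq - bnew, "inf");
            bnew = bq;
            if (d < tol) break;
          }
        }
        double d = arma::norm(bnew - bj, "inf");
        if (d > 0.0) {
          r += Xj * (bj - bnew);
          beta.subvec(a0, a1) = bnew;
          if (d > maxd) maxd = d;
        }
      }
      ++it;
      if (track_obj) {
        double pen = 0.0;
        for (int j = 0; j < J; ++j)
          pen += wj[j] * arma::norm(beta.subvec(gstart[j], gend[j]), 2);
        objs.push_back(arma::dot(r, r) / n + (1.0 - alpha) * L * pen +
                       alpha * L * arma::norm(beta, 1));
      }
      if (maxd < tol) { converged = true; break; }
    }
    B.col(k) = beta;
    iters[k] = it;
    conv[k] = converged;
    if (track_obj) obj_hist[k] = NumericVector(objs.begin(), objs.end());
  }
  return List::create(_["beta"] = B, _["iters"] = iters,
                      _["converged"] = conv, _["objective"] = obj_hist);
}

// ---------------------------------------------------------------------------
// Group lasso:
// minimize (1/n)||y - X b||^2 + L sum_j w_j ||b_j||   (w_j = sqrt(p_j))
// Block coordinate descent with *exact* block solves: with
// S_j = (2/n) X_j'X_j = Q diag(s) Q' and c = (2/n) X_j'r_j, the nonzero block
// solves (S_j + nu I) b = c with nu = L w_j / ||b||; the scalar nu is found by
// bisection on phi(nu) = nu ||b(nu)|| - L w_j, which is monotone increasing.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_grouplasso_path(const arma::mat& X, const arma::vec& y,
                         const arma::ivec& gstart, const arma::ivec& gend,
                         const arma::vec& wj, const arma::vec& lambda,
                         double tol, int max_iter, bool track_obj) {
  const int n = X.n_rows, p = X.n_cols, m = lambda.n_elem, J = gstart.n_elem;

  // per-group eigendecompositions, computed once
  std::vector<arma::mat> Q(J);
  std::vector<arma::vec> s(J);
  for (int j = 0; j < J; ++j) {
    arma::mat Xj = X.cols(gstart[j], gend[j]);
    arma::mat Sj = (2.0 / n) * (Xj.t() * Xj);
    arma::eig_sym(s[j], Q[j], Sj);
  }

  arma::mat B(p, m, arma::fill::zeros);
  arma::ivec iters(m, arma::fill::zeros);
  LogicalVector conv(m);
  List obj_hist(m);

  arma::vec beta(p, arma::fill::zeros);
  arma::vec r = y;

  for (int k = 0; k < m; ++k) {
    const double L = lambda[k];
    std::vector<double> objs;
    int it = 0;
    bool converged = false;

    while (it < max_iter) {
      double maxd = 0.0;
      for (int j = 0; j < J; ++j) {
        const int a0 = gstart[j], a1 = gend[j];
        arma::vec bj = beta.subvec(a0, a1);
        arma::mat Xj = X.cols(a0, a1);
        arma::vec c = (2.0 / n) * (Xj.t() * r);
        if (!arma::all(bj == 0.0))
          c += Q[j] * (s[j] % (Q[j].t() * bj));   // S_j b_j via eigenbasis
        double nc = arma::norm(c, 2);
        arma::vec bnew;
        const double lw = L * wj[j];
        if (lw > 0.0 && nc <= lw) {
          bnew = arma::vec(bj.n_elem, arma::fill::zeros);
        } else if (lw <= 0.0) {
          // unpenalized block: least-squares solve (guard tiny eigenvalues)
          arma::vec d = Q[j].t() * c;
          arma::vec x(d.n_elem);
          for (arma::uword h = 0; h < d.n_elem; ++h)
            x[h] = (s[j][h] > 1e-12) ? d[h] / s[j][h] : 0.0;
          bnew = Q[j] * x;
        } else {
          arma::vec d = Q[j].t() * c;
          double smax = s[j].max();
          double lo = 0.0;
          double hi = smax * lw / (nc - lw) + 1.0;
          auto normb = [&](double nu) {
            double acc = 0.0;
            for (arma::uword h = 0; h < d.n_elem; ++h) {
              double den = s[j][h] + nu;
              acc += d[h] * d[h] / (den * den);
            }
            return std::sqrt(acc);
          };
          for (int q = 0; q < 200; ++q) {
            double mid = (lo + hi) / 2.0;
            if (mid * normb(mid) - lw > 0.0) hi = mid; else lo = mid;
            if (hi - lo < 1e-13 * (1.0 + hi)) break;
          }
          double nu = (lo + hi) / 2.0;
          arma::vec x(d.n_elem);
          for (arma::uword h = 0; h < d.n_elem; ++h) x[h] = d[h] / (s[j][h] + nu);
          bnew = Q[j] * x;
        }
        double dch = arma::norm(bnew - bj, "inf");
        if (dch > 0.0) {
          r += Xj * (bj - bnew);
          beta.subvec(a0, a1) = bnew;
          if (dch > maxd) maxd = dch;
        }
      }
      ++it;
      if (track_obj) {
        double pen = 0.0;
        for (int j = 0; j < J; ++j)
          pen += wj[j] * arma::norm(beta.subvec(gstart[j], gend[j]), 2);
        objs.push_back(arma::dot(r, r) / n + L * pen);
      }
      if (maxd < tol) { converged = true; break; }
    }
    B.col(k) = beta;
    iters[k] = it;
    conv[k] = converged;
    if (track_obj) obj_hist[k] = NumericVector(objs.begin(), objs.end());
  }
  return List::create(_["beta"] = B, _["iters"] = iters,
                      _["converged"] = conv, _["objective"] = obj_hist);
}

// ---------------------------------------------------------------------------
// Drop lasso: proximal stochastic gradient on the mask-augmented objective
// (1/n)||y - X_drop b||^2 + L ||b||_1, with inverted-dropout masks
// (Bernoulli(q) / q) redrawn each epoch after a row permutation. Uses the R RNG,
// so determinism follows from set.seed() in the caller.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_droplasso(const arma::mat& X, const arma::vec& y, double lambda,
                   double q, int n_epochs, double step0, double decay,
                   double tol, bool tail_avg) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec acc(p, arma::fill::zeros);
  int n_acc = 0;
  const int tail_from = tail_avg ? (3 * n_epochs) / 4 : n_epochs;
  bool converged = false;
  int it = 0;

  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  arma::mat M(n, p);
  arma::vec yp(n);

  for (int e = 0; e < n_epochs; ++e) {
    // Fisher-Yates permutation from the R RNG
    for (int i = n - 1; i > 0; --i) {
      int k = (int)std::floor(unif_rand() * (i + 1));
      if (k > i) k = i;
      std::swap(perm[i], perm[k]);
    }
    if (q >= 1.0) {
      M = X; yp = y;
    } else {
      for (int i = 0; i < n; ++i) {
        yp[i] = y[perm[i]];
        for (int j = 0; j < p; ++j) {
          double mask = (unif_rand() < q) ? 1.0 / q : 0.0;
          M(i, j) = X(perm[i], j) * mask;
        }
      }
    }
    double t = step0 / (1.0 + decay * e);
    arma::vec grad = (2.0 / n) * (M.t() * (M * beta - yp));
    arma::vec u = beta - t * grad;
    double maxd = 0.0;
    for (int j = 0; j < p; ++j) {
      double bn = soft(u[j], t * lambda);
      double d = std::abs(bn - beta[j]);
      if (d > maxd) maxd = d;
      beta[j] = bn;
    }
    ++it;
    if (e >= tail_from) { acc += beta; ++n_acc; }
    if (q >= 1.0 && maxd < tol) { converged = true; break; }
  }
  if (tail_avg && n_acc > 0) beta = acc / n_acc;
  return List::create(_["beta"] = beta, _["iters"] = it,
                      _["converged"] = converged);
}
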