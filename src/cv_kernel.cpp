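// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Least-squares coefficients for [1 | X] via normal equations (Cholesky),
// falling back to the pseudoinverse when the Gram matrix is singular.
// pinv(X'X) X'y is the minimum-norm least-squares solution.
static vec ls_coef(const mat& X, const vec& y) {
  mat X1(X.n_rows, X.n_cols + 1);
  X1.col(0).ones();
  if (X.n_cols > 0) X1.cols(1, X.n_cols) = X;
  if (X1.n_cols > X1.n_rows) {
    // underdetermined: the minimum-norm solution X1' (X1 X1')^+ y via the
    // small n x n dual system instead of the large Gram matrix
    mat K = X1 * X1.t();
    vec a;
    bool ok = solve(a, K, y, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) a = pinv(K) * y;
    return X1.t() * a;
  }
  mat G = X1.t() * X1;
  vec b = X1.t() * y;
  vec coef;
  bool ok = solve(coef, G, b, solve_opts::likely_sympd + solve_opts::no_approx);
  if (!ok) coef = pinv(G) * b;
  return coef;
}

static double fold_r2(const mat& Xtr, const vec& ytr,
                      const mat& Xte, const vec& yte) {
  vec coef = ls_coef(Xtr, ytr);
  vec pred(Xte.n_rows, fill::value(coef(0)));
  if (Xte.n_cols > 0) pred += Xte * coef.subvec(1, Xte.n_cols);
  double mu = mean(yte);
  double sstot = accu(square(yte - mu));
  if (sstot <= 0.0) return NA_REAL;
  double ssres = accu(square(yte - pred));
  return 1.0 - ssres / sstot;
}

// Test-fold R^2 scores of an ordinary least-squares fit over p rounds of
// k-fold cross-validation. `folds` is n x p with fold labels 1..k.
// Returns a vector of length p * k (column-major by round, then fold).
// [[Rcpp::export]]
Rcpp::NumericVector cv_r2_scores_cpp(const arma::mat& Z,
                                     const arma::vec& y,
                                     const arma::imat& folds,
                                     int n_folds) {
  const uword n = Z.n_rows;
  const int p = folds.n_cols;
  Rcpp::NumericVector out(p * n_folds);
  int pos = 0;
  for (int r = 0; r < p; ++r) {
    for (int f = 1; f <= n_folds; ++f) {
      uvec te = find(folds.col(r) == f);
      uvec tr = find(folds.col(r) != f);
      if (te.n_elem == 0 || tr.n_elem < 2) {
        out[pos++] = NA_REAL;
        continue;
      }
      out[pos++] = fold_r2(Z.rows(tr), y.elem(tr), Z.rows(te), y.elem(te));
    }
  }
  (void)n;
  return out;
}

// Minimum-norm least-squares coefficients (intercept first), exported so the
// R-level MLR fit and the CV kernel share one solver.
// [[Rcpp::export]]
Rcpp::NumericVector ls_coef_cpp(const arma::mat& Z, const arma::vec& y) {
  vec coef = ls_coef(Z, y);
  return Rcpp::NumericVector(coef.begin(), coef.end());
}

static double median_finite(std::vector<double>& v) {
  std::vector<double> f;
  f.reserve(v.size());
  for (double x : v) if (std::isfinite(x)) f.push_back(x);
  if (f.empty()) return NA_REAL;
  std::sort(f.begin(), f.end());
  size_t m = f.size() / 2;
  return (f.size() % 2 == 1) ? f[m] : 0.5 * (f[m - 1] + f[m]);
}


// inv_sympd with a tiny diagonal jitter fallback. The quadratic universe is
// exactly collinear by construction (x_i = x_i x_j + x_i (1 - x_j) on every
// row), so Gram matrices of selected supports are routinely singular; under
// exact global collinearity test predictions are invariant across least-
// squares solutions, so a jittered inverse changes scores only at the
// jitter scale.
static bool inv_sympd_jitter(mat& out, const mat& G) {
  if (inv_sympd(out, G, inv_opts::no_ugly)) return true;
  double eps = 1e-10 * (1.0 + trace(G) / G.n_rows);
  mat Gj = G;
  Gj.diag() += eps;
  return inv_sympd(out, Gj, inv_opts::no_ugly);
}

// Full backward-elimination path. Maintains, per CV fold, the inverse Gram
// matrix of the active design and downdates it in O(k^2) after each
// permanent removal (the same Schur-complement identity used for candidate
// scoring), so one elimination pass over k descriptors costs O(k^3) per
// fold instead of O(k^4). Returns the removal order (1-based columns of Z),
// the score of the chosen candidate at each step, and the full-set score;
// the caller reconstructs the best prefix.
// [[Rcpp::export]]
Rcpp::List bs_path_cpp(const arma::mat& Z, const arma::vec& y,
                       const arma::imat& folds, int n_folds) {
  const uword k = Z.n_cols;
  const int p = folds.n_cols;
  const int nf = p * n_folds;

  struct FoldState {
    mat X1tr, X1te;
    vec ytr, yte;
    double sstot = 0.0;
    mat Ginv;
    vec b, w;
    bool usable = false;   // Schur path available
    bool scored = false;   // fold contributes scores at all
  };
  std::vector<FoldState> st(nf);

  int fi = 0;
  for (int r = 0; r < p; ++r) {
    for (int f = 1; f <= n_folds; ++f, ++fi) {
      FoldState& s = st[fi];
      uvec te = find(folds.col(r) == f);
      uvec tr = find(folds.col(r) != f);
      if (te.n_elem == 0 || tr.n_elem < 2) continue;
      s.ytr = y.elem(tr); s.yte = y.elem(te);
      double mu = mean(s.yte);
      s.sstot = accu(square(s.yte - mu));
      if (s.sstot <= 0.0) continue;
      s.X1tr.set_size(tr.n_elem, k + 1);
      s.X1te.set_size(te.n_elem, k + 1);
      s.X1tr.col(0).ones(); s.X1te.col(0).ones();
      if (k > 0) {
        s.X1tr.cols(1, k) = Z.rows(tr);
        s.X1te.cols(1, k) = Z.rows(te);
      }
      s.scored = true;
      if (s.X1tr.n_cols <= s.X1tr.n_rows) {
        mat G = s.X1tr.t() * s.X1tr;
        s.b = s.X1tr.t() * s.ytr;
        if (inv_sympd_jitter(s.Ginv, G)) {
          s.w = s.Ginv * s.b;
          s.usable = true;
        }
      }
    }
  }

  // full-set score
  std::vector<double> full_scores;
  for (auto& s : st) {
    if (!s.scored) { full_scores.push_back(NA_REAL); continue; }
    vec coef = s.usable ? s.w
                        : ls_coef(s.X1tr.cols(1, s.X1tr.n_cols - 1), s.ytr);
    vec pred = s.X1te * coef;
    full_scores.push_back(1.0 - accu(square(s.yte - pred)) / s.sstot);
  }
  double full_score = median_finite(full_scores);

  std::vector<int> order; order.reserve(k);
  std::vector<double> chosen; chosen.reserve(k);
  std::vector<int> active(k);
  for (uword d = 0; d < k; ++d) active[d] = d + 1;   // 1-based Z columns

  while (!active.empty()) {
    const size_t ka = active.size();
    // candidate scores: rows = candidate, filled per fold
    std::vector<std::vector<double>> cs(ka);
    for (auto& v : cs) v.reserve(nf);
    for (auto& s : st) {
      if (!s.scored) {
        for (size_t j = 0; j < ka; ++j) cs[j].push_back(NA_REAL);
        continue;
      }
      if (s.usable) {
        vec q = s.X1te * s.w;
        mat P = s.X1te * s.Ginv;
        for (size_t j = 0; j < ka; ++j) {
          uword c = j + 1;               // local column in X1 (0 = intercept)
          double alpha = s.Ginv(c, c);
          if (alpha <= 0.0) { cs[j].push_back(NA_REAL); continue; }
          vec pred = q - (s.w(c) / alpha) * P.col(c);
          cs[j].push_back(1.0 - accu(square(s.yte - pred)) / s.sstot);
        }
      } else {
        for (size_t j = 0; j < ka; ++j) {
          mat Zs = s.X1tr.cols(1, s.X1tr.n_cols - 1);
          mat Zts = s.X1te.cols(1, s.X1te.n_cols - 1);
          Zs.shed_col(j); Zts.shed_col(j);
          vec coef = ls_coef(Zs, s.ytr);
          vec pred(Zts.n_rows, fill::value(coef(0)));
          if (Zts.n_cols > 0) pred += Zts * coef.subvec(1, Zts.n_cols);
          cs[j].push_back(1.0 - accu(square(s.yte - pred)) / s.sstot);
        }
      }
    }
    size_t j_star = 0;
    double best_med = -datum::inf;
    for (size_t j = 0; j < ka; ++j) {
      double m = median_finite(cs[j]);
      double mv = std::isfinite(m) ? m : -datum::inf;
      if (mv > best_med) { best_med = mv; j_star = j; }
    }
    order.push_back(active[j_star]);
    chosen.push_back(best_med);
    active.erase(active.begin() + j_star);

    // permanently remove column j_star from every fold state
    uword c = j_star + 1;
    for (auto& s : st) {
      if (!s.scored) continue;
      if (s.usable) {
        double alpha = s.Ginv(c, c);
        vec u = s.Ginv.col(c);
        if (alpha > 1e-13 * (1.0 + std::abs(trace(s.Ginv)))) {
          mat Gnew = s.Ginv - (u * u.t()) / alpha;
          Gnew.shed_row(c); Gnew.shed_col(c);
          s.Ginv = Gnew;
          s.b.shed_row(c);
          s.X1tr.shed_col(c);
          s.X1te.shed_col(c);
          s.w = s.Ginv * s.b;
        } else {
          // ill-conditioned pivot: rebuild from scratch
          s.X1tr.shed_col(c);
          s.X1te.shed_col(c);
          mat G = s.X1tr.t() * s.X1tr;
          s.b = s.X1tr.t() * s.ytr;
          s.usable = inv_sympd_jitter(s.Ginv, G);
          if (s.usable) s.w = s.Ginv * s.b;
        }
      } else {
        s.X1tr.shed_col(c);
        s.X1te.shed_col(c);
        // retry the fast path at the smaller size
        if (s.X1tr.n_cols <= s.X1tr.n_rows) {
          mat G = s.X1tr.t() * s.X1tr;
          s.b = s.X1tr.t() * s.ytr;
          s.usable = inv_sympd_jitter(s.Ginv, G);
          if (s.usable) s.w = s.Ginv * s.b;
        }
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("full_score") = full_score,
    Rcpp::Named("order") = Rcpp::IntegerVector(order.begin(), order.end()),
    Rcpp::Named("chosen_scores") = Rcpp::NumericVector(chosen.begin(), chosen.end()));
}
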