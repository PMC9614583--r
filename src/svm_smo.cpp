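#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Sequential minimal optimisation for the linear C-SVC dual, operating on
// a precomputed Gram matrix. Working-set selection is second order
// (maximal violating i, gain-maximising j), with the Keerthi stopping
// rule: converged when max_{I_up} F - min_{I_low} F < eps, where
// F_t = y_t - u_t and u_t = sum_s alpha_s y_s K_ts.
// alpha/u may carry a warm start (must satisfy sum alpha*y = 0, box
// constraints, and u consistent with alpha).
static void smo_solve(const mat& K, const vec& y, double C, double eps,
                      int max_iter, vec& alpha, vec& u) {
  const int n = K.n_rows;
  const double tau = 1e-12, bnd = 1e-12;
  for (int it = 0; it < max_iter; ++it) {
    // i: most violating index in I_up
    double Fmax = -datum::inf;
    int i = -1;
    for (int t = 0; t < n; ++t) {
      const bool up = (y(t) > 0) ? (alpha(t) < C - bnd) : (alpha(t) > bnd);
      if (!up) continue;
      const double F = y(t) - u(t);
      if (F > Fmax) { Fmax = F; i = t; }
    }
    if (i < 0) break;
    // j: gain-maximising violator in I_low
    double Fmin = datum::inf, best_gain = -1.0;
    int j = -1;
    for (int t = 0; t < n; ++t) {
      const bool low = (y(t) > 0) ? (alpha(t) > bnd) : (alpha(t) < C - bnd);
      if (!low) continue;
      const double F = y(t) - u(t);
      if (F < Fmin) Fmin = F;
      const double diff = Fmax - F;
      if (diff > 0) {
        double a = K(i, i) + K(t, t) - 2.0 * K(i, t);
        if (a < tau) a = tau;
        const double gain = diff * diff / a;
        if (gain > best_gain) { best_gain = gain; j = t; }
      }
    }
    if (j < 0 || Fmax - Fmin < eps) break;

    const double s = y(i) * y(j);
    double L, H;
    if (s < 0) {
      L = std::max(0.0, alpha(j) - alpha(i));
      H = std::min(C, C + alpha(j) - alpha(i));
    } else {
      L = std::max(0.0, alpha(i) + alpha(j) - C);
      H = std::min(C, alpha(i) + alpha(j));
    }
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < tau) eta = tau;
    // Platt update on alpha_j; E_i - E_j = (u_i - u_j) - (y_i - y_j)
    double aj = alpha(j) + y(j) * ((u(i) - u(j)) - (y(i) - y(j))) / eta;
    aj = std::min(H, std::max(L, aj));
    const double dj = aj - alpha(j);
    if (std::fabs(dj) < 1e-14) break;  // numerically stalled at the box
    const double ai = alpha(i) - s * dj;
    u += (ai - alpha(i)) * y(i) * K.col(i) + dj * y(j) * K.col(j);
    alpha(i) = ai;
    alpha(j) = aj;
  }
}

// bias from the final KKT interval
static double smo_bias(const vec& y, const vec& u, const vec& alpha,
                       double C) {
  const int n = y.n_elem;
  const double bnd = 1e-12;
  double m = -datum::inf, M = datum::inf;
  for (int t = 0; t < n; ++t) {
    const double F = y(t) - u(t);
    const bool up  = (y(t) > 0) ? (alpha(t) < C - bnd) : (alpha(t) > bnd);
    const bool low = (y(t) > 0) ? (alpha(t) > bnd)     : (alpha(t) < C - bnd);
    if (up && F > m)  m = F;
    if (low && F < M) M = F;
  }
  if (std::isfinite(m) && std::isfinite(M)) return 0.5 * (m + M);
  if (std::isfinite(m)) return m;
  if (std::isfinite(M)) return M;
  return 0.0;
}

// [[Rcpp::export(name = ".svm_train_cpp")]]
Rcpp::List svm_train_cpp(const arma::mat& X, const arma::vec& y,
                         double C, double eps, int max_iter) {
  const mat K = X * X.t();
  vec alpha(X.n_rows, fill::zeros), u(X.n_rows, fill::zeros);
  smo_solve(K, y, C, eps, max_iter, alpha, u);
  const vec w = X.t() * (alpha % y);
  return Rcpp::List::create(Rcpp::Named("w") = w,
                            Rcpp::Named("b") = smo_bias(y, u, alpha, C),
                            Rcpp::Named("alpha") = alpha);
}

// Cross-validated prediction: for each fold id, train on the remaining
// samples and predict the held-out ones with sign(w.x + b). The Gram
// matrix is computed once; each fold's solution is warm-started from the
// full-sample solution (with the held-out subjects' alpha mass
// redistributed to keep the equality constraint feasible), which makes
// leave-one-pair-out folds converge in a handful of SMO steps.
// Ties (score exactly 0) are assigned to the negative class.
// [[Rcpp::export(name = ".svm_cv_predict_cpp")]]
arma::vec svm_cv_predict_cpp(const arma::mat& X, const arma::vec& y,
                             const arma::ivec& fold, double C, double eps,
                             int max_iter) {
  const int n = X.n_rows;
  const mat K = X * X.t();
  vec pred(n, fill::zeros);

  vec alpha_full(n, fill::zeros), u_full(n, fill::zeros);
  smo_solve(K, y, C, eps, max_iter, alpha_full, u_full);

  const int nf = fold.max();
  for (int f = 1; f <= nf; ++f) {
    const uvec test_idx  = find(fold == f);
    const uvec train_idx = find(fold != f);
    if (test_idx.n_elem == 0) continue;
    const int m = train_idx.n_elem;
    const mat Ktr = K.submat(train_idx, train_idx);
    const vec ytr = y(train_idx);

    // warm start from the full solution
    vec alpha = alpha_full(train_idx);
    // restore sum(alpha * y) = 0 after dropping the held-out subjects
    double resid = -dot(alpha, ytr);  // amount of y-weighted mass missing
    for (int t = 0; t < m && std::fabs(resid) > 1e-12; ++t) {
      // adding d to alpha_t changes the sum by y_t d
      const double d_needed = resid * ytr(t);
      double d = d_needed;
      if (d > 0) d = std::min(d, C - alpha(t));
      else       d = std::max(d, -alpha(t));
      alpha(t) += d;
      resid -= d * ytr(t);
    }
    vec u = Ktr * (alpha % ytr);
    smo_solve(Ktr, ytr, C, eps, max_iter, alpha, u);
    const double b = smo_bias(ytr, u, alpha, C);

    const mat Kte = K.submat(test_idx, train_idx);
    const vec score = Kte * (alpha % ytr) + b;
    for (uword k = 0; k < test_idx.n_elem; ++k)
      pred(test_idx(k)) = (score(k) > 0.0) ? 1.0 : -1.0;
  }
  return pred;
}
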