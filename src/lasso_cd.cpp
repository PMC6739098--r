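#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-descent solver for the penalised least squares objective
//   ||y - X beta||_2^2 + lambda * sum_j w_j |beta_j|
// (no 1/(2n) factor; the penalty convention matches the printed objective).
// X is assumed column-standardised (or at least centred) by the caller when
// a shared lambda grid across variables is intended; the solver itself makes
// no such assumption. Residual-update form: O(n) per coordinate visit.

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// One sweep over the coordinates listed in idx; returns the largest
// coefficient update.
static double cd_sweep(const NumericMatrix& X, NumericVector& beta,
                       NumericVector& resid, const NumericVector& xtx,
                       double lam, const NumericVector& w,
                       const std::vector<int>& idx) {
  const int n = X.nrow();
  double max_delta = 0.0;
  for (size_t k = 0; k < idx.size(); ++k) {
    const int j = idx[k];
    if (xtx[j] <= 0.0) { beta[j] = 0.0; continue; }
    const double* xj = &X(0, j);
    double rho = 0.0;
    for (int i = 0; i < n; ++i) rho += xj[i] * resid[i];
    rho += xtx[j] * beta[j];
    // minimiser of xtx_j b^2 - 2 rho b + lam w_j |b|
    double bj = soft_threshold(rho, 0.5 * lam * w[j]) / xtx[j];
    double delta = bj - beta[j];
    if (delta != 0.0) {
      for (int i = 0; i < n; ++i) resid[i] -= delta * xj[i];
      beta[j] = bj;
      double ad = std::fabs(delta);
      if (ad > max_delta) max_delta = ad;
    }
  }
  return max_delta;
}

// Coordinate-descent solve at one lambda, warm-started from beta/resid in
// place. Full sweeps alternate with inner iterations restricted to the
// current active set until a full sweep introduces no new variables and
// moves nothing beyond tol. Returns sweeps used (maxit + 1 if not
// converged).
static int cd_solve(const NumericMatrix& X, NumericVector& beta,
                    NumericVector& resid, const NumericVector& xtx,
                    double lam, const NumericVector& w,
                    double tol, int maxit) {
  const int p = X.ncol();
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;
  int used = 0;
  while (used < maxit) {
    double full_delta = cd_sweep(X, beta, resid, xtx, lam, w, all);
    ++used;
    if (full_delta < tol) return used;
    std::vector<int> active;
    active.reserve(p);
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
    while (used < maxit) {
      double d = cd_sweep(X, beta, resid, xtx, lam, w, active);
      ++used;
      if (d < tol) break;
    }
  }
  return maxit + 1;
}

// [[Rcpp::export(name = ".cd_lasso_single")]]
List cd_lasso_single(NumericMatrix X, NumericVector y, double lam,
                     NumericVector w, double tol, int maxit,
                     NumericVector beta0) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector beta = clone(beta0);
  NumericVector resid(n);
  NumericVector xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  for (int i = 0; i < n; ++i) {
    double f = 0.0;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) f += X(i, j) * beta[j];
    resid[i] = y[i] - f;
  }
  int used = cd_solve(X, beta, resid, xtx, lam, w, tol, maxit);
  return List::create(_["beta"] = beta,
                      _["converged"] = used <= maxit,
                      _["iter"] = used);
}

// Full path over a (descending) lambda sequence with warm starts.
// Returns p x nlambda coefficient matrix.
// [[Rcpp::export(name = ".cd_lasso_path")]]
NumericMatrix cd_lasso_path(NumericMatrix X, NumericVector y,
                            NumericVector lambdas, NumericVector w,
                            double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  NumericMatrix out(p, L);
  NumericVector beta(p), resid = clone(y), xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  for (int l = 0; l < L; ++l) {
    cd_solve(X, beta, resid, xtx, lambdas[l], w, tol, maxit);
    for (int j = 0; j < p; ++j) out(j, l) = beta[j];
  }
  return out;
}

// Selection indicator over a lambda path: which variables are ever nonzero
// at each lambda. Avoids materialising coefficients when only selection
// frequencies are needed (stability selection inner loop).
// [[Rcpp::export(name = ".cd_lasso_path_support")]]
LogicalMatrix cd_lasso_path_support(NumericMatrix X, NumericVector y,
                                    NumericVector lambdas, NumericVector w,
                                    double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  LogicalMatrix out(p, L);
  NumericVector beta(p), resid = clone(y), xtx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  for (int l = 0; l < L; ++l) {
    cd_solve(X, beta, resid, xtx, lambdas[l], w, tol, maxit);
    for (int j = 0; j < p; ++j) out(j, l) = beta[j] != 0.0;
  }
  return out;
}
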