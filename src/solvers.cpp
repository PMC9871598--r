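// Coordinate-descent solvers used by the estimators:
//  - cd_lasso_cols: column-wise lasso with a structural zero diagonal,
//    the W-step shared by SR and the noise-depressed variants.
//  - glasso_cpp: block-coordinate graphical lasso (Friedman et al. scheme),
//    the Omega-step under the L1 noise prior.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// min_W ||Y - Y W||_F^2 + lambda * ||W||_1  s.t. w_ii = 0
// Solved per column on the Gram matrix G = Y'Y; for coordinate j of column i
// the update is w_j <- S(c_j - sum_{k!=j} G_jk w_k, lambda/2) / G_jj with
// c = G[, i]. The objective carries no 1/2 or 1/T factor, so the soft
// threshold is lambda/2 and any lambda >= 2 zeroes W on unit-norm columns.
// Convergence: max coefficient change in a sweep <= tol * max(1, max|w|),
// i.e. absolute for O(1) coefficients and relative for larger ones. An
// optional warm start (previous W) is used by the alternating estimators.
// [[Rcpp::export]]
Rcpp::List cd_lasso_cols(const arma::mat& Y, double lambda, double tol,
                         int max_iter,
                         Rcpp::Nullable<Rcpp::NumericMatrix> w_init =
                             R_NilValue) {
  const uword n = Y.n_cols;
  mat G = Y.t() * Y;
  mat W(n, n, fill::zeros);
  bool have_init = w_init.isNotNull();
  mat W0;
  if (have_init) {
    W0 = Rcpp::as<mat>(w_init);
    if (W0.n_rows != n || W0.n_cols != n) Rcpp::stop("w_init has wrong size");
  }
  Rcpp::IntegerVector iters(n);
  bool converged = true;

  for (uword i = 0; i < n; ++i) {
    vec w(n, fill::zeros);
    if (have_init) {
      w = W0.col(i);
      w(i) = 0.0;
    }
    vec gw = G * w;  // maintained incrementally
    const vec c = G.col(i);
    int it = 0;
    double maxdiff = std::numeric_limits<double>::infinity();
    double thr = tol;
    while (it < max_iter && maxdiff > thr) {
      maxdiff = 0.0;
      double wmax = 1.0;
      for (uword j = 0; j < n; ++j) {
        if (j == i) continue;
        const double gjj = G(j, j);
        if (gjj <= 1e-300) continue;
        const double z = c(j) - (gw(j) - gjj * w(j));
        const double wj_new = soft_threshold(z, lambda / 2.0) / gjj;
        const double d = wj_new - w(j);
        if (d != 0.0) {
          gw += d * G.col(j);
          w(j) = wj_new;
          const double ad = std::fabs(d);
          if (ad > maxdiff) maxdiff = ad;
        }
        const double aw = std::fabs(w(j));
        if (aw > wmax) wmax = aw;
      }
      thr = tol * wmax;
      ++it;
    }
    iters(i) = it;
    if (maxdiff > thr) converged = false;
    W.col(i) = w;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("iterations") = iters,
                            Rcpp::Named("converged") = converged);
}

// min_Theta tr(S Theta) - log|Theta| + rho * ||Theta||_1   (diagonal penalised)
// Block coordinate descent on the covariance estimate: start from
// Wcov = S + rho I, cycle columns solving the dual lasso subproblem
//   min_b 0.5 b' W11 b - s12' b + rho ||b||_1
// and recover Theta from the regression coefficients at the end.
// [[Rcpp::export]]
arma::mat glasso_cpp(const arma::mat& S, double rho, double tol, int max_iter,
                     int inner_max_iter) {
  const uword p = S.n_rows;
  mat Wcov = S;
  Wcov.diag() += rho;
  mat Beta(p > 0 ? p - 1 : 0, p, fill::zeros);

  // convergence threshold relative to the mean absolute off-diagonal of S
  double sbar = 0.0;
  if (p > 1) {
    for (uword i = 0; i < p; ++i)
      for (uword j = 0; j < p; ++j)
        if (i != j) sbar += std::fabs(S(i, j));
    sbar /= double(p) * double(p - 1);
  }
  const double thr = tol * (sbar > 0.0 ? sbar : 1.0);
  const double inner_thr = thr / 10.0;

  std::vector<uvec> drop(p);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword k = 0;
    for (uword i = 0; i < p; ++i)
      if (i != j) idx(k++) = i;
    drop[j] = idx;
  }

  for (int iter = 0; iter < max_iter; ++iter) {
    double maxd = 0.0;
    for (uword j = 0; j < p; ++j) {
      const uvec& idx = drop[j];
      mat W11 = Wcov.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = Beta.col(j);
      vec v = W11 * beta;
      double md = std::numeric_limits<double>::infinity();
      for (int t = 0; t < inner_max_iter && md > inner_thr; ++t) {
        md = 0.0;
        for (uword q = 0; q < p - 1; ++q) {
          const double wqq = W11(q, q);
          if (wqq <= 1e-300) continue;
          const double z = s12(q) - (v(q) - wqq * beta(q));
          const double bn = soft_threshold(z, rho) / wqq;
          const double d = bn - beta(q);
          if (d != 0.0) {
            v += d * W11.col(q);
            beta(q) = bn;
            const double ad = std::fabs(d);
            if (ad > md) md = ad;
          }
        }
      }
      Beta.col(j) = beta;
      vec w12 = W11 * beta;
      for (uword q = 0; q < p - 1; ++q) {
        const double d = std::fabs(w12(q) - Wcov(idx(q), j));
        if (d > maxd) maxd = d;
        Wcov(idx(q), j) = w12(q);
        Wcov(j, idx(q)) = w12(q);
      }
    }
    if (maxd < thr) break;
  }

  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    const uvec& idx = drop[j];
    vec beta = Beta.col(j);
    vec w12 = Wcov.col(j);
    w12 = w12.elem(idx);
    const double tjj = 1.0 / (Wcov(j, j) - dot(w12, beta));
    Theta(j, j) = tjj;
    for (uword q = 0; q < p - 1; ++q) Theta(idx(q), j) = -beta(q) * tjj;
  }
  return 0.5 * (Theta + Theta.t());
}
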