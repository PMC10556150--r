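#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Soft-threshold operator used by the lasso coordinate descent.
static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Lasso subproblem: minimise 0.5 * b' V b - b' u + lambda * ||b||_1
// by cyclic coordinate descent, warm-started at `beta`.
static void lasso_cd(const mat& V, const vec& u, double lambda, vec& beta,
                     int max_iter, double tol) {
  const uword p = u.n_elem;
  for (int it = 0; it < max_iter; ++it) {
    double max_delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      double old = beta(j);
      double grad = u(j) - dot(V.col(j), beta) + V(j, j) * old;
      double bj = soft(grad, lambda) / V(j, j);
      if (bj != old) {
        beta(j) = bj;
        double d = std::abs(bj - old);
        if (d > max_delta) max_delta = d;
      }
    }
    if (max_delta < tol) break;
  }
}

// Graphical lasso, Friedman-style block coordinate descent on the working
// covariance W. Off-diagonal L1 penalty only: maximises
//   log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|.
// Returns the precision matrix Theta; attributes carry convergence info.
// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      int max_outer = 200, double tol = 1e-6,
                      int max_inner = 500) {
  const uword p = S.n_rows;
  mat W = S;            // diagonal unpenalised: W_ii = S_ii throughout
  mat B(p, p, fill::zeros); // column j holds the lasso coefficients beta_j

  double off_mean = 0.0;
  if (p > 1) {
    mat A = abs(S);
    off_mean = (accu(A) - trace(A)) / double(p * (p - 1));
  }
  double thr = tol * std::max(off_mean, 1e-12);

  bool converged = (p == 1);
  int iters = 0;
  for (int it = 0; it < max_outer && !converged; ++it) {
    double max_change = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(regspace<uvec>(0, p - 1) != j);
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec beta = B.col(j);
      vec beta_sub = beta.elem(idx);
      lasso_cd(W11, s12, lambda, beta_sub, max_inner, 1e-8);
      vec w12 = W11 * beta_sub;
      for (uword k = 0; k < idx.n_elem; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > max_change) max_change = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
      beta.zeros();
      beta.elem(idx) = beta_sub;
      B.col(j) = beta;
    }
    iters = it + 1;
    if (max_change < thr) converged = true;
  }

  // Recover Theta from W and the regression coefficients.
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(regspace<uvec>(0, p - 1) != j);
    vec beta_sub = B.col(j);
    beta_sub = beta_sub.elem(idx);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double theta_jj = 1.0 / (W(j, j) - dot(w12, beta_sub));
    Theta(j, j) = theta_jj;
    vec t12 = -beta_sub * theta_jj;
    for (uword k = 0; k < idx.n_elem; ++k) Theta(idx(k), j) = t12(k);
  }
  Theta = 0.5 * (Theta + Theta.t()); // symmetrise numerical asymmetry

  // Duality gap for the penalised log-likelihood: tr(S Theta) - p + lambda*||Theta||_1,off
  mat A = abs(Theta);
  double l1_off = accu(A) - trace(A);
  double gap = dot(vectorise(S), vectorise(Theta)) - double(p) + lambda * l1_off;

  return Rcpp::List::create(
    Rcpp::Named("theta") = Theta,
    Rcpp::Named("w") = W,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("dual_gap") = gap);
}
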