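#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double l1_dist(const mat& X, uword i, const mat& C, uword c) {
  return accu(abs(X.row(i) - C.row(c)));
}

// Column-wise median of the rows of X indexed by idx.
static rowvec median_rows(const mat& X, const uvec& idx) {
  mat sub = X.rows(idx);
  return median(sub, 0);
}

// Lloyd iterations for city-block k-means: L1 assignment, coordinate-wise
// median update. Ties in assignment go to the lowest centroid index. An
// emptied cluster is re-seeded at the observation farthest (L1) from its
// assigned centroid. Deterministic given the initial centroids.
// [[Rcpp::export(name = ".kmeans_l1_cpp")]]
Rcpp::List kmeans_l1_cpp(const arma::mat& X, arma::mat C,
                         int max_iter = 100) {
  const uword n = X.n_rows, k = C.n_rows;
  uvec assign(n, fill::zeros);
  vec d_assigned(n);
  std::vector<double> cost_trace;

  for (int it = 0; it < max_iter; ++it) {
    // assignment step
    bool changed = (it == 0);
    for (uword i = 0; i < n; ++i) {
      double best = datum::inf;
      uword best_c = 0;
      for (uword c = 0; c < k; ++c) {
        double d = l1_dist(X, i, C, c);
        if (d < best - 1e-15) { best = d; best_c = c; }
      }
      if (assign(i) != best_c) { assign(i) = best_c; changed = true; }
      d_assigned(i) = best;
    }

    // empty-cluster repair: re-seed at the farthest observation
    for (uword c = 0; c < k; ++c) {
      if (!any(assign == c)) {
        uword far = index_max(d_assigned);
        C.row(c) = X.row(far);
        assign(far) = c;
        d_assigned(far) = 0.0;
        changed = true;
      }
    }

    cost_trace.push_back(accu(d_assigned));
    if (!changed && it > 0) break;

    // update step: coordinate-wise median
    for (uword c = 0; c < k; ++c) {
      uvec idx = find(assign == c);
      if (idx.n_elem > 0) C.row(c) = median_rows(X, idx);
    }
  }

  // final assignment against the last centroids
  for (uword i = 0; i < n; ++i) {
    double best = datum::inf;
    uword best_c = 0;
    for (uword c = 0; c < k; ++c) {
      double d = l1_dist(X, i, C, c);
      if (d < best - 1e-15) { best = d; best_c = c; }
    }
    assign(i) = best_c;
    d_assigned(i) = best;
  }
  cost_trace.push_back(accu(d_assigned));

  return Rcpp::List::create(
    Rcpp::Named("centroids") = C,
    Rcpp::Named("labels") = assign + 1, // 1-based state labels
    Rcpp::Named("cost") = accu(d_assigned),
    Rcpp::Named("cost_trace") = cost_trace);
}

// L1-nearest-centroid assignment; ties to the lowest centroid index.
// [[Rcpp::export(name = ".assign_l1_cpp")]]
Rcpp::IntegerVector assign_l1_cpp(const arma::mat& X, const arma::mat& C) {
  const uword n = X.n_rows, k = C.n_rows;
  Rcpp::IntegerVector out(n);
  for (uword i = 0; i < n; ++i) {
    double best = datum::inf;
    uword best_c = 0;
    for (uword c = 0; c < k; ++c) {
      double d = l1_dist(X, i, C, c);
      if (d < best - 1e-15) { best = d; best_c = c; }
    }
    out[i] = int(best_c) + 1;
  }
  return out;
}
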