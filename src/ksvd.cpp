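#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One K-SVD dictionary-update pass (Gauss-Seidel over atoms).
// For atom k with users U: E_k = Y_U - D A_U + d_k a_kU' is never formed;
// its leading singular pair is found by power iteration applied through
// matrix-vector products. Dead atoms are replaced by the currently
// worst-represented signal. Sign fixed so each updated atom has a
// nonnegative element sum. Returns the updated dictionary and the updated
// coefficient values on the unchanged sparsity pattern.
// [[Rcpp::export]]
List cpp_ksvd_update(arma::mat D, const arma::mat &Y, IntegerVector ci,
                     IntegerVector cj, NumericVector cx, int max_power,
                     double pow_tol) {
  const int K = D.n_cols;
  const int m = Y.n_cols;
  arma::mat A(K, m, arma::fill::zeros);
  const int nnz = ci.size();
  for (int t = 0; t < nnz; ++t) A(ci[t] - 1, cj[t] - 1) = cx[t];
  // residual norms per signal (for dead-atom replacement); uses the
  // sparsity of the code instead of a dense multiply
  const int n = Y.n_rows;
  arma::vec resid(m);
  {
    std::vector<double> rbuf(n);
    int t = 0;
    for (int j = 0; j < m; ++j) {
      const double *yj = Y.colptr(j);
      std::copy(yj, yj + n, rbuf.data());
      while (t < nnz && cj[t] == j + 1) {
        const double *atom = D.colptr(ci[t] - 1);
        const double x = cx[t];
        for (int r = 0; r < n; ++r) rbuf[r] -= x * atom[r];
        ++t;
      }
      double s = 0.0;
      for (int r = 0; r < n; ++r) s += rbuf[r] * rbuf[r];
      resid[j] = std::sqrt(s);
    }
  }
  std::vector<bool> taken(m, false);
  for (int k = 0; k < K; ++k) {
    arma::uvec users = arma::find(A.row(k) != 0.0);
    if (users.n_elem == 0) {
      // replace with the worst-represented signal not already taken
      int best = -1;
      double bv = -1.0;
      for (int j = 0; j < m; ++j)
        if (!taken[j] && resid[j] > bv) { bv = resid[j]; best = j; }
      if (best >= 0) {
        double nv = arma::norm(Y.col(best));
        if (nv > 0) {
          D.col(k) = Y.col(best) / nv;
          taken[best] = true;
        }
      }
      continue;
    }
    arma::mat Yu = Y.cols(users);
    arma::mat Au = A.cols(users);
    arma::rowvec akr = A.row(k);
    arma::vec ak(users.n_elem);
    for (arma::uword t = 0; t < users.n_elem; ++t) ak[t] = akr[users[t]];
    arma::vec d = D.col(k);
    arma::vec g = ak;
    for (int it = 0; it < max_power; ++it) {
      // g <- E_k' d ; d <- E_k g ; normalize
      arma::vec gn = Yu.t() * d - Au.t() * (D.t() * d) + ak * arma::dot(D.col(k), d);
      arma::vec dn = Yu * gn - D * (Au * gn) + D.col(k) * arma::dot(ak, gn);
      double nd = arma::norm(dn);
      if (nd == 0) break;
      dn /= nd;
      double diff = arma::norm(dn - d);
      d = dn;
      g = gn;
      if (diff < pow_tol && it > 0) break;
    }
    g = Yu.t() * d - Au.t() * (D.t() * d) + ak * arma::dot(D.col(k), d);
    if (arma::accu(d) < 0) { d = -d; g = -g; }
    D.col(k) = d;
    for (arma::uword t = 0; t < users.n_elem; ++t) A(k, users[t]) = g[t];
  }
  // cleanup pass: an atom nearly collinear with another, or used by
  // almost no signal, contributes no representational power; replace it
  // with a poorly represented signal (the next re-encode redistributes
  // its coefficients)
  arma::mat G = D.t() * D;
  for (int k = 0; k < K; ++k) {
    double coh = 0.0;
    for (int j = 0; j < K; ++j)
      if (j != k) coh = std::max(coh, std::fabs(G(k, j)));
    int usage = 0;
    for (int j = 0; j < m; ++j)
      if (A(k, j) != 0.0) ++usage;
    if (coh > 0.99 || usage < 4) {
      int best = -1;
      double bv = -1.0;
      for (int j = 0; j < m; ++j)
        if (!taken[j] && resid[j] > bv) { bv = resid[j]; best = j; }
      if (best >= 0) {
        double nv = arma::norm(Y.col(best));
        if (nv > 0) {
          D.col(k) = Y.col(best) / nv;
          A.row(k).zeros();
          taken[best] = true;
          G.row(k) = D.col(k).t() * D;
          G.col(k) = G.row(k).t();
        }
      }
    }
  }
  NumericVector nx(nnz);
  for (int t = 0; t < nnz; ++t) nx[t] = A(ci[t] - 1, cj[t] - 1);
  return List::create(_["D"] = D, _["x"] = nx);
}
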