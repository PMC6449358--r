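#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Orthogonal matching pursuit against a precomputed Gram matrix, with a
// progressive Cholesky factorisation of G[S,S] so each step costs O(K*l)
// and no heap allocation. Selection: largest |correlation| with the
// current residual, ties to the lowest atom index; refit by least squares
// on the accumulated support; stop at L atoms or residual <= tol*||y||.
struct OmpWork {
  std::vector<double> c;      // residual correlations, length K
  std::vector<double> Lmat;   // lower-triangular factor, L x L
  std::vector<double> pS, v, z, w;
  std::vector<int> S;
  void resize(int K, int L) {
    c.resize(K);
    Lmat.resize((size_t)L * L);
    pS.resize(L);
    v.resize(L);
    z.resize(L);
    w.resize(L);
    S.resize(L);
  }
};

// returns the number of selected atoms; fills work.S / work.w
static int omp_fast(const double *G, int K, const double *p0, double normY2,
                    int L, double tol, OmpWork &wk, double &res2_out) {
  res2_out = normY2;
  if (normY2 <= 0.0) return 0;
  const double tol2 = tol * tol * normY2;
  double *c = wk.c.data();
  double *Lm = wk.Lmat.data();
  double *pS = wk.pS.data();
  double *v = wk.v.data();
  double *z = wk.z.data();
  double *w = wk.w.data();
  int *S = wk.S.data();
  std::copy(p0, p0 + K, c);
  int nsel = 0;
  double res2 = normY2;
  for (int l = 0; l < L; ++l) {
    int best = -1;
    double bv = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = std::fabs(c[k]);
      if (a > bv) { bv = a; best = k; }
    }
    if (best < 0 || bv == 0.0) break;
    const double *gj = G + (size_t)best * K;
    // progressive Cholesky: solve Lm v = G[S, best]
    for (int t = 0; t < nsel; ++t) {
      double s = gj[S[t]];
      for (int u = 0; u < t; ++u) s -= Lm[t * L + u] * v[u];
      v[t] = s / Lm[t * L + t];
    }
    double d2 = gj[best];
    for (int t = 0; t < nsel; ++t) d2 -= v[t] * v[t];
    if (d2 <= 1e-12) break;  // atom (near-)dependent on the support
    for (int t = 0; t < nsel; ++t) Lm[nsel * L + t] = v[t];
    Lm[nsel * L + nsel] = std::sqrt(d2);
    S[nsel] = best;
    pS[nsel] = p0[best];
    ++nsel;
    // w = (G[S,S])^{-1} p_S via the two triangular solves
    for (int t = 0; t < nsel; ++t) {
      double s = pS[t];
      for (int u = 0; u < t; ++u) s -= Lm[t * L + u] * z[u];
      z[t] = s / Lm[t * L + t];
    }
    for (int t = nsel - 1; t >= 0; --t) {
      double s = z[t];
      for (int u = t + 1; u < nsel; ++u) s -= Lm[u * L + t] * w[u];
      w[t] = s / Lm[t * L + t];
    }
    // c = p0 - G[,S] w, zeroed on the support
    std::copy(p0, p0 + K, c);
    for (int t = 0; t < nsel; ++t) {
      const double *gs = G + (size_t)S[t] * K;
      const double wt = w[t];
      for (int k = 0; k < K; ++k) c[k] -= wt * gs[k];
    }
    res2 = normY2;
    for (int t = 0; t < nsel; ++t) {
      c[S[t]] = 0.0;
      res2 -= w[t] * pS[t];
    }
    if (res2 <= tol2) break;
  }
  res2_out = res2 > 0 ? res2 : 0.0;
  return nsel;
}

// Batch OMP over the columns of Y. When a previous code is supplied
// (old_i/old_j 1-based, old_j non-decreasing), each column keeps whichever
// of {new greedy code, previous code} has the smaller residual under D --
// the descent safeguard used between K-SVD iterations.
// [[Rcpp::export]]
List cpp_batch_omp(const arma::mat &D, const arma::mat &Y, int L, double tol,
                   IntegerVector old_i, IntegerVector old_j,
                   NumericVector old_x) {
  const int m = Y.n_cols;
  const int K = D.n_cols;
  arma::mat G = D.t() * D;
  arma::mat P = D.t() * Y;
  OmpWork wk;
  wk.resize(K, std::min(L, K));
  std::vector<int> ti, tj;
  std::vector<double> tx;
  NumericVector resid(m), scores(m);
  ti.reserve((size_t)m * L);
  tj.reserve((size_t)m * L);
  tx.reserve((size_t)m * L);
  int op = 0;  // cursor into the old code triplets
  const int nold = old_i.size();
  std::vector<int> S0(K);
  std::vector<double> w0(K);
  for (int j = 0; j < m; ++j) {
    double normY2 = arma::dot(Y.col(j), Y.col(j));
    double res2;
    int nsel = omp_fast(G.memptr(), K, P.colptr(j), normY2,
                        std::min(L, K), tol, wk, res2);
    int *S = wk.S.data();
    double *w = wk.w.data();
    // residual of the previous code under the current dictionary
    int o0 = op;
    while (op < nold && old_j[op] == j + 1) ++op;
    if (op > o0) {
      int u = op - o0;
      double old_r2 = normY2;
      const double *pj = P.colptr(j);
      for (int t = 0; t < u; ++t) {
        S0[t] = old_i[o0 + t] - 1;
        w0[t] = old_x[o0 + t];
        old_r2 -= 2.0 * w0[t] * pj[S0[t]];
      }
      for (int t = 0; t < u; ++t)
        for (int s = 0; s < u; ++s)
          old_r2 += w0[t] * w0[s] * G(S0[t], S0[s]);
      if (old_r2 < res2) {
        nsel = u;
        S = S0.data();
        w = w0.data();
        res2 = old_r2;
      }
    }
    double sc = 0.0;
    for (int t = 0; t < nsel; ++t) {
      ti.push_back(S[t] + 1);
      tj.push_back(j + 1);
      tx.push_back(w[t]);
      sc += std::fabs(w[t]);
    }
    resid[j] = res2 > 0 ? std::sqrt(res2) : 0.0;
    scores[j] = sc;
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx),
                      _["residual"] = resid, _["score"] = scores);
}

// Full-volume encoding without materialising the (n x m) patch matrix:
// extracts patches chunk-wise in raster order, OMP-encodes each chunk and
// accumulates the reconstruction D*alpha and the per-patch |alpha| sums.
// [[Rcpp::export]]
List cpp_encode_volume(NumericVector vol, IntegerVector dims,
                       IntegerVector psz, const arma::mat &D, int L,
                       double tol, int chunk, bool keep_code) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int N1 = psz[0], N2 = psz[1], M = psz[2];
  const int nx = X - N1 + 1, ny = Y - N2 + 1, nz = Z - M + 1;
  const size_t m = (size_t)nx * ny * nz;
  const int n = N1 * N2 * M;
  const int K = D.n_cols;
  arma::mat G = D.t() * D;
  OmpWork wk;
  wk.resize(K, std::min(L, K));
  NumericVector sum((size_t)X * Y * Z), cov((size_t)X * Y * Z);
  NumericVector scores(m);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (keep_code) {
    ti.reserve(m * L);
    tj.reserve(m * L);
    tx.reserve(m * L);
  }
  arma::mat Yc(n, chunk);
  std::vector<double> rec(n);
  size_t idx = 0;
  while (idx < m) {
    int B = (int)std::min((size_t)chunk, m - idx);
    for (int b = 0; b < B; ++b) {
      size_t id = idx + b;
      int ox = id % nx, oy = (id / nx) % ny, oz = id / ((size_t)nx * ny);
      double *col = Yc.colptr(b);
      int t = 0;
      for (int dz = 0; dz < M; ++dz)
        for (int dy = 0; dy < N2; ++dy) {
          const double *src = &vol[ox + X * ((oy + dy) + (size_t)Y * (oz + dz))];
          for (int dx = 0; dx < N1; ++dx) col[t++] = src[dx];
        }
    }
    arma::mat P = D.t() * Yc.head_cols(B);
    for (int b = 0; b < B; ++b) {
      size_t id = idx + b;
      int ox = id % nx, oy = (id / nx) % ny, oz = id / ((size_t)nx * ny);
      double normY2 = arma::dot(Yc.col(b), Yc.col(b));
      double res2;
      int nsel = omp_fast(G.memptr(), K, P.colptr(b), normY2,
                          std::min(L, K), tol, wk, res2);
      double sc = 0.0;
      std::fill(rec.begin(), rec.end(), 0.0);
      for (int t = 0; t < nsel; ++t) {
        const double wt = wk.w[t];
        const double *atom = D.colptr(wk.S[t]);
        for (int r = 0; r < n; ++r) rec[r] += wt * atom[r];
        sc += std::fabs(wt);
        if (keep_code) {
          ti.push_back(wk.S[t] + 1);
          tj.push_back((int)id + 1);
          tx.push_back(wt);
        }
      }
      scores[id] = sc;
      int t2 = 0;
      for (int dz = 0; dz < M; ++dz)
        for (int dy = 0; dy < N2; ++dy) {
          size_t base = ox + X * ((oy + dy) + (size_t)Y * (oz + dz));
          for (int dx = 0; dx < N1; ++dx) {
            sum[base + dx] += rec[t2++];
            cov[base + dx] += 1.0;
          }
        }
    }
    idx += B;
  }
  return List::create(_["sum"] = sum, _["coverage"] = cov,
                      _["score"] = scores, _["i"] = wrap(ti),
                      _["j"] = wrap(tj), _["x"] = wrap(tx));
}
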