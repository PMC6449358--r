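#include <Rcpp.h>
using namespace Rcpp;

// Volumes are 3D arrays dim (X, Y, Z), column-major, voxel (x,y,z) at
// x + X*(y + Y*z). Patch origins are 0-based corner coordinates.

// [[Rcpp::export]]
NumericMatrix cpp_extract_patches(NumericVector vol, IntegerVector dims,
                                  IntegerVector psz, IntegerMatrix origins) {
  const int X = dims[0], Y = dims[1];
  const int N1 = psz[0], N2 = psz[1], M = psz[2];
  const int n = N1 * N2 * M;
  const int m = origins.nrow();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const int ox = origins(j, 0), oy = origins(j, 1), oz = origins(j, 2);
    double *col = &out(0, j);
    int t = 0;
    for (int dz = 0; dz < M; ++dz)
      for (int dy = 0; dy < N2; ++dy) {
        const double *src = &vol[(ox) + X * ((oy + dy) + (size_t)Y * (oz + dz))];
        for (int dx = 0; dx < N1; ++dx) col[t++] = src[dx];
      }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_accumulate_patches(NumericMatrix data, IntegerMatrix origins,
                            IntegerVector psz, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int N1 = psz[0], N2 = psz[1], M = psz[2];
  const int m = origins.nrow();
  NumericVector sum((size_t)X * Y * Z);
  NumericVector cov((size_t)X * Y * Z);
  for (int j = 0; j < m; ++j) {
    const int ox = origins(j, 0), oy = origins(j, 1), oz = origins(j, 2);
    const double *col = &data(0, j);
    int t = 0;
    for (int dz = 0; dz < M; ++dz)
      for (int dy = 0; dy < N2; ++dy) {
        size_t base = ox + X * ((oy + dy) + (size_t)Y * (oz + dz));
        for (int dx = 0; dx < N1; ++dx) {
          sum[base + dx] += col[t++];
          cov[base + dx] += 1.0;
        }
      }
  }
  return List::create(_["sum"] = sum, _["coverage"] = cov);
}

// Accumulate one scalar per patch over that patch's footprint.
// [[Rcpp::export]]
List cpp_accumulate_scalar(NumericVector values, IntegerMatrix origins,
                           IntegerVector psz, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int N1 = psz[0], N2 = psz[1], M = psz[2];
  const int m = origins.nrow();
  NumericVector sum((size_t)X * Y * Z);
  NumericVector cov((size_t)X * Y * Z);
  for (int j = 0; j < m; ++j) {
    const int ox = origins(j, 0), oy = origins(j, 1), oz = origins(j, 2);
    const double v = values[j];
    for (int dz = 0; dz < M; ++dz)
      for (int dy = 0; dy < N2; ++dy) {
        size_t base = ox + X * ((oy + dy) + (size_t)Y * (oz + dz));
        for (int dx = 0; dx < N1; ++dx) {
          sum[base + dx] += v;
          cov[base + dx] += 1.0;
        }
      }
  }
  return List::create(_["sum"] = sum, _["coverage"] = cov);
}
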