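#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform with feature (nearest-site) tracking,
// Felzenszwalb & Huttenlocher lower-envelope-of-parabolas algorithm, run
// separably over the three axes with anisotropic spacing. Returns, for every
// voxel, the distance (mm) to the nearest site voxel centre and the 1-based
// linear index of that site.
static void dt1d(const std::vector<double>& f, const std::vector<int>& ff,
                 double w, std::vector<double>& d, std::vector<int>& df) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = 0;
    while (k >= 0) {
      // intersection of parabola at q with parabola at v[k]
      s = ((f[q] + w * w * q * q) - (f[v[k]] + w * w * v[k] * v[k])) /
          (2.0 * w * w * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no finite entries on this line
    for (int q = 0; q < n; ++q) { d[q] = INF; df[q] = -1; }
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (j < k && z[j + 1] < q) ++j;
    double dq = w * (q - v[j]);
    d[q] = dq * dq + f[v[j]];
    df[q] = ff[v[j]];
  }
}

// [[Rcpp::export(name = ".edt_feature")]]
List edt_feature(LogicalVector sites, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D(n);
  std::vector<int> F(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    D[i] = sites[i] ? 0.0 : INF;
    F[i] = sites[i] ? (int)i : -1;
  }
  // pass along x
  {
    std::vector<double> f(nx), d(nx); std::vector<int> ff(nx), df(nx);
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) { f[x] = D[base + x]; ff[x] = F[base + x]; }
      dt1d(f, ff, spacing[0], d, df);
      for (int x = 0; x < nx; ++x) { D[base + x] = d[x]; F[base + x] = df[x]; }
    }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny); std::vector<int> ff(ny), df(ny);
    for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        f[y] = D[i]; ff[y] = F[i];
      }
      dt1d(f, ff, spacing[1], d, df);
      for (int y = 0; y < ny; ++y) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        D[i] = d[y]; F[i] = df[y];
      }
    }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz); std::vector<int> ff(nz), df(nz);
    for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        f[z] = D[i]; ff[z] = F[i];
      }
      dt1d(f, ff, spacing[2], d, df);
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        D[i] = d[z]; F[i] = df[z];
      }
    }
  }
  NumericVector dist(n);
  IntegerVector feat(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    dist[i] = (D[i] == INF) ? NA_REAL : sqrt(D[i]);
    feat[i] = (F[i] < 0) ? NA_INTEGER : F[i] + 1;
  }
  return List::create(_["dist"] = dist, _["feature"] = feat);
}
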