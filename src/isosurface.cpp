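#include <Rcpp.h>
#include <vector>
#include <map>
#include <tuple>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian smoothing (sigma in voxels), kernel truncated at
// ceil(3*sigma) and renormalised at the grid edges.
// [[Rcpp::export(name = ".gauss3")]]
NumericVector gauss3(NumericVector vol, IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; ++i) k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const int len = nd[ax];
    const R_xlen_t st = stride[ax];
    for (R_xlen_t i = 0; i < n; ++i) {
      int pos = (ax == 0) ? (int)(i % nx)
              : (ax == 1) ? (int)((i / nx) % ny)
                          : (int)(i / ((R_xlen_t)nx * ny));
      double s = 0, w = 0;
      int lo = std::max(-r, -pos), hi = std::min(r, len - 1 - pos);
      for (int d = lo; d <= hi; ++d) { s += k[d + r] * a[i + (R_xlen_t)d * st]; w += k[d + r]; }
      b[i] = s / w;
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// Iso-surface extraction at `level` via marching tetrahedra on the Kuhn
// (Freudenthal) 6-tetrahedra decomposition of each grid cube. The uniform
// decomposition is consistent across neighbouring cubes, so the mesh is
// watertight. Vertices are returned in 0-based continuous voxel coordinates;
// the caller maps them to world mm.
static const int CNR[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                              {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
static const int TETS[6][4] = {{0,5,1,6},{0,1,2,6},{0,2,3,6},
                               {0,3,7,6},{0,7,4,6},{0,4,5,6}};

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector vol, IntegerVector dims, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::map<std::tuple<long long, long long, long long>, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;
  double P[8][3], V[8];

  auto val = [&](int x, int y, int z) -> double {
    return vol[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
  };
  auto addv = [&](const double p[3]) -> int {
    std::tuple<long long, long long, long long> key(
      (long long)llround(p[0] * 1e6), (long long)llround(p[1] * 1e6),
      (long long)llround(p[2] * 1e6));
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int id = (int)vx.size();
    vmap[key] = id;
    vx.push_back(p[0]); vy.push_back(p[1]); vz.push_back(p[2]);
    return id;
  };
  auto interp = [&](int a, int b, double out[3]) {
    double va = V[a], vb = V[b];
    double t = (vb == va) ? 0.5 : (level - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    for (int d = 0; d < 3; ++d) out[d] = P[a][d] + t * (P[b][d] - P[a][d]);
  };
  auto tri = [&](const double a[3], const double b[3], const double c[3]) {
    // skip degenerate triangles
    double u[3], w[3], cr[3];
    for (int d = 0; d < 3; ++d) { u[d] = b[d] - a[d]; w[d] = c[d] - a[d]; }
    cr[0] = u[1] * w[2] - u[2] * w[1];
    cr[1] = u[2] * w[0] - u[0] * w[2];
    cr[2] = u[0] * w[1] - u[1] * w[0];
    if (cr[0]*cr[0] + cr[1]*cr[1] + cr[2]*cr[2] < 1e-24) return;
    int ia = addv(a), ib = addv(b), ic = addv(c);
    if (ia == ib || ib == ic || ia == ic) return;
    f1.push_back(ia + 1); f2.push_back(ib + 1); f3.push_back(ic + 1);
  };

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          V[c] = val(x + CNR[c][0], y + CNR[c][1], z + CNR[c][2]);
          P[c][0] = x + CNR[c][0]; P[c][1] = y + CNR[c][1]; P[c][2] = z + CNR[c][2];
          if (V[c] > level) ++nin;
        }
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int in[4], out[4], ki = 0, ko = 0;
          for (int c = 0; c < 4; ++c) {
            int v = TETS[t][c];
            if (V[v] > level) in[ki++] = v; else out[ko++] = v;
          }
          if (ki == 0 || ki == 4) continue;
          double e0[3], e1[3], e2[3], e3[3];
          if (ki == 1) {
            interp(in[0], out[0], e0); interp(in[0], out[1], e1); interp(in[0], out[2], e2);
            tri(e0, e1, e2);
          } else if (ki == 3) {
            interp(out[0], in[0], e0); interp(out[0], in[1], e1); interp(out[0], in[2], e2);
            tri(e0, e1, e2);
          } else { // ki == 2: quad split into two triangles
            interp(in[0], out[0], e0); interp(in[0], out[1], e1);
            interp(in[1], out[1], e2); interp(in[1], out[0], e3);
            tri(e0, e1, e2); tri(e0, e2, e3);
          }
        }
      }

  const int nv = (int)vx.size(), nf = (int)f1.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) { verts(i,0) = vx[i]; verts(i,1) = vy[i]; verts(i,2) = vz[i]; }
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) { faces(i,0) = f1[i]; faces(i,1) = f2[i]; faces(i,2) = f3[i]; }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
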