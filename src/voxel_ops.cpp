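#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Connected components of a 3-D logical mask under 26-connectivity.
// Components are numbered 1..k in raster-scan discovery order, so the
// labelling is deterministic for a given mask.
// [[Rcpp::export(name = ".cc_label26")]]
IntegerVector cc_label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::stack<int> st;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    st.push((int)i);
    while (!st.empty()) {
      int c = st.top(); st.pop();
      int cx = c % nx, cy = (c / nx) % ny, cz = c / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        int z = cz + dz; if (z < 0 || z >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int y = cy + dy; if (y < 0 || y >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int x = cx + dx; if (x < 0 || x >= nx) continue;
            int j = lin(x, y, z, nx, ny);
            if (mask[j] && lab[j] == 0) { lab[j] = next; st.push(j); }
          }
        }
      }
    }
  }
  return lab;
}

// In-mask voxels with a 6-neighbour outside the mask (or outside the grid).
// [[Rcpp::export(name = ".boundary6")]]
LogicalVector boundary6(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int cx = (int)(i % nx), cy = (int)((i / nx) % ny), cz = (int)(i / ((R_xlen_t)nx * ny));
    for (int k = 0; k < 6; ++k) {
      int x = cx + off[k][0], y = cy + off[k][1], z = cz + off[k][2];
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz ||
          !mask[lin(x, y, z, nx, ny)]) { out[i] = true; break; }
    }
  }
  return out;
}

// For each candidate centre (0-based voxel indices, rows of `centers`),
// statistics of `vol` over the sphere offsets (rows of `offsets`, voxel
// steps): mean, member count (in-grid voxels only) and, if `mask` is
// non-empty, the fraction of in-grid sphere voxels lying inside `mask`.
// [[Rcpp::export(name = ".sphere_scan")]]
List sphere_scan(NumericVector vol, IntegerVector dims, IntegerMatrix centers,
                 IntegerMatrix offsets, LogicalVector mask) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nc = centers.nrow(), k = offsets.nrow();
  const bool haveVol = vol.size() > 0, haveMask = mask.size() > 0;
  NumericVector mean(nc, NA_REAL), sd(nc, NA_REAL), frac(nc, NA_REAL);
  IntegerVector cnt(nc, 0);
  for (int c = 0; c < nc; ++c) {
    double s = 0, s2 = 0; int m = 0, inmask = 0;
    for (int j = 0; j < k; ++j) {
      int x = centers(c, 0) + offsets(j, 0);
      int y = centers(c, 1) + offsets(j, 1);
      int z = centers(c, 2) + offsets(j, 2);
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      R_xlen_t i = (R_xlen_t)lin(x, y, z, nx, ny);
      ++m;
      if (haveVol) { double v = vol[i]; s += v; s2 += v * v; }
      if (haveMask && mask[i]) ++inmask;
    }
    cnt[c] = m;
    if (m > 0 && haveVol) {
      mean[c] = s / m;
      sd[c] = m > 1 ? sqrt(std::max(0.0, (s2 - s * s / m) / (m - 1))) : 0.0;
    }
    if (m > 0 && haveMask) frac[c] = (double)inmask / m;
  }
  return List::create(_["mean"] = mean, _["sd"] = sd, _["count"] = cnt,
                      _["maskfrac"] = frac);
}

// Brute-force nearest neighbours: for each query row, index (1-based) of the
// closest reference row and the distance.
// [[Rcpp::export(name = ".nn_brute")]]
List nn_brute(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < nr; ++j) {
      double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy, dz = ref(j, 2) - qz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
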