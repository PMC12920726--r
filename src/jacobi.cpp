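#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Jacobi relaxation of the discrete Laplace equation on one displacement
// component, restricted to the voxels of one body region. Dirichlet voxels
// (`fixed`) keep their initial values; free in-region voxels are repeatedly
// replaced by the mean of their in-region 6-neighbours (neighbours outside
// the region or the grid are mirrored, i.e. dropped from the average), until
// the largest per-iteration update falls below `tol` or `maxiter` sweeps.
// [[Rcpp::export(name = ".jacobi_relax")]]
List jacobi_relax(NumericVector u0, LogicalVector fixed, LogicalVector inregion,
                  IntegerVector dims, double tol, int maxiter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> u(u0.begin(), u0.end()), unew(u0.begin(), u0.end());
  // precompute free voxel list and neighbour indices
  std::vector<int> freev;
  freev.reserve(1024);
  for (R_xlen_t i = 0; i < n; ++i)
    if (inregion[i] && !fixed[i]) freev.push_back((int)i);
  const int nf = (int)freev.size();
  std::vector<int> nbr(6 * (size_t)nf);
  std::vector<unsigned char> nnb(nf);
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int q = 0; q < nf; ++q) {
    int i = freev[q];
    int cx = i % nx, cy = (i / nx) % ny, cz = i / (nx * ny);
    int m = 0;
    for (int k = 0; k < 6; ++k) {
      int x = cx + off[k][0], y = cy + off[k][1], z = cz + off[k][2];
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      int j = x + nx * (y + ny * z);
      if (!inregion[j]) continue;
      nbr[6 * (size_t)q + m] = j;
      ++m;
    }
    nnb[q] = (unsigned char)m;
  }
  double maxupd = 0.0;
  int it = 0;
  for (it = 0; it < maxiter && nf > 0; ++it) {
    maxupd = 0.0;
    for (int q = 0; q < nf; ++q) {
      int m = nnb[q];
      if (m == 0) continue;
      double s = 0;
      const int* nb = &nbr[6 * (size_t)q];
      for (int k = 0; k < m; ++k) s += u[nb[k]];
      double v = s / m;
      double d = fabs(v - u[freev[q]]);
      if (d > maxupd) maxupd = d;
      unew[freev[q]] = v;
    }
    for (int q = 0; q < nf; ++q) u[freev[q]] = unew[freev[q]];
    if (maxupd < tol) { ++it; break; }
  }
  NumericVector out(u.begin(), u.end());
  return List::create(_["u"] = out, _["iterations"] = it,
                      _["maxUpdate"] = maxupd, _["converged"] = maxupd < tol);
}
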