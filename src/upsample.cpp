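#include <Rcpp.h>
using namespace Rcpp;

// Trilinear upsampling of a coarse grid (sampled every s-th voxel of the
// fine grid, starting at voxel 0) back to the full fine grid.
// [[Rcpp::export(name = ".upsample3")]]
NumericVector upsample3(NumericVector coarse, IntegerVector cdims,
                        IntegerVector fdims, double s) {
  const int cx = cdims[0], cy = cdims[1], cz = cdims[2];
  const int nx = fdims[0], ny = fdims[1], nz = fdims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  auto cval = [&](int x, int y, int z) -> double {
    if (x > cx - 1) x = cx - 1;
    if (y > cy - 1) y = cy - 1;
    if (z > cz - 1) z = cz - 1;
    return coarse[x + (R_xlen_t)cx * (y + (R_xlen_t)cy * z)];
  };
  R_xlen_t i = 0;
  for (int z = 0; z < nz; ++z) {
    double gz = z / s;
    int z0 = (int)gz; if (z0 > cz - 1) z0 = cz - 1;
    double fz = gz - z0;
    for (int y = 0; y < ny; ++y) {
      double gy = y / s;
      int y0 = (int)gy; if (y0 > cy - 1) y0 = cy - 1;
      double fy = gy - y0;
      for (int x = 0; x < nx; ++x, ++i) {
        double gx = x / s;
        int x0 = (int)gx; if (x0 > cx - 1) x0 = cx - 1;
        double fx = gx - x0;
        double c00 = cval(x0, y0, z0) * (1 - fx) + cval(x0 + 1, y0, z0) * fx;
        double c10 = cval(x0, y0 + 1, z0) * (1 - fx) + cval(x0 + 1, y0 + 1, z0) * fx;
        double c01 = cval(x0, y0, z0 + 1) * (1 - fx) + cval(x0 + 1, y0, z0 + 1) * fx;
        double c11 = cval(x0, y0 + 1, z0 + 1) * (1 - fx) + cval(x0 + 1, y0 + 1, z0 + 1) * fx;
        out[i] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                 (c01 * (1 - fy) + c11 * fy) * fz;
      }
    }
  }
  return out;
}
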