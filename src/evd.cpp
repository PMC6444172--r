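// Extravascular distance kernel: signed distance from each voxel centre to
// the nearest vessel surface (centreline distance minus radius; negative
// values are intravascular). Exact brute force over segments; the grids and
// networks used here are small enough that no spatial index is needed.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector evd_grid_cpp(NumericMatrix A, NumericMatrix B,
                           NumericVector radius, NumericVector origin,
                           IntegerVector dims, double voxel) {
  int nseg = A.nrow();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::fill(out.begin(), out.end(), R_PosInf);

  for (int s = 0; s < nseg; ++s) {
    double ax = A(s, 0), ay = A(s, 1), az = A(s, 2);
    double dx = B(s, 0) - ax, dy = B(s, 1) - ay, dz = B(s, 2) - az;
    double L2 = dx * dx + dy * dy + dz * dz;
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k) {
      double z = origin[2] + (k + 0.5) * voxel;
      for (int j = 0; j < ny; ++j) {
        double y = origin[1] + (j + 0.5) * voxel;
        for (int i = 0; i < nx; ++i, ++idx) {
          double x = origin[0] + (i + 0.5) * voxel;
          double px = x - ax, py = y - ay, pz = z - az;
          double t = 0.0;
          if (L2 > 0) {
            t = (px * dx + py * dy + pz * dz) / L2;
            if (t < 0) t = 0; else if (t > 1) t = 1;
          }
          double qx = px - t * dx, qy = py - t * dy, qz = pz - t * dz;
          double d2 = qx * qx + qy * qy + qz * qz;
          double d = std::sqrt(d2) - radius[s];
          if (d < out[idx]) out[idx] = d;
        }
      }
    }
  }
  return out;
}
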