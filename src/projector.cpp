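#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam forward projector.
//
// The rotation axis is the vertical line through voxel coordinates (cx, cy)
// (0-based).  Detector column j sees the ray at lateral offset
// t = j - center_px (voxel units) from the axis; the ray direction at angle
// theta is (-sin, cos) and the lateral direction (cos, sin).  Line integrals
// are accumulated with unit-voxel steps and bilinear in-slice sampling; the
// caller converts to physical optical depth by multiplying with the voxel
// size in metres.
//
// vol: numeric array (nx, ny, nz); returns array (nAngles, nz, ndet).
// [[Rcpp::export]]
NumericVector forward_project_cpp(NumericVector vol, NumericVector angles_rad,
                                  double cx, double cy, double center_px,
                                  int ndet) {
  IntegerVector dims = vol.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles_rad.size();
  const double *v = REAL(vol);
  NumericVector out(static_cast<R_xlen_t>(na) * nz * ndet);
  out.attr("dim") = IntegerVector::create(na, nz, ndet);
  double *o = REAL(out);

  const double smax = 0.5 * std::sqrt(double(nx) * nx + double(ny) * ny) + 1.0;
  const int ns = int(2.0 * smax) + 1;
  std::vector<double> acc(nz);

  for (int a = 0; a < na; ++a) {
    const double ca = std::cos(angles_rad[a]);
    const double sa = std::sin(angles_rad[a]);
    for (int j = 0; j < ndet; ++j) {
      const double t = j - center_px;
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int is = 0; is < ns; ++is) {
        const double s = -smax + is;
        const double x = cx + t * ca - s * sa;
        const double y = cy + t * sa + s * ca;
        if (x < 0.0 || x > nx - 1.0 || y < 0.0 || y > ny - 1.0) continue;
        int ix = int(x), iy = int(y);
        if (ix >= nx - 1) ix = nx - 2;
        if (iy >= ny - 1) iy = ny - 2;
        const double fx = x - ix, fy = y - iy;
        const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
        const double w01 = (1 - fx) * fy, w11 = fx * fy;
        const R_xlen_t b00 = ix + R_xlen_t(nx) * iy;
        const R_xlen_t plane = R_xlen_t(nx) * ny;
        for (int z = 0; z < nz; ++z) {
          const R_xlen_t base = b00 + plane * z;
          acc[z] += w00 * v[base] + w10 * v[base + 1] +
                    w01 * v[base + nx] + w11 * v[base + nx + 1];
        }
      }
      for (int z = 0; z < nz; ++z)
        o[a + R_xlen_t(na) * (z + R_xlen_t(nz) * j)] = acc[z];
    }
  }
  return out;
}

// Back-projection of ramp-filtered projections onto a slice grid.
//
// qT: (nT x nAngles) filtered projection rows (transposed for contiguous
//    per-view access), already multiplied by their angular quadrature
//    weights (and any overlap weighting).
// tvals: lateral detector coordinates (same length units as xs/ys), assumed
//    uniformly spaced.
// xs, ys: output grid coordinates relative to the rotation axis.
// [[Rcpp::export]]
NumericMatrix backproject_cpp(NumericMatrix qT, NumericVector tvals,
                              NumericVector angles_rad,
                              NumericVector xs, NumericVector ys) {
  const int nt = qT.nrow(), na = qT.ncol();
  const int nxo = xs.size(), nyo = ys.size();
  const double t0 = tvals[0];
  const double dt = nt > 1 ? (tvals[nt - 1] - t0) / (nt - 1) : 1.0;
  NumericMatrix out(nxo, nyo);
  double *o = REAL(out);
  const double *q = REAL(qT);

  for (int a = 0; a < na; ++a) {
    const double ca = std::cos(angles_rad[a]) / dt;
    const double sa = std::sin(angles_rad[a]) / dt;
    const double off = -t0 / dt;
    const double *col = q + R_xlen_t(nt) * a;
    for (int iy = 0; iy < nyo; ++iy) {
      const double base = ys[iy] * sa + off;
      double *orow = o + R_xlen_t(nxo) * iy;
      for (int ix = 0; ix < nxo; ++ix) {
        const double u = xs[ix] * ca + base;
        if (u < 0.0 || u > nt - 1.0) continue;
        int i0 = int(u);
        if (i0 >= nt - 1) i0 = nt - 2;
        const double f = u - i0;
        orow[ix] += (1.0 - f) * col[i0] + f * col[i0 + 1];
      }
    }
  }
  return out;
}
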