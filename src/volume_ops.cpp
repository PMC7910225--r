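#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trilinear sampling of a 3-D array at fractional 0-based coordinates.
// Coordinates outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector sample_trilinear_cpp(NumericVector vol, NumericVector xs,
                                   NumericVector ys, NumericVector zs,
                                   double fill) {
  IntegerVector dims = vol.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = REAL(vol);
  const R_xlen_t n = xs.size();
  NumericVector out(n);
  const R_xlen_t plane = R_xlen_t(nx) * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = xs[i], y = ys[i], z = zs[i];
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[i] = fill;
      continue;
    }
    int ix = int(x), iy = int(y), iz = int(z);
    if (ix >= nx - 1) ix = nx - 2 < 0 ? 0 : nx - 2;
    if (iy >= ny - 1) iy = ny - 2 < 0 ? 0 : ny - 2;
    if (iz >= nz - 1) iz = nz - 2 < 0 ? 0 : nz - 2;
    const double fx = x - ix, fy = y - iy, fz = z - iz;
    const R_xlen_t b = ix + R_xlen_t(nx) * iy + plane * iz;
    const int sx = nx > 1 ? 1 : 0;
    const int sy = ny > 1 ? nx : 0;
    const R_xlen_t sz = nz > 1 ? plane : 0;
    const double c00 = v[b] * (1 - fx) + v[b + sx] * fx;
    const double c10 = v[b + sy] * (1 - fx) + v[b + sy + sx] * fx;
    const double c01 = v[b + sz] * (1 - fx) + v[b + sz + sx] * fx;
    const double c11 = v[b + sz + sy] * (1 - fx) + v[b + sz + sy + sx] * fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// 26-connected component labelling of a 3-D logical mask.
// Returns an integer array of labels (0 = background), labelled in scan
// order; component sizes are recovered with tabulate() on the R side.
// [[Rcpp::export]]
IntegerVector conncomp3d_cpp(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = R_xlen_t(nx) * ny * nz;
  IntegerVector labels(n);
  labels.attr("dim") = dims;
  const int *m = LOGICAL(mask);
  int *lab = INTEGER(labels);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!m[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int iz = int(cur / (R_xlen_t(nx) * ny));
      const int rem = int(cur - R_xlen_t(nx) * ny * iz);
      const int iy = rem / nx, ix = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) {
        const int z2 = iz + dz;
        if (z2 < 0 || z2 >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int y2 = iy + dy;
          if (y2 < 0 || y2 >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            const int x2 = ix + dx;
            if (x2 < 0 || x2 >= nx) continue;
            const R_xlen_t q = x2 + R_xlen_t(nx) * y2 + R_xlen_t(nx) * ny * z2;
            if (m[q] && !lab[q]) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  return labels;
}

// Binary dilation of a 3-D mask with a Euclidean ball of the given radius
// (voxels).  Implemented by stamping the ball at every foreground voxel.
// [[Rcpp::export]]
LogicalVector dilate3d_cpp(LogicalVector mask, double radius) {
  IntegerVector dims = mask.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = R_xlen_t(nx) * ny * nz;
  LogicalVector out(n);
  out.attr("dim") = dims;
  const int *m = LOGICAL(mask);
  int *o = LOGICAL(out);
  const int r = int(radius);
  std::vector<int> odx, ody, odz;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius) {
          odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
        }
  const size_t no = odx.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!m[i]) continue;
    const int iz = int(i / (R_xlen_t(nx) * ny));
    const int rem = int(i - R_xlen_t(nx) * ny * iz);
    const int iy = rem / nx, ix = rem % nx;
    for (size_t k = 0; k < no; ++k) {
      const int x2 = ix + odx[k], y2 = iy + ody[k], z2 = iz + odz[k];
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
        continue;
      o[x2 + R_xlen_t(nx) * y2 + R_xlen_t(nx) * ny * z2] = 1;
    }
  }
  return out;
}

static inline bool block_stats(const double *v, const IntegerVector &dims,
                               int cx, int cy, int cz, int r,
                               double &mean, double &sd,
                               std::vector<double> *store) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (cx - r < 0 || cx + r >= nx || cy - r < 0 || cy + r >= ny ||
      cz - r < 0 || cz + r >= nz)
    return false;
  double s = 0.0, s2 = 0.0;
  const int m = 2 * r + 1;
  const int nvox = m * m * m;
  if (store) store->resize(nvox);
  int k = 0;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx) {
        const double val = v[(cx + dx) + R_xlen_t(nx) * (cy + dy) +
                             R_xlen_t(nx) * ny * (cz + dz)];
        s += val; s2 += val * val;
        if (store) (*store)[k++] = val;
      }
  mean = s / nvox;
  const double var = s2 / nvox - mean * mean;
  sd = var > 0 ? std::sqrt(var) : 0.0;
  return true;
}

// Normalised cross-correlation displacement search.
//
// For each control point (row of pts, 0-based coordinates in volA) the block
// of radius blockR in volA is compared against blocks in volB displaced by
// shift0 + d for all integer d with |d|_inf <= searchR.  Returns a matrix
// with columns (dx, dy, dz, score): the best displacement (total, including
// shift0, refined to sub-voxel by separable parabolic interpolation of the
// NCC score) and its NCC.  Score is -2 when no candidate block fits inside
// both volumes.
// [[Rcpp::export]]
NumericMatrix ncc_search_cpp(NumericVector volA, NumericVector volB,
                             NumericMatrix pts, NumericVector shift0,
                             int searchR, int blockR) {
  IntegerVector dimsA = volA.attr("dim");
  IntegerVector dimsB = volB.attr("dim");
  const double *a = REAL(volA);
  const double *b = REAL(volB);
  const int npts = pts.nrow();
  NumericMatrix out(npts, 4);
  const int w = 2 * searchR + 1;
  std::vector<double> scores(size_t(w) * w * w);
  std::vector<double> blockA, blockB;

  for (int p = 0; p < npts; ++p) {
    const int cx = int(std::lround(pts(p, 0)));
    const int cy = int(std::lround(pts(p, 1)));
    const int cz = int(std::lround(pts(p, 2)));
    double mA, sA;
    out(p, 3) = -2.0;
    if (!block_stats(a, dimsA, cx, cy, cz, blockR, mA, sA, &blockA) || sA <= 0)
      continue;
    std::fill(scores.begin(), scores.end(), -2.0);
    double best = -2.0;
    int bi = -1;
    for (int dz = -searchR; dz <= searchR; ++dz)
      for (int dy = -searchR; dy <= searchR; ++dy)
        for (int dx = -searchR; dx <= searchR; ++dx) {
          const int bx = cx + int(std::lround(shift0[0])) + dx;
          const int by = cy + int(std::lround(shift0[1])) + dy;
          const int bz = cz + int(std::lround(shift0[2])) + dz;
          double mB, sB;
          if (!block_stats(b, dimsB, bx, by, bz, blockR, mB, sB, &blockB) ||
              sB <= 0)
            continue;
          double cc = 0.0;
          const size_t nv = blockA.size();
          for (size_t k = 0; k < nv; ++k)
            cc += (blockA[k] - mA) * (blockB[k] - mB);
          cc /= nv * sA * sB;
          const int idx = (dx + searchR) + w * ((dy + searchR) +
                          w * (dz + searchR));
          scores[idx] = cc;
          if (cc > best) { best = cc; bi = idx; }
        }
    if (bi < 0) continue;
    int bx = bi % w, by = (bi / w) % w, bz = bi / (w * w);
    double d[3] = { double(bx - searchR), double(by - searchR),
                    double(bz - searchR) };
    // separable parabolic sub-voxel refinement
    const int strides[3] = { 1, w, w * w };
    const int pos[3] = { bx, by, bz };
    for (int ax = 0; ax < 3; ++ax) {
      if (pos[ax] <= 0 || pos[ax] >= w - 1) continue;
      const double sm = scores[bi - strides[ax]];
      const double sp = scores[bi + strides[ax]];
      if (sm <= -2.0 || sp <= -2.0) continue;
      const double denom = sm - 2.0 * best + sp;
      if (denom < 0) d[ax] += 0.5 * (sm - sp) / denom;
    }
    out(p, 0) = shift0[0] + d[0];
    out(p, 1) = shift0[1] + d[1];
    out(p, 2) = shift0[2] + d[2];
    out(p, 3) = best;
  }
  return out;
}

// Stamp a set of balls (centres 0-based, per-ball radius) into a fresh mask.
// [[Rcpp::export]]
LogicalVector carve_balls_cpp(IntegerVector dims, NumericMatrix centres,
                              NumericVector radii) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(R_xlen_t(nx) * ny * nz);
  out.attr("dim") = dims;
  int *o = LOGICAL(out);
  for (int p = 0; p < centres.nrow(); ++p) {
    const double cx = centres(p, 0), cy = centres(p, 1), cz = centres(p, 2);
    const double r = radii[p], r2 = r * r;
    const int x0 = std::max(0, int(std::floor(cx - r)));
    const int x1 = std::min(nx - 1, int(std::ceil(cx + r)));
    const int y0 = std::max(0, int(std::floor(cy - r)));
    const int y1 = std::min(ny - 1, int(std::ceil(cy + r)));
    const int z0 = std::max(0, int(std::floor(cz - r)));
    const int z1 = std::min(nz - 1, int(std::ceil(cz + r)));
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y) {
        const double dyz = (y - cy) * (y - cy) + (z - cz) * (z - cz);
        if (dyz > r2) continue;
        const double dx = std::sqrt(r2 - dyz);
        const int xa = std::max(x0, int(std::ceil(cx - dx)));
        const int xb = std::min(x1, int(std::floor(cx + dx)));
        R_xlen_t base = R_xlen_t(nx) * y + R_xlen_t(nx) * ny * z;
        for (int x = xa; x <= xb; ++x) o[base + x] = 1;
      }
  }
  return out;
}
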