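// Low-level voxel kernels for the registration engine and phantom plumbing.
// All grids are column-major (R array layout): index = i + nx*(j + ny*k).
// Physical convention: voxel i centre at origin + i*spacing (0-based, mm).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sample with nearest-edge clamping; (x,y,z) in 0-based voxel units.
static inline double sample_tri(const double* v, int nx, int ny, int nz,
                                double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2;
  if (y0 > ny - 2) y0 = ny - 2;
  if (z0 > nz - 2) z0 = nz - 2;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double* p = v + x0 * sx + (R_xlen_t)y0 * sy + (R_xlen_t)z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Backward warp: out(x) = img(x + U(x)), U in mm on the same grid.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector img, IntegerVector dim,
                       NumericVector ux, NumericVector uy, NumericVector uz,
                       NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(img.size());
  const double* v = img.begin();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        out[idx] = sample_tri(v, nx, ny, nz,
                              i + ux[idx] / sx,
                              j + uy[idx] / sy,
                              k + uz[idx] / sz);
      }
  return out;
}

// Sample img at arbitrary 0-based voxel coordinates (used by grid resampling
// and landmark transfer).
// [[Rcpp::export]]
NumericVector cpp_sample(NumericVector img, IntegerVector dim,
                         NumericVector x, NumericVector y, NumericVector z) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = x.size();
  NumericVector out(n);
  const double* v = img.begin();
  for (R_xlen_t t = 0; t < n; ++t)
    out[t] = sample_tri(v, nx, ny, nz, x[t], y[t], z[t]);
  return out;
}

// Demons force. Gradients by central differences in voxel units;
// displacement returned in mm.
// Passive (Thirion):
//   u = (I_s - I_m) * grad(I_s) / (|grad(I_s)|^2 + (I_s - I_m)^2 + eps)
// Symmetric: grad(I_s) replaced by the mean of the static and
// warped-moving gradients, which keeps the force alive where one of the
// two images is locally flat (e.g. a sharp edge against a blurred one).
// [[Rcpp::export]]
List cpp_demons_force(NumericVector stat, NumericVector mov, IntegerVector dim,
                      LogicalVector roi, NumericVector spacing, double eps,
                      bool symmetric) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = stat.size();
  NumericVector ux(n), uy(n), uz(n);
  const double* s = stat.begin();
  const double* m = mov.begin();
  const R_xlen_t stx = 1, sty = nx, stz = (R_xlen_t)nx * ny;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        if (!roi[idx]) continue;
        const R_xlen_t ox = (i < nx - 1 ? stx : 0), oxm = (i > 0 ? stx : 0);
        const R_xlen_t oy = (j < ny - 1 ? sty : 0), oym = (j > 0 ? sty : 0);
        const R_xlen_t oz = (k < nz - 1 ? stz : 0), ozm = (k > 0 ? stz : 0);
        double gx = 0.5 * (s[idx + ox] - s[idx - oxm]);
        double gy = 0.5 * (s[idx + oy] - s[idx - oym]);
        double gz = 0.5 * (s[idx + oz] - s[idx - ozm]);
        if (symmetric) {
          gx = 0.5 * (gx + 0.5 * (m[idx + ox] - m[idx - oxm]));
          gy = 0.5 * (gy + 0.5 * (m[idx + oy] - m[idx - oym]));
          gz = 0.5 * (gz + 0.5 * (m[idx + oz] - m[idx - ozm]));
        }
        double d = s[idx] - m[idx];
        double denom = gx * gx + gy * gy + gz * gz + d * d + eps;
        if (denom <= eps) continue;
        double f = d / denom;
        ux[idx] = f * gx * spacing[0];
        uy[idx] = f * gy * spacing[1];
        uz[idx] = f * gz * spacing[2];
      }
  return List::create(_["ux"] = ux, _["uy"] = uy, _["uz"] = uz);
}

// Separable 1-D convolution along one axis (0,1,2). Two boundary modes:
// renorm = true  -> kernel renormalised over in-bounds taps (smoothing);
// renorm = false -> zero padding (mass-conserving for interior support).
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nx, int ny, int nz, const NumericVector& ker,
                      int axis, bool renorm) {
  int r = (ker.size() - 1) / 2;
  int dims[3] = {nx, ny, nz};
  R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int nax = dims[axis];
  R_xlen_t sax = strides[axis];
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int pos = (axis == 0) ? i : (axis == 1 ? j : k);
        double acc = 0.0, wsum = 0.0;
        for (int t = -r; t <= r; ++t) {
          int p = pos + t;
          if (p < 0 || p >= nax) continue;
          double w = ker[t + r];
          acc += w * in[idx + (R_xlen_t)t * sax];
          wsum += w;
        }
        out[idx] = renorm ? (wsum > 0 ? acc / wsum : 0.0) : acc;
      }
}

// [[Rcpp::export]]
NumericVector cpp_convolve_sep(NumericVector img, IntegerVector dim,
                               NumericVector kernel, bool renorm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = img.size();
  std::vector<double> a(img.begin(), img.end()), b(n);
  conv_axis(a, b, nx, ny, nz, kernel, 0, renorm);
  conv_axis(b, a, nx, ny, nz, kernel, 1, renorm);
  conv_axis(a, b, nx, ny, nz, kernel, 2, renorm);
  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  return out;
}

// 6-connected component labelling of a binary mask (BFS). Labels 1..K by
// discovery order; 0 for background.
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = mask.size();
  IntegerVector lab(n);
  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  int next = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / sz;
      const R_xlen_t nb[6] = {cur - sx, cur + sx, cur - sy,
                              cur + sy, cur - sz, cur + sz};
      const bool ok[6] = {i > 0, i < nx - 1, j > 0, j < ny - 1,
                          k > 0, k < nz - 1};
      for (int t = 0; t < 6; ++t) {
        if (!ok[t]) continue;
        R_xlen_t q = nb[t];
        if (mask[q] && !lab[q]) {
          lab[q] = next;
          queue.push_back(q);
        }
      }
    }
  }
  return lab;
}
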