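#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---- uniform B-spline kernel -------------------------------------------
// centred cardinal B-spline beta_n evaluated by the Cox-de Boor recursion;
// n <= 4 so the recursion depth is trivial.
static double beta_n(int n, double t) {
  if (n == 0) {
    double a = std::fabs(t);
    if (a < 0.5) return 1.0;
    if (a == 0.5) return 0.5;
    return 0.0;
  }
  double h = (n + 1.0) / 2.0;
  if (std::fabs(t) >= h) return 0.0;
  return ((t + h) * beta_n(n - 1, t + 0.5) + (h - t) * beta_n(n - 1, t - 0.5)) / n;
}

// mirror index into [0, n-1] (whole-sample symmetric boundary)
static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i = i % period;
  if (i < 0) i += period;
  if (i >= n) i = period - i;
  return i;
}

// ---- IIR prefilter (Unser) for interpolating B-splines ------------------
static void filter_line(std::vector<double> &c, const double *poles, int npoles) {
  int n = (int)c.size();
  if (n == 1) return;
  double lambda = 1.0;
  for (int k = 0; k < npoles; ++k)
    lambda *= (1.0 - poles[k]) * (1.0 - 1.0 / poles[k]);
  for (int i = 0; i < n; ++i) c[i] *= lambda;
  for (int k = 0; k < npoles; ++k) {
    double z = poles[k];
    // causal init (mirror boundary)
    double zn = z, sum = c[0];
    int horizon = n;
    double tol = 1e-14;
    int m = (int)std::ceil(std::log(tol) / std::log(std::fabs(z)));
    if (m < horizon) horizon = m;
    for (int i = 1; i < horizon; ++i) { sum += zn * c[i]; zn *= z; }
    c[0] = sum;
    for (int i = 1; i < n; ++i) c[i] += z * c[i - 1];
    // anticausal init
    c[n - 1] = (z / (z * z - 1.0)) * (z * c[n - 2] + c[n - 1]);
    for (int i = n - 2; i >= 0; --i) c[i] = z * (c[i + 1] - c[i]);
  }
}

// [[Rcpp::export]]
NumericVector cpp_prefilter(NumericVector vol, IntegerVector dim, int order) {
  if (order < 2) return clone(vol);
  double poles3[1] = { std::sqrt(3.0) - 2.0 };
  double poles2[1] = { std::sqrt(8.0) - 3.0 };
  double poles4[2] = { std::sqrt(664.0 - std::sqrt(438976.0)) + std::sqrt(304.0) - 19.0,
                       std::sqrt(664.0 + std::sqrt(438976.0)) - std::sqrt(304.0) - 19.0 };
  const double *poles; int npoles;
  if (order == 2)      { poles = poles2; npoles = 1; }
  else if (order == 3) { poles = poles3; npoles = 1; }
  else if (order == 4) { poles = poles4; npoles = 2; }
  else stop("unsupported spline order");

  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  std::vector<double> line;
  // x lines
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) line[x] = out[base + x];
      filter_line(line, poles, npoles);
      for (int x = 0; x < nx; ++x) out[base + x] = line[x];
    }
  // y lines
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) line[y] = out[base + (R_xlen_t)y * nx];
      filter_line(line, poles, npoles);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = line[y];
    }
  // z lines
  line.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) line[z] = out[base + (R_xlen_t)z * nx * ny];
      filter_line(line, poles, npoles);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = line[z];
    }
  return out;
}

// sample prefiltered coefficients at one continuous (0-based) index point
static double sample_point(const double *c, int nx, int ny, int nz,
                           double x, double y, double z, int order) {
  // outside the voxel-centre hull -> background 0
  const double eps = 1e-9;
  if (x < -eps || y < -eps || z < -eps ||
      x > nx - 1 + eps || y > ny - 1 + eps || z > nz - 1 + eps)
    return 0.0;
  if (order == 0) {
    int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5), k = (int)std::floor(z + 0.5);
    i = mirror_idx(i, nx); j = mirror_idx(j, ny); k = mirror_idx(k, nz);
    return c[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i];
  }
  if (order == 1) {
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double v = 0.0;
    for (int dk = 0; dk <= 1; ++dk) {
      double wz = dk ? fz : 1.0 - fz;
      if (wz == 0.0) continue;
      int k = mirror_idx(k0 + dk, nz);
      for (int dj = 0; dj <= 1; ++dj) {
        double wy = dj ? fy : 1.0 - fy;
        if (wy == 0.0) continue;
        int j = mirror_idx(j0 + dj, ny);
        for (int di = 0; di <= 1; ++di) {
          double wx = di ? fx : 1.0 - fx;
          if (wx == 0.0) continue;
          int i = mirror_idx(i0 + di, nx);
          v += wx * wy * wz * c[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i];
        }
      }
    }
    return v;
  }
  // order 2..4
  int ns = order + 1;
  int i0, j0, k0;
  if (order % 2 == 1) {
    i0 = (int)std::floor(x) - (order - 1) / 2;
    j0 = (int)std::floor(y) - (order - 1) / 2;
    k0 = (int)std::floor(z) - (order - 1) / 2;
  } else {
    i0 = (int)std::floor(x + 0.5) - order / 2;
    j0 = (int)std::floor(y + 0.5) - order / 2;
    k0 = (int)std::floor(z + 0.5) - order / 2;
  }
  double wx[5], wy[5], wz[5];
  for (int s = 0; s < ns; ++s) {
    wx[s] = beta_n(order, x - (i0 + s));
    wy[s] = beta_n(order, y - (j0 + s));
    wz[s] = beta_n(order, z - (k0 + s));
  }
  double v = 0.0;
  for (int dk = 0; dk < ns; ++dk) {
    if (wz[dk] == 0.0) continue;
    int k = mirror_idx(k0 + dk, nz);
    for (int dj = 0; dj < ns; ++dj) {
      if (wy[dj] == 0.0) continue;
      int j = mirror_idx(j0 + dj, ny);
      double acc = 0.0;
      for (int di = 0; di < ns; ++di) {
        if (wx[di] == 0.0) continue;
        int i = mirror_idx(i0 + di, nx);
        acc += wx[di] * c[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i];
      }
      v += wz[dk] * wy[dj] * acc;
    }
  }
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_sample(NumericVector coeff, IntegerVector dim,
                         NumericMatrix pts, int order) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *c = coeff.begin();
  for (R_xlen_t p = 0; p < n; ++p)
    out[p] = sample_point(c, nx, ny, nz, pts(p, 0), pts(p, 1), pts(p, 2), order);
  return out;
}

// fast path: sample through a 3x4 index->index affine map over a full grid
// [[Rcpp::export]]
NumericVector cpp_sample_affine(NumericVector coeff, IntegerVector dim,
                                NumericMatrix M, IntegerVector outdim, int order) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *c = coeff.begin();
  R_xlen_t p = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j) {
      double bx = M(0, 1) * j + M(0, 2) * k + M(0, 3);
      double by = M(1, 1) * j + M(1, 2) * k + M(1, 3);
      double bz = M(2, 1) * j + M(2, 2) * k + M(2, 3);
      for (int i = 0; i < ox; ++i, ++p) {
        out[p] = sample_point(c, nx, ny, nz,
                              M(0, 0) * i + bx, M(1, 0) * i + by, M(2, 0) * i + bz,
                              order);
      }
    }
  return out;
}

// ---- separable Gaussian smoothing (reflect boundary) ---------------------
static void smooth_axis(std::vector<double> &buf, const double *src, double *dst,
                        int n, R_xlen_t stride, R_xlen_t nline, R_xlen_t linestride,
                        const std::vector<double> &kern) {
  int r = ((int)kern.size() - 1) / 2;
  for (R_xlen_t l = 0; l < nline; ++l) {
    const double *s = src + l * linestride;
    double *d = dst + l * linestride;
    for (int i = 0; i < n; ++i) buf[i] = s[(R_xlen_t)i * stride];
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int k = -r; k <= r; ++k)
        acc += kern[k + r] * buf[mirror_idx(i + k, n)];
      d[(R_xlen_t)i * stride] = acc;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dim,
                               NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * r + 1);
    double tot = 0.0;
    for (int k = -r; k <= r; ++k) { kern[k + r] = std::exp(-0.5 * k * k / (s * s)); tot += kern[k + r]; }
    for (auto &w : kern) w /= tot;
    std::vector<double> buf(std::max(nx, std::max(ny, nz)));
    NumericVector tmp = clone(out);
    if (ax == 0) {
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
          R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
          smooth_axis(buf, tmp.begin() + base, out.begin() + base, nx, 1, 1, 0, kern);
        }
    } else if (ax == 1) {
      for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t base = (R_xlen_t)z * nx * ny + x;
          smooth_axis(buf, tmp.begin() + base, out.begin() + base, ny, nx, 1, 0, kern);
        }
    } else {
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t base = (R_xlen_t)y * nx + x;
          smooth_axis(buf, tmp.begin() + base, out.begin() + base, nz, (R_xlen_t)nx * ny, 1, 0, kern);
        }
    }
  }
  return out;
}
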