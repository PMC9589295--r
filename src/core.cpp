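// Compiled kernels for sctqa: resampling/warping, vector-field composition,
// separable Gaussian smoothing, anisotropic Euclidean distance transform,
// masked Laplace solver, multi-resolution diffeomorphic Demons, coarse
// free-form prealignment, ray-cast dose deposition and 3D gamma search.
//
// All volumes are column-major (x fastest), voxel centers at index*spacing
// (mm, relative to the first voxel center); displacement fields are in mm.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static inline long long IDX(int i, int j, int k, int nx, int ny) {
  return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// trilinear sample at voxel coords (x,y,z); edge-clamped
static double sample_lin_clamp(const double* v, int nx, int ny, int nz,
                               double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  int z0 = (int)std::floor(z); if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  if (nx == 1) { x0 = 0; x = 0; }
  if (ny == 1) { y0 = 0; y = 0; }
  if (nz == 1) { z0 = 0; z = 0; }
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = nx == 1 ? 0 : x0 + 1, y1 = ny == 1 ? 0 : y0 + 1, z1 = nz == 1 ? 0 : z0 + 1;
  double c000 = v[IDX(x0,y0,z0,nx,ny)], c100 = v[IDX(x1,y0,z0,nx,ny)];
  double c010 = v[IDX(x0,y1,z0,nx,ny)], c110 = v[IDX(x1,y1,z0,nx,ny)];
  double c001 = v[IDX(x0,y0,z1,nx,ny)], c101 = v[IDX(x1,y0,z1,nx,ny)];
  double c011 = v[IDX(x0,y1,z1,nx,ny)], c111 = v[IDX(x1,y1,z1,nx,ny)];
  double c00 = c000 + (c100 - c000) * fx;
  double c10 = c010 + (c110 - c010) * fx;
  double c01 = c001 + (c101 - c001) * fx;
  double c11 = c011 + (c111 - c011) * fx;
  double c0 = c00 + (c10 - c00) * fy;
  double c1 = c01 + (c11 - c01) * fy;
  return c0 + (c1 - c0) * fz;
}

// trilinear with background outside the grid
static double sample_lin_bg(const double* v, int nx, int ny, int nz,
                            double x, double y, double z, double bg) {
  if (x < 0 || x > nx - 1.0 || y < 0 || y > ny - 1.0 || z < 0 || z > nz - 1.0)
    return bg;
  return sample_lin_clamp(v, nx, ny, nz, x, y, z);
}

static double sample_nn_bg(const double* v, int nx, int ny, int nz,
                           double x, double y, double z, double bg) {
  int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
  if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return bg;
  return v[IDX(i,j,k,nx,ny)];
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim_in,
                           NumericVector sp_in, NumericVector or_in,
                           IntegerVector dim_out, NumericVector sp_out,
                           NumericVector or_out, int nearest, double background) {
  int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  int mx = dim_out[0], my = dim_out[1], mz = dim_out[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  const double* v = vol.begin();
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double X = (or_out[0] + i * sp_out[0] - or_in[0]) / sp_in[0];
        double Y = (or_out[1] + j * sp_out[1] - or_in[1]) / sp_in[1];
        double Z = (or_out[2] + k * sp_out[2] - or_in[2]) / sp_in[2];
        out[IDX(i,j,k,mx,my)] = nearest
          ? sample_nn_bg(v, nx, ny, nz, X, Y, Z, background)
          : sample_lin_bg(v, nx, ny, nz, X, Y, Z, background);
      }
  return out;
}

// backward warp: out(x) = vol(x + f(x)/spacing)
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, IntegerVector dim, NumericVector spacing,
                       NumericVector fx, NumericVector fy, NumericVector fz,
                       int nearest, double background, int clamp_edges) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double* v = vol.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long long id = IDX(i,j,k,nx,ny);
        double X = i + fx[id] / spacing[0];
        double Y = j + fy[id] / spacing[1];
        double Z = k + fz[id] / spacing[2];
        if (clamp_edges)
          out[id] = sample_lin_clamp(v, nx, ny, nz, X, Y, Z);
        else if (nearest)
          out[id] = sample_nn_bg(v, nx, ny, nz, X, Y, Z, background);
        else
          out[id] = sample_lin_bg(v, nx, ny, nz, X, Y, Z, background);
      }
  return out;
}

// compose(f_outer, f_inner)(x) = f_inner(x) + f_outer(x + f_inner(x))
// [[Rcpp::export]]
List cpp_compose(NumericVector fox, NumericVector foy, NumericVector foz,
                 NumericVector fix_, NumericVector fiy, NumericVector fiz,
                 IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector rx(n), ry(n), rz(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long long id = IDX(i,j,k,nx,ny);
        double X = i + fix_[id] / spacing[0];
        double Y = j + fiy[id] / spacing[1];
        double Z = k + fiz[id] / spacing[2];
        rx[id] = fix_[id] + sample_lin_clamp(fox.begin(), nx, ny, nz, X, Y, Z);
        ry[id] = fiy[id] + sample_lin_clamp(foy.begin(), nx, ny, nz, X, Y, Z);
        rz[id] = fiz[id] + sample_lin_clamp(foz.begin(), nx, ny, nz, X, Y, Z);
      }
  return List::create(_["x"] = rx, _["y"] = ry, _["z"] = rz);
}

static void gauss_1d(std::vector<double>& buf, std::vector<double>& tmp,
                     const std::vector<double>& ker) {
  int n = (int)buf.size();
  int r = (int)ker.size() / 2;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = -r; t <= r; ++t) {
      int p = i + t;
      if (p < 0) p = -p;                 // reflect
      if (p > n - 1) p = 2 * (n - 1) - p;
      if (p < 0) p = 0;
      s += buf[p] * ker[t + r];
    }
    tmp[i] = s;
  }
  buf = tmp;
}

static std::vector<double> make_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (auto& v : k) v /= s;
  return k;
}

static void gauss_3d_inplace(std::vector<double>& v, int nx, int ny, int nz,
                             double sx, double sy, double sz) {
  if (sx > 0 && nx > 1) {
    auto ker = make_kernel(sx);
    std::vector<double> line(nx), tmp(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) line[i] = v[IDX(i,j,k,nx,ny)];
        gauss_1d(line, tmp, ker);
        for (int i = 0; i < nx; ++i) v[IDX(i,j,k,nx,ny)] = line[i];
      }
  }
  if (sy > 0 && ny > 1) {
    auto ker = make_kernel(sy);
    std::vector<double> line(ny), tmp(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) line[j] = v[IDX(i,j,k,nx,ny)];
        gauss_1d(line, tmp, ker);
        for (int j = 0; j < ny; ++j) v[IDX(i,j,k,nx,ny)] = line[j];
      }
  }
  if (sz > 0 && nz > 1) {
    auto ker = make_kernel(sz);
    std::vector<double> line(nz), tmp(nz);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) line[k] = v[IDX(i,j,k,nx,ny)];
        gauss_1d(line, tmp, ker);
        for (int k = 0; k < nz; ++k) v[IDX(i,j,k,nx,ny)] = line[k];
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss(NumericVector vol, IntegerVector dim, NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  gauss_3d_inplace(v, nx, ny, nz, sigma_vox[0], sigma_vox[1], sigma_vox[2]);
  return NumericVector(v.begin(), v.end());
}

// Felzenszwalb-Huttenlocher 1D squared distance transform with sample spacing s
static void dt_1d(std::vector<double>& f, double s) {
  int n = (int)f.size();
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double sq = (double)q * s, s2 = sq * sq;
    while (true) {
      double sv = (double)v[k] * s;
      double denom = 2.0 * sq - 2.0 * sv;
      double inter = (f[q] + s2 - f[v[k]] - sv * sv) / denom;
      if (inter <= z[k]) { --k; continue; }
      ++k; v[k] = q; z[k] = inter; z[k + 1] = std::numeric_limits<double>::infinity();
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (z[k + 1] < sq) ++k;
    double dv = sq - (double)v[k] * s;
    d[q] = dv * dv + f[v[k]];
  }
  f = d;
}

// squared Euclidean distance (mm^2) to the nearest true voxel center
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> v(n);
  for (R_xlen_t i = 0; i < n; ++i) v[i] = mask[i] ? 0.0 : INF;
  std::vector<double> line;
  line.resize(std::max(nx, std::max(ny, nz)));
  // x pass
  { std::vector<double> f(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) f[i] = v[IDX(i,j,k,nx,ny)];
        dt_1d(f, spacing[0]);
        for (int i = 0; i < nx; ++i) v[IDX(i,j,k,nx,ny)] = f[i];
      } }
  { std::vector<double> f(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) f[j] = v[IDX(i,j,k,nx,ny)];
        dt_1d(f, spacing[1]);
        for (int j = 0; j < ny; ++j) v[IDX(i,j,k,nx,ny)] = f[j];
      } }
  { std::vector<double> f(nz);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) f[k] = v[IDX(i,j,k,nx,ny)];
        dt_1d(f, spacing[2]);
        for (int k = 0; k < nz; ++k) v[IDX(i,j,k,nx,ny)] = f[k];
      } }
  return NumericVector(v.begin(), v.end());
}

// Gauss-Seidel Laplace solve. lab: 0 outside, 1 interior, 2 boundary (=1), 3 sink (=0).
// [[Rcpp::export]]
NumericVector cpp_laplace(IntegerVector lab, IntegerVector dim, NumericVector spacing,
                          double tol, int max_iter) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> u(n, 0.0);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (lab[i] == 2) u[i] = 1.0;
    else if (lab[i] == 1) u[i] = 0.5;
  }
  double wx = 1.0 / (spacing[0] * spacing[0]);
  double wy = 1.0 / (spacing[1] * spacing[1]);
  double wz = 1.0 / (spacing[2] * spacing[2]);
  for (int it = 0; it < max_iter; ++it) {
    double maxd = 0.0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long long id = IDX(i,j,k,nx,ny);
          if (lab[id] != 1) continue;
          double num = 0.0, den = 0.0;
          // neighbors outside the mask are treated as boundary (value 1)
          double vxm = (i > 0      && lab[IDX(i-1,j,k,nx,ny)] != 0) ? u[IDX(i-1,j,k,nx,ny)] : 1.0;
          double vxp = (i < nx - 1 && lab[IDX(i+1,j,k,nx,ny)] != 0) ? u[IDX(i+1,j,k,nx,ny)] : 1.0;
          double vym = (j > 0      && lab[IDX(i,j-1,k,nx,ny)] != 0) ? u[IDX(i,j-1,k,nx,ny)] : 1.0;
          double vyp = (j < ny - 1 && lab[IDX(i,j+1,k,nx,ny)] != 0) ? u[IDX(i,j+1,k,nx,ny)] : 1.0;
          double vzm = (k > 0      && lab[IDX(i,j,k-1,nx,ny)] != 0) ? u[IDX(i,j,k-1,nx,ny)] : 1.0;
          double vzp = (k < nz - 1 && lab[IDX(i,j,k+1,nx,ny)] != 0) ? u[IDX(i,j,k+1,nx,ny)] : 1.0;
          num = wx * (vxm + vxp) + wy * (vym + vyp) + wz * (vzm + vzp);
          den = 2.0 * (wx + wy + wz);
          double nv = num / den;
          double d = std::fabs(nv - u[id]);
          if (d > maxd) maxd = d;
          u[id] = nv;
        }
    if (maxd < tol) break;
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (lab[i] == 0) ? NA_REAL : u[i];
  return out;
}

// trilinear resize (voxel-center aligned via physical extent mapping)
static std::vector<double> resize_vol(const std::vector<double>& v,
                                      int nx, int ny, int nz,
                                      int mx, int my, int mz) {
  std::vector<double> out((size_t)mx * my * mz);
  double rx = (double)nx / mx, ry = (double)ny / my, rz = (double)nz / mz;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double X = (i + 0.5) * rx - 0.5;
        double Y = (j + 0.5) * ry - 0.5;
        double Z = (k + 0.5) * rz - 0.5;
        out[IDX(i,j,k,mx,my)] = sample_lin_clamp(v.data(), nx, ny, nz, X, Y, Z);
      }
  return out;
}

// one symmetric-forces compositive Demons iteration set at a fixed level
static void demons_iterate(const std::vector<double>& fixedv,
                           const std::vector<double>& movingv,
                           std::vector<double>& fx, std::vector<double>& fy,
                           std::vector<double>& fz,
                           int nx, int ny, int nz,
                           double sx, double sy, double sz,
                           int iters, double sigma_vox, double total_sigma_vox,
                           double max_step_mm) {
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> warped(n), ux(n), uy(n), uz(n);
  std::vector<double> nfx(n), nfy(n), nfz(n);
  double alpha2 = 1.0 / (max_step_mm * max_step_mm);
  for (int it = 0; it < iters; ++it) {
    // warp moving by current field
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long long id = IDX(i,j,k,nx,ny);
          warped[id] = sample_lin_clamp(movingv.data(), nx, ny, nz,
                                        i + fx[id] / sx, j + fy[id] / sy, k + fz[id] / sz);
        }
    // symmetric demons force
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long long id = IDX(i,j,k,nx,ny);
          int im = i > 0 ? i - 1 : i, ip = i < nx - 1 ? i + 1 : i;
          int jm = j > 0 ? j - 1 : j, jp = j < ny - 1 ? j + 1 : j;
          int km = k > 0 ? k - 1 : k, kp = k < nz - 1 ? k + 1 : k;
          double gxf = (fixedv[IDX(ip,j,k,nx,ny)] - fixedv[IDX(im,j,k,nx,ny)]) / ((ip - im) * sx);
          double gyf = (fixedv[IDX(i,jp,k,nx,ny)] - fixedv[IDX(i,jm,k,nx,ny)]) / ((jp - jm) * sy);
          double gzf = (fixedv[IDX(i,j,kp,nx,ny)] - fixedv[IDX(i,j,km,nx,ny)]) / ((kp - km) * sz);
          double gxw = (warped[IDX(ip,j,k,nx,ny)] - warped[IDX(im,j,k,nx,ny)]) / ((ip - im) * sx);
          double gyw = (warped[IDX(i,jp,k,nx,ny)] - warped[IDX(i,jm,k,nx,ny)]) / ((jp - jm) * sy);
          double gzw = (warped[IDX(i,j,kp,nx,ny)] - warped[IDX(i,j,km,nx,ny)]) / ((kp - km) * sz);
          double gx = 0.5 * (gxf + gxw), gy = 0.5 * (gyf + gyw), gz = 0.5 * (gzf + gzw);
          double diff = warped[id] - fixedv[id];
          double g2 = gx * gx + gy * gy + gz * gz;
          double den = g2 + alpha2 * diff * diff;
          if (den < 1e-12) { ux[id] = uy[id] = uz[id] = 0.0; continue; }
          double f = -diff / den;
          double vx = f * gx, vy = f * gy, vz = f * gz;
          double norm = std::sqrt(vx * vx + vy * vy + vz * vz);
          if (norm > max_step_mm) {
            double sc = max_step_mm / norm;
            vx *= sc; vy *= sc; vz *= sc;
          }
          ux[id] = vx; uy[id] = vy; uz[id] = vz;
        }
    gauss_3d_inplace(ux, nx, ny, nz, sigma_vox, sigma_vox, sigma_vox);
    gauss_3d_inplace(uy, nx, ny, nz, sigma_vox, sigma_vox, sigma_vox);
    gauss_3d_inplace(uz, nx, ny, nz, sigma_vox, sigma_vox, sigma_vox);
    // compositive update: f <- u + f(x + u)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long long id = IDX(i,j,k,nx,ny);
          double X = i + ux[id] / sx, Y = j + uy[id] / sy, Z = k + uz[id] / sz;
          nfx[id] = ux[id] + sample_lin_clamp(fx.data(), nx, ny, nz, X, Y, Z);
          nfy[id] = uy[id] + sample_lin_clamp(fy.data(), nx, ny, nz, X, Y, Z);
          nfz[id] = uz[id] + sample_lin_clamp(fz.data(), nx, ny, nz, X, Y, Z);
        }
    fx = nfx; fy = nfy; fz = nfz;
    // diffusion-like regularization of the deformation field itself
    if (total_sigma_vox > 0) {
      gauss_3d_inplace(fx, nx, ny, nz, total_sigma_vox, total_sigma_vox, total_sigma_vox);
      gauss_3d_inplace(fy, nx, ny, nz, total_sigma_vox, total_sigma_vox, total_sigma_vox);
      gauss_3d_inplace(fz, nx, ny, nz, total_sigma_vox, total_sigma_vox, total_sigma_vox);
    }
  }
}

// multi-resolution diffeomorphic Demons; factors coarse-to-fine, iters aligned
// [[Rcpp::export]]
List cpp_demons(NumericVector fixed, NumericVector moving, IntegerVector dim,
                NumericVector spacing, IntegerVector iters, IntegerVector factors,
                double sigma_vox, NumericVector total_sigma_vox, NumericVector fx0,
                NumericVector fy0, NumericVector fz0, double max_step_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> F(fixed.begin(), fixed.end());
  std::vector<double> M(moving.begin(), moving.end());
  std::vector<double> fx(fx0.begin(), fx0.end());
  std::vector<double> fy(fy0.begin(), fy0.end());
  std::vector<double> fz(fz0.begin(), fz0.end());
  int cur_nx = nx, cur_ny = ny, cur_nz = nz; // resolution the field currently lives on
  bool field_full = true;
  for (int lev = 0; lev < iters.size(); ++lev) {
    if (iters[lev] <= 0) continue;
    int f = factors[lev];
    int mx = std::max(2, nx / f), my = std::max(2, ny / f), mz = std::max(2, nz / f);
    double lsx = spacing[0] * nx / mx, lsy = spacing[1] * ny / my, lsz = spacing[2] * nz / mz;
    // anti-alias then resize images
    std::vector<double> Fs = F, Ms = M;
    if (f > 1) {
      double s = 0.5 * f;
      gauss_3d_inplace(Fs, nx, ny, nz, s, s, s);
      gauss_3d_inplace(Ms, nx, ny, nz, s, s, s);
    }
    std::vector<double> Fl = (f > 1) ? resize_vol(Fs, nx, ny, nz, mx, my, mz) : Fs;
    std::vector<double> Ml = (f > 1) ? resize_vol(Ms, nx, ny, nz, mx, my, mz) : Ms;
    // bring field to level resolution (mm values preserved)
    std::vector<double> lfx = resize_vol(fx, cur_nx, cur_ny, cur_nz, mx, my, mz);
    std::vector<double> lfy = resize_vol(fy, cur_nx, cur_ny, cur_nz, mx, my, mz);
    std::vector<double> lfz = resize_vol(fz, cur_nx, cur_ny, cur_nz, mx, my, mz);
    // step cap in full-resolution voxel units at every level: coarse levels
    // move no faster than fine ones, which keeps the accumulation stable
    double max_step_mm = max_step_vox *
      std::min(spacing[0], std::min(spacing[1], spacing[2]));
    double ts = total_sigma_vox[lev % total_sigma_vox.size()];
    demons_iterate(Fl, Ml, lfx, lfy, lfz, mx, my, mz, lsx, lsy, lsz,
                   iters[lev], sigma_vox, ts, max_step_mm);
    fx = lfx; fy = lfy; fz = lfz;
    cur_nx = mx; cur_ny = my; cur_nz = mz;
    field_full = (mx == nx && my == ny && mz == nz);
  }
  if (!field_full) {
    fx = resize_vol(fx, cur_nx, cur_ny, cur_nz, nx, ny, nz);
    fy = resize_vol(fy, cur_nx, cur_ny, cur_nz, nx, ny, nz);
    fz = resize_vol(fz, cur_nx, cur_ny, cur_nz, nx, ny, nz);
  }
  (void)n;
  return List::create(_["x"] = NumericVector(fx.begin(), fx.end()),
                      _["y"] = NumericVector(fy.begin(), fy.end()),
                      _["z"] = NumericVector(fz.begin(), fz.end()));
}

// Coarse free-form prealignment: displacement parameterized on a control grid
// (spacing cp voxels, trilinear interpolation), mean-squared metric, gradient
// descent with normalized step. Returns the total field (init + parametric part).
// [[Rcpp::export]]
List cpp_ffd_prealign(NumericVector fixed, NumericVector moving, IntegerVector dim,
                      NumericVector spacing, int cp_spacing_vox, int n_iter,
                      double step_mm, NumericVector fx0, NumericVector fy0,
                      NumericVector fz0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  int cp = std::max(2, cp_spacing_vox);
  int ncx = (nx - 2 + cp) / cp + 2, ncy = (ny - 2 + cp) / cp + 2, ncz = (nz - 2 + cp) / cp + 2;
  size_t nc = (size_t)ncx * ncy * ncz;
  std::vector<double> cx(nc, 0.0), cy(nc, 0.0), cz(nc, 0.0);
  std::vector<double> gx(nc), gy(nc), gz(nc);
  std::vector<double> bx(n), by(n), bz(n);
  const double* F = fixed.begin();
  const double* M = moving.begin();
  for (int it = 0; it < n_iter; ++it) {
    // field from control points
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long long id = IDX(i,j,k,nx,ny);
          double X = (double)i / cp, Y = (double)j / cp, Z = (double)k / cp;
          bx[id] = sample_lin_clamp(cx.data(), ncx, ncy, ncz, X, Y, Z);
          by[id] = sample_lin_clamp(cy.data(), ncx, ncy, ncz, X, Y, Z);
          bz[id] = sample_lin_clamp(cz.data(), ncx, ncy, ncz, X, Y, Z);
        }
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
    std::fill(gz.begin(), gz.end(), 0.0);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long long id = IDX(i,j,k,nx,ny);
          double ux = fx0[id] + bx[id], uy = fy0[id] + by[id], uz = fz0[id] + bz[id];
          double X = i + ux / spacing[0], Y = j + uy / spacing[1], Z = k + uz / spacing[2];
          double w = sample_lin_clamp(M, nx, ny, nz, X, Y, Z);
          double diff = w - F[id];
          if (std::fabs(diff) < 1e-12) continue;
          // gradient of the warped moving image (finite differences in sample space)
          double h = 0.5;
          double gmx = (sample_lin_clamp(M, nx, ny, nz, X + h, Y, Z) -
                        sample_lin_clamp(M, nx, ny, nz, X - h, Y, Z)) / (2 * h * spacing[0]);
          double gmy = (sample_lin_clamp(M, nx, ny, nz, X, Y + h, Z) -
                        sample_lin_clamp(M, nx, ny, nz, X, Y - h, Z)) / (2 * h * spacing[1]);
          double gmz = (sample_lin_clamp(M, nx, ny, nz, X, Y, Z + h) -
                        sample_lin_clamp(M, nx, ny, nz, X, Y, Z - h)) / (2 * h * spacing[2]);
          // distribute to the 8 surrounding control points
          double Xc = (double)i / cp, Yc = (double)j / cp, Zc = (double)k / cp;
          int x0 = std::min((int)std::floor(Xc), ncx - 2);
          int y0 = std::min((int)std::floor(Yc), ncy - 2);
          int z0 = std::min((int)std::floor(Zc), ncz - 2);
          double fxw = Xc - x0, fyw = Yc - y0, fzw = Zc - z0;
          for (int dz = 0; dz <= 1; ++dz)
            for (int dy = 0; dy <= 1; ++dy)
              for (int dx = 0; dx <= 1; ++dx) {
                double w8 = (dx ? fxw : 1 - fxw) * (dy ? fyw : 1 - fyw) * (dz ? fzw : 1 - fzw);
                long long cid = IDX(x0 + dx, y0 + dy, z0 + dz, ncx, ncy);
                gx[cid] += diff * gmx * w8;
                gy[cid] += diff * gmy * w8;
                gz[cid] += diff * gmz * w8;
              }
        }
    double mx = 0.0;
    for (size_t c = 0; c < nc; ++c) {
      double norm = std::sqrt(gx[c]*gx[c] + gy[c]*gy[c] + gz[c]*gz[c]);
      if (norm > mx) mx = norm;
    }
    if (mx < 1e-12) break;
    double sc = step_mm / mx;
    for (size_t c = 0; c < nc; ++c) {
      cx[c] -= sc * gx[c]; cy[c] -= sc * gy[c]; cz[c] -= sc * gz[c];
    }
  }
  NumericVector rx(n), ry(n), rz(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long long id = IDX(i,j,k,nx,ny);
        double X = (double)i / cp, Y = (double)j / cp, Z = (double)k / cp;
        rx[id] = fx0[id] + sample_lin_clamp(cx.data(), ncx, ncy, ncz, X, Y, Z);
        ry[id] = fy0[id] + sample_lin_clamp(cy.data(), ncx, ncy, ncz, X, Y, Z);
        rz[id] = fz0[id] + sample_lin_clamp(cz.data(), ncx, ncy, ncz, X, Y, Z);
      }
  return List::create(_["x"] = rx, _["y"] = ry, _["z"] = rz);
}

// Unit-weight dose of one beam: exponential depth attenuation of the relative
// electron density along parallel rays in direction `dir`, sigmoid lateral
// field edge of radius `field_radius` (mm) around the axis line through
// `axis_point` (mm), penumbra width `pen` (mm).
// [[Rcpp::export]]
NumericVector cpp_ray_dose(NumericVector rho, IntegerVector dim, NumericVector spacing,
                           NumericVector dir, NumericVector axis_point, double mu,
                           double field_radius, double pen, double step, double cutoff) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double* R = rho.begin();
  double dx = dir[0], dy = dir[1], dz = dir[2];
  double nrm = std::sqrt(dx*dx + dy*dy + dz*dz);
  dx /= nrm; dy /= nrm; dz /= nrm;
  double box_lo[3] = { -0.5 * spacing[0], -0.5 * spacing[1], -0.5 * spacing[2] };
  double box_hi[3] = { (nx - 0.5) * spacing[0], (ny - 0.5) * spacing[1], (nz - 0.5) * spacing[2] };
  double bvec[3] = { -dx, -dy, -dz };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long long id = IDX(i,j,k,nx,ny);
        double x = i * spacing[0], y = j * spacing[1], z = k * spacing[2];
        // lateral distance to the beam axis line
        double rxp = x - axis_point[0], ryp = y - axis_point[1], rzp = z - axis_point[2];
        double proj = rxp * dx + ryp * dy + rzp * dz;
        double lx = rxp - proj * dx, ly = ryp - proj * dy, lz = rzp - proj * dz;
        double lat = std::sqrt(lx*lx + ly*ly + lz*lz);
        double P = 1.0 / (1.0 + std::exp((lat - field_radius) / pen));
        if (P < cutoff) { out[id] = 0.0; continue; }
        // distance backwards along -dir to the bounding box
        double t_exit = std::numeric_limits<double>::infinity();
        double pos[3] = { x, y, z };
        for (int ax = 0; ax < 3; ++ax) {
          if (std::fabs(bvec[ax]) < 1e-12) continue;
          double t = bvec[ax] > 0 ? (box_hi[ax] - pos[ax]) / bvec[ax]
                                  : (box_lo[ax] - pos[ax]) / bvec[ax];
          if (t < t_exit) t_exit = t;
        }
        double depth = t_exit;
        long nsteps = (long)std::floor(depth / step);
        double rem = depth - nsteps * step;
        double cum = 0.0;
        // midpoint rule over [0, depth] measured backwards from the voxel:
        // full steps span [rem, depth] starting at the entry side, the
        // remainder spans [0, rem] next to the voxel.
        for (long s = 0; s < nsteps; ++s) {
          double t = depth - (s + 0.5) * step;
          double px = x + bvec[0] * t, py = y + bvec[1] * t, pz = z + bvec[2] * t;
          cum += step * sample_lin_clamp(R, nx, ny, nz,
                                         px / spacing[0], py / spacing[1], pz / spacing[2]);
        }
        if (rem > 1e-12) {
          double t = 0.5 * rem;
          double px = x + bvec[0] * t, py = y + bvec[1] * t, pz = z + bvec[2] * t;
          cum += rem * sample_lin_clamp(R, nx, ny, nz,
                                        px / spacing[0], py / spacing[1], pz / spacing[2]);
        }
        out[id] = P * std::exp(-mu * cum);
      }
  return out;
}

// 3D gamma with subvoxel search on a regular sample lattice inside a sphere
// of radius search_radius_mm, sample step sample_step_mm.
// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector ref, NumericVector evald, IntegerVector dim,
                        NumericVector spacing, double dose_pct, double dta_mm,
                        int local, double threshold_pct, double search_radius_mm,
                        double sample_step_mm) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double* Rv = ref.begin();
  const double* Ev = evald.begin();
  double dmax = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) if (Rv[i] > dmax) dmax = Rv[i];
  double thr = threshold_pct / 100.0 * dmax;
  double delta_global = dose_pct / 100.0 * dmax;
  // precompute offsets sorted by radius
  int half = (int)std::ceil(search_radius_mm / sample_step_mm);
  struct Off { double ox, oy, oz, r2; };
  std::vector<Off> offs;
  for (int a = -half; a <= half; ++a)
    for (int b = -half; b <= half; ++b)
      for (int c = -half; c <= half; ++c) {
        double ox = a * sample_step_mm, oy = b * sample_step_mm, oz = c * sample_step_mm;
        double r2 = ox*ox + oy*oy + oz*oz;
        if (r2 <= search_radius_mm * search_radius_mm + 1e-9)
          offs.push_back({ox, oy, oz, r2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off& a, const Off& b) { return a.r2 < b.r2; });
  NumericVector out(n);
  double dta2 = dta_mm * dta_mm;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long long id = IDX(i,j,k,nx,ny);
        double rd = Rv[id];
        if (rd < thr) { out[id] = NA_REAL; continue; }
        double delta = local ? dose_pct / 100.0 * rd : delta_global;
        if (delta < 1e-12) delta = 1e-12;
        double best = std::numeric_limits<double>::infinity();
        for (const auto& o : offs) {
          double rterm = o.r2 / dta2;
          if (rterm >= best) break; // offsets sorted: no better candidate ahead
          double X = i + o.ox / spacing[0];
          double Y = j + o.oy / spacing[1];
          double Z = k + o.oz / spacing[2];
          if (X < 0 || X > nx - 1 || Y < 0 || Y > ny - 1 || Z < 0 || Z > nz - 1)
            continue;
          double ed = sample_lin_clamp(Ev, nx, ny, nz, X, Y, Z);
          double dd = (ed - rd) / delta;
          double g2 = dd * dd + rterm;
          if (g2 < best) best = g2;
        }
        out[id] = std::sqrt(best);
      }
  return out;
}
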