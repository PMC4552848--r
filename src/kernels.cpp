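#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Index helper for column-major 3-D arrays.
static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sampling of `vol` at voxel coordinates (1-based, same convention
// as R indexing).  Coordinates outside the grid are clamped to the edge.
static double sample_trilinear(const NumericVector &vol, int nx, int ny, int nz,
                               double x, double y, double z) {
  x = clampd(x, 1.0, (double)nx);
  y = clampd(y, 1.0, (double)ny);
  z = clampd(z, 1.0, (double)nz);
  int i0 = (int)std::floor(x); if (i0 >= nx) i0 = nx - 1;
  int j0 = (int)std::floor(y); if (j0 >= ny) j0 = ny - 1;
  int k0 = (int)std::floor(z); if (k0 >= nz) k0 = nz - 1;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  int i1 = i0 + 1, j1 = j0 + 1, k1 = k0 + 1;
  // to 0-based
  int a = i0 - 1, b = j0 - 1, c = k0 - 1;
  int a1 = i1 - 1, b1 = j1 - 1, c1 = k1 - 1;
  double v000 = vol[idx3(a,  b,  c,  nx, ny)];
  double v100 = vol[idx3(a1, b,  c,  nx, ny)];
  double v010 = vol[idx3(a,  b1, c,  nx, ny)];
  double v110 = vol[idx3(a1, b1, c,  nx, ny)];
  double v001 = vol[idx3(a,  b,  c1, nx, ny)];
  double v101 = vol[idx3(a1, b,  c1, nx, ny)];
  double v011 = vol[idx3(a,  b1, c1, nx, ny)];
  double v111 = vol[idx3(a1, b1, c1, nx, ny)];
  double v00 = v000 * (1 - fx) + v100 * fx;
  double v10 = v010 * (1 - fx) + v110 * fx;
  double v01 = v001 * (1 - fx) + v101 * fx;
  double v11 = v011 * (1 - fx) + v111 * fx;
  double v0 = v00 * (1 - fy) + v10 * fy;
  double v1 = v01 * (1 - fy) + v11 * fy;
  return v0 * (1 - fz) + v1 * fz;
}

// [[Rcpp::export(name = ".cpp_warp")]]
NumericVector cpp_warp(NumericVector vol, IntegerVector dims,
                       NumericVector ux, NumericVector uy, NumericVector uz) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(vol.size());
  int n = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++n)
        out[n] = sample_trilinear(vol, nx, ny, nz,
                                  (i + 1) + ux[n], (j + 1) + uy[n], (k + 1) + uz[n]);
  return out;
}

// [[Rcpp::export(name = ".cpp_resample")]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dims,
                           IntegerVector newdims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = newdims[0], my = newdims[1], mz = newdims[2];
  NumericVector out((double)mx * my * mz);
  // voxel-center alignment: coordinate of output voxel i maps to
  // (i - 0.5) * nx/mx + 0.5 in input voxel units
  double sx = (double)nx / mx, sy = (double)ny / my, sz = (double)nz / mz;
  int n = 0;
  for (int k = 0; k < mz; ++k) {
    double z = (k + 0.5) * sz + 0.5;
    for (int j = 0; j < my; ++j) {
      double y = (j + 0.5) * sy + 0.5;
      for (int i = 0; i < mx; ++i, ++n)
        out[n] = sample_trilinear(vol, nx, ny, nz, (i + 0.5) * sx + 0.5, y, z);
    }
  }
  return out;
}

// Central differences in the interior, one-sided at the faces.
// [[Rcpp::export(name = ".cpp_gradient")]]
List cpp_gradient(NumericVector vol, IntegerVector dims, NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector gx(vol.size()), gy(vol.size()), gz(vol.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int n = idx3(i, j, k, nx, ny);
        int ip = i < nx - 1 ? i + 1 : i, im = i > 0 ? i - 1 : i;
        int jp = j < ny - 1 ? j + 1 : j, jm = j > 0 ? j - 1 : j;
        int kp = k < nz - 1 ? k + 1 : k, km = k > 0 ? k - 1 : k;
        gx[n] = (vol[idx3(ip, j, k, nx, ny)] - vol[idx3(im, j, k, nx, ny)]) /
                ((ip - im) * spacing[0]);
        gy[n] = (vol[idx3(i, jp, k, nx, ny)] - vol[idx3(i, jm, k, nx, ny)]) /
                ((jp - jm) * spacing[1]);
        gz[n] = (vol[idx3(i, j, kp, nx, ny)] - vol[idx3(i, j, km, nx, ny)]) /
                ((kp - km) * spacing[2]);
      }
  return List::create(_["x"] = gx, _["y"] = gy, _["z"] = gz);
}

static void smooth_axis(std::vector<double> &buf, NumericVector &vol,
                        int nx, int ny, int nz, int axis,
                        const std::vector<double> &kern) {
  int r = ((int)kern.size() - 1) / 2;
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  buf.resize(len);
  int n_outer1 = axis == 0 ? ny : nx;
  int n_outer2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n_outer2; ++b)
    for (int a = 0; a < n_outer1; ++a) {
      for (int t = 0; t < len; ++t) {
        int i = axis == 0 ? t : a;
        int j = axis == 0 ? a : (axis == 1 ? t : b);
        int k = axis == 2 ? t : b;
        buf[t] = vol[idx3(i, j, k, nx, ny)];
      }
      for (int t = 0; t < len; ++t) {
        double acc = 0.0, wsum = 0.0;
        for (int s = -r; s <= r; ++s) {
          int u = t + s;
          if (u < 0 || u >= len) continue;
          acc += kern[s + r] * buf[u];
          wsum += kern[s + r];
        }
        int i = axis == 0 ? t : a;
        int j = axis == 0 ? a : (axis == 1 ? t : b);
        int k = axis == 2 ? t : b;
        vol[idx3(i, j, k, nx, ny)] = acc / wsum;
      }
    }
}

// Separable Gaussian smoothing, sigma in voxels.
// [[Rcpp::export(name = ".cpp_gauss_smooth")]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dims,
                               double sigma) {
  NumericVector out = clone(vol);
  if (sigma <= 0) return out;
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  for (int s = -r; s <= r; ++s)
    kern[s + r] = std::exp(-0.5 * (double)s * s / (sigma * sigma));
  std::vector<double> buf;
  smooth_axis(buf, out, nx, ny, nz, 0, kern);
  smooth_axis(buf, out, nx, ny, nz, 1, kern);
  smooth_axis(buf, out, nx, ny, nz, 2, kern);
  return out;
}

// 6-connected component labelling of a logical mask (iterative stack-based
// flood fill).  Labels are 1..n_components in decreasing order of size.
// [[Rcpp::export(name = ".cpp_label6")]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ntot = nx * ny * nz;
  IntegerVector lab(ntot, 0);
  std::vector<int> stack;
  std::vector<std::pair<int,int> > sizes; // (label, size)
  int next = 0;
  for (int seed = 0; seed < ntot; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++next;
    int sz = 0;
    stack.push_back(seed);
    lab[seed] = next;
    while (!stack.empty()) {
      int n = stack.back(); stack.pop_back();
      ++sz;
      int i = n % nx, j = (n / nx) % ny, k = n / (nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        int m = idx3(ii, jj, kk, nx, ny);
        if (mask[m] && lab[m] == 0) {
          lab[m] = next;
          stack.push_back(m);
        }
      }
    }
    sizes.push_back(std::make_pair(next, sz));
  }
  // relabel so component 1 is the largest
  std::sort(sizes.begin(), sizes.end(),
            [](const std::pair<int,int> &a, const std::pair<int,int> &b) {
              return a.second > b.second;
            });
  std::vector<int> remap(next + 1, 0);
  for (size_t r = 0; r < sizes.size(); ++r) remap[sizes[r].first] = (int)r + 1;
  for (int n = 0; n < ntot; ++n)
    if (lab[n] != 0) lab[n] = remap[lab[n]];
  return lab;
}

// Determinant of the Jacobian of phi(x) = x + u(x) by central differences,
// u given in voxel units.  One-sided differences at faces, and -- when a
// mask is supplied -- at the mask boundary, so that field values outside
// the masked region never enter the derivative of a masked voxel.
// [[Rcpp::export(name = ".cpp_jacobian_det")]]
NumericVector cpp_jacobian_det(NumericVector ux, NumericVector uy,
                               NumericVector uz, IntegerVector dims,
                               Nullable<LogicalVector> mask_ = R_NilValue) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  bool has_mask = mask_.isNotNull();
  LogicalVector mask;
  if (has_mask) mask = mask_.get();
  NumericVector out((double)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int n = idx3(i, j, k, nx, ny);
        int ip = i < nx - 1 ? i + 1 : i, im = i > 0 ? i - 1 : i;
        int jp = j < ny - 1 ? j + 1 : j, jm = j > 0 ? j - 1 : j;
        int kp = k < nz - 1 ? k + 1 : k, km = k > 0 ? k - 1 : k;
        if (has_mask && mask[n]) {
          // retreat to one-sided differences along axes whose neighbour
          // leaves the mask (keep central if both would)
          if (!mask[idx3(ip, j, k, nx, ny)] && mask[idx3(im, j, k, nx, ny)])
            ip = i;
          else if (!mask[idx3(im, j, k, nx, ny)] &&
                   mask[idx3(ip, j, k, nx, ny)])
            im = i;
          if (!mask[idx3(i, jp, k, nx, ny)] && mask[idx3(i, jm, k, nx, ny)])
            jp = j;
          else if (!mask[idx3(i, jm, k, nx, ny)] &&
                   mask[idx3(i, jp, k, nx, ny)])
            jm = j;
          if (!mask[idx3(i, j, kp, nx, ny)] && mask[idx3(i, j, km, nx, ny)])
            kp = k;
          else if (!mask[idx3(i, j, km, nx, ny)] &&
                   mask[idx3(i, j, kp, nx, ny)])
            km = k;
          if (ip == im) { ip = i < nx - 1 ? i + 1 : i; im = i > 0 ? i - 1 : i; }
          if (jp == jm) { jp = j < ny - 1 ? j + 1 : j; jm = j > 0 ? j - 1 : j; }
          if (kp == km) { kp = k < nz - 1 ? k + 1 : k; km = k > 0 ? k - 1 : k; }
        }
        double hx = (double)(ip - im), hy = (double)(jp - jm),
               hz = (double)(kp - km);
        double a11 = 1 + (ux[idx3(ip,j,k,nx,ny)] - ux[idx3(im,j,k,nx,ny)]) / hx;
        double a12 =     (ux[idx3(i,jp,k,nx,ny)] - ux[idx3(i,jm,k,nx,ny)]) / hy;
        double a13 =     (ux[idx3(i,j,kp,nx,ny)] - ux[idx3(i,j,km,nx,ny)]) / hz;
        double a21 =     (uy[idx3(ip,j,k,nx,ny)] - uy[idx3(im,j,k,nx,ny)]) / hx;
        double a22 = 1 + (uy[idx3(i,jp,k,nx,ny)] - uy[idx3(i,jm,k,nx,ny)]) / hy;
        double a23 =     (uy[idx3(i,j,kp,nx,ny)] - uy[idx3(i,j,km,nx,ny)]) / hz;
        double a31 =     (uz[idx3(ip,j,k,nx,ny)] - uz[idx3(im,j,k,nx,ny)]) / hx;
        double a32 =     (uz[idx3(i,jp,k,nx,ny)] - uz[idx3(i,jm,k,nx,ny)]) / hy;
        double a33 = 1 + (uz[idx3(i,j,kp,nx,ny)] - uz[idx3(i,j,km,nx,ny)]) / hz;
        out[n] = a11 * (a22 * a33 - a23 * a32)
               - a12 * (a21 * a33 - a23 * a31)
               + a13 * (a21 * a32 - a22 * a31);
      }
  return out;
}
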