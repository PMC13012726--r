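#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Interpolation kernels used for plane extraction, resampling and radial
// profile sampling. Voxel coordinates are 0-based; voxel (i,j,k) is centred
// at physical position index * spacing.

static inline long long lin3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// Trilinear sampling of a 3D volume at arbitrary voxel coordinates.
// Points outside the grid return `fill` and are flagged.
// [[Rcpp::export]]
List cpp_trilinear(NumericVector vol, IntegerVector dims, NumericMatrix pts,
                   double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = pts.nrow();
  NumericVector out(m);
  LogicalVector oob(m);
  for (int p = 0; p < m; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = fill;
      oob[p] = true;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c00 = vol[lin3(i0, j0, k0, nx, ny)] * (1 - fx) + vol[lin3(i1, j0, k0, nx, ny)] * fx;
    double c10 = vol[lin3(i0, j1, k0, nx, ny)] * (1 - fx) + vol[lin3(i1, j1, k0, nx, ny)] * fx;
    double c01 = vol[lin3(i0, j0, k1, nx, ny)] * (1 - fx) + vol[lin3(i1, j0, k1, nx, ny)] * fx;
    double c11 = vol[lin3(i0, j1, k1, nx, ny)] * (1 - fx) + vol[lin3(i1, j1, k1, nx, ny)] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
    oob[p] = false;
  }
  return List::create(_["values"] = out, _["outside"] = oob);
}

// Nearest-neighbour sampling of a 3D volume at arbitrary voxel coordinates.
// [[Rcpp::export]]
List cpp_nearest3(NumericVector vol, IntegerVector dims, NumericMatrix pts,
                  double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = pts.nrow();
  NumericVector out(m);
  LogicalVector oob(m);
  for (int p = 0; p < m; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
      out[p] = fill;
      oob[p] = true;
    } else {
      out[p] = vol[lin3(i, j, k, nx, ny)];
      oob[p] = false;
    }
  }
  return List::create(_["values"] = out, _["outside"] = oob);
}

// Keys cubic convolution kernel (a = -0.5), the standard bicubic kernel.
static inline double keys(double t) {
  t = std::fabs(t);
  if (t <= 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

// Bicubic sampling of a 2D image at arbitrary pixel coordinates (0-based),
// border pixels clamped.
// [[Rcpp::export]]
NumericVector cpp_bicubic2d(NumericMatrix img, NumericMatrix pts) {
  const int nx = img.nrow(), ny = img.ncol();
  const int m = pts.nrow();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    double x = pts(p, 0), y = pts(p, 1);
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y);
    double acc = 0.0, wsum = 0.0;
    for (int dj = -1; dj <= 2; ++dj) {
      int j = j0 + dj;
      int jc = std::min(std::max(j, 0), ny - 1);
      double wy = keys(y - j);
      if (wy == 0.0) continue;
      for (int di = -1; di <= 2; ++di) {
        int i = i0 + di;
        int ic = std::min(std::max(i, 0), nx - 1);
        double wx = keys(x - i);
        if (wx == 0.0) continue;
        acc += wx * wy * img(ic, jc);
        wsum += wx * wy;
      }
    }
    out[p] = wsum != 0.0 ? acc / wsum : 0.0;
  }
  return out;
}
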