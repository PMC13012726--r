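#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// 3D voxel primitives shared by the preprocessing, skeletonization and radius
// modules. All grids are column-major (nx, ny, nz) as stored by R arrays;
// voxel (i,j,k) sits at linear index i + nx*(j + ny*k).

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// ---------------------------------------------------------------------------
// Connected component labelling (6- or 26-connectivity), BFS flood fill.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && ad != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::vector<long long> stack;
  for (long long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      long long v = stack.back(); stack.pop_back();
      int k = (int)(v / ((long long)nx * ny));
      int rem = (int)(v - (long long)k * nx * ny);
      int j = rem / nx, i = rem % nx;
      for (auto &o : offs) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        long long w = lin(ii, jj, kk, nx, ny);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// anisotropic spacing; distance of every voxel to the nearest TRUE voxel.
static void dt1d(std::vector<double> &f, std::vector<double> &d, double step) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) / (2.0 * s2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector sites, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  const double INF = 1e30;
  NumericVector d(n);
  for (long long s = 0; s < n; ++s) d[s] = sites[s] ? 0.0 : INF;
  // x pass
  {
    std::vector<double> f(nx), g(nx);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) f[i] = d[lin(i, j, k, nx, ny)];
        dt1d(f, g, spacing[0]);
        for (int i = 0; i < nx; ++i) d[lin(i, j, k, nx, ny)] = g[i];
      }
  }
  // y pass
  {
    std::vector<double> f(ny), g(ny);
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) f[j] = d[lin(i, j, k, nx, ny)];
        dt1d(f, g, spacing[1]);
        for (int j = 0; j < ny; ++j) d[lin(i, j, k, nx, ny)] = g[j];
      }
  }
  // z pass
  {
    std::vector<double> f(nz), g(nz);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) f[k] = d[lin(i, j, k, nx, ny)];
        dt1d(f, g, spacing[2]);
        for (int k = 0; k < nz; ++k) d[lin(i, j, k, nx, ny)] = g[k];
      }
  }
  for (long long s = 0; s < n; ++s) d[s] = std::sqrt(d[s]);
  return d;
}

// ---------------------------------------------------------------------------
// Slicewise binary dilation with a radius-1 disk (diamond / plus footprint)
// applied in the xy plane, `rounds` times.
// [[Rcpp::export]]
LogicalVector cpp_dilate_xy_disk(LogicalVector mask, IntegerVector dims, int rounds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  LogicalVector a = clone(mask), b(n);
  for (int r = 0; r < rounds; ++r) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long long v = lin(i, j, k, nx, ny);
          bool on = a[v];
          if (!on && i > 0) on = a[lin(i - 1, j, k, nx, ny)];
          if (!on && i < nx - 1) on = a[lin(i + 1, j, k, nx, ny)];
          if (!on && j > 0) on = a[lin(i, j - 1, k, nx, ny)];
          if (!on && j < ny - 1) on = a[lin(i, j + 1, k, nx, ny)];
          b[v] = on;
        }
    std::swap(a, b);
  }
  return a;
}

// ---------------------------------------------------------------------------
// Homotopy-preserving 3D thinning to a curve skeleton.
//
// A border voxel is deleted when it is a simple point (Bertrand & Malandain
// characterisation: exactly one 26-component of foreground in the 26-
// neighbourhood, exactly one 6-component of background in the 18-
// neighbourhood that touches a face neighbour) and not a curve endpoint
// (<= 1 foreground 26-neighbour). Six directional subiterations per pass
// keep the result centred; deletions are sequential, so topology is
// preserved exactly.

static const int N26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}
};

static bool is_simple(const std::vector<char> &m, int i, int j, int k,
                      int nx, int ny, int nz) {
  // local 3x3x3 neighbourhood, center excluded; out-of-volume is background
  bool fg[3][3][3];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ii = i + dx, jj = j + dy, kk = k + dz;
        bool v = false;
        if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
          v = m[lin(ii, jj, kk, nx, ny)] != 0;
        fg[dx + 1][dy + 1][dz + 1] = v;
      }
  fg[1][1][1] = false;

  // condition 1: foreground 26-neighbours form exactly one 26-component
  int idx[3][3][3];
  int nf = 0;
  for (int a = 0; a < 26; ++a) {
    int x = N26[a][0] + 1, y = N26[a][1] + 1, z = N26[a][2] + 1;
    idx[x][y][z] = fg[x][y][z] ? nf++ : -1;
  }
  if (nf == 0) return false;
  {
    // flood fill over foreground cells of the 26-neighbourhood
    std::vector<char> seen(nf, 0);
    std::vector<std::array<int,3>> st;
    int comps = 0;
    for (int a = 0; a < 26; ++a) {
      int x = N26[a][0] + 1, y = N26[a][1] + 1, z = N26[a][2] + 1;
      if (!fg[x][y][z] || seen[idx[x][y][z]]) continue;
      ++comps;
      if (comps > 1) return false;
      st.clear(); st.push_back({x, y, z}); seen[idx[x][y][z]] = 1;
      while (!st.empty()) {
        auto c = st.back(); st.pop_back();
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = c[0] + dx, y2 = c[1] + dy, z2 = c[2] + dz;
              if (x2 < 0 || y2 < 0 || z2 < 0 || x2 > 2 || y2 > 2 || z2 > 2) continue;
              if (x2 == 1 && y2 == 1 && z2 == 1) continue;
              if (!fg[x2][y2][z2]) continue;
              if (seen[idx[x2][y2][z2]]) continue;
              seen[idx[x2][y2][z2]] = 1;
              st.push_back({x2, y2, z2});
            }
      }
    }
    if (comps != 1) return false;
  }

  // condition 2: background 6-components within the 18-neighbourhood,
  // restricted to those 6-adjacent to the center (i.e. containing a face
  // neighbour), must number exactly one.
  // cells of the 18-neighbourhood: |dx|+|dy|+|dz| <= 2, not center
  auto in18 = [](int x, int y, int z) {
    int ad = std::abs(x - 1) + std::abs(y - 1) + std::abs(z - 1);
    return ad >= 1 && ad <= 2;
  };
  char seen2[3][3][3] = {{{0}}};
  int comps2 = 0;
  std::vector<std::array<int,3>> st2;
  static const int F6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (auto &f6 : F6) {
    int x0 = f6[0] + 1, y0 = f6[1] + 1, z0 = f6[2] + 1;
    if (fg[x0][y0][z0] || seen2[x0][y0][z0]) continue;
    ++comps2;
    if (comps2 > 1) return false;
    st2.clear(); st2.push_back({x0, y0, z0}); seen2[x0][y0][z0] = 1;
    while (!st2.empty()) {
      auto c = st2.back(); st2.pop_back();
      for (auto &d6 : F6) {
        int x2 = c[0] + d6[0], y2 = c[1] + d6[1], z2 = c[2] + d6[2];
        if (x2 < 0 || y2 < 0 || z2 < 0 || x2 > 2 || y2 > 2 || z2 > 2) continue;
        if (!in18(x2, y2, z2)) continue;
        if (fg[x2][y2][z2] || seen2[x2][y2][z2]) continue;
        seen2[x2][y2][z2] = 1;
        st2.push_back({x2, y2, z2});
      }
    }
  }
  return comps2 == 1;
}

static int n_fg_neighbours(const std::vector<char> &m, int i, int j, int k,
                           int nx, int ny, int nz) {
  int c = 0;
  for (int a = 0; a < 26; ++a) {
    int ii = i + N26[a][0], jj = j + N26[a][1], kk = k + N26[a][2];
    if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
    if (m[lin(ii, jj, kk, nx, ny)]) ++c;
  }
  return c;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  std::vector<char> m(n);
  for (long long s = 0; s < n; ++s) m[s] = mask[s] ? 1 : 0;
  static const int DIRS[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool changed = true;
  while (changed) {
    changed = false;
    for (auto &d : DIRS) {
      // collect candidates with a background neighbour in direction d
      std::vector<long long> cand;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            long long v = lin(i, j, k, nx, ny);
            if (!m[v]) continue;
            int ii = i + d[0], jj = j + d[1], kk = k + d[2];
            bool bg = true;
            if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
              bg = !m[lin(ii, jj, kk, nx, ny)];
            if (bg) cand.push_back(v);
          }
      for (long long v : cand) {
        if (!m[v]) continue;
        int k = (int)(v / ((long long)nx * ny));
        int rem = (int)(v - (long long)k * nx * ny);
        int j = rem / nx, i = rem % nx;
        if (n_fg_neighbours(m, i, j, k, nx, ny, nz) <= 1) continue; // endpoint
        if (is_simple(m, i, j, k, nx, ny, nz)) {
          m[v] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (long long s = 0; s < n; ++s) out[s] = m[s] != 0;
  return out;
}
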