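#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// All kernels operate on 3D arrays stored in R's column-major layout:
// linear index = i + nx*(j + ny*k), 0-based here.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable Gaussian smoothing with per-axis sigma in voxel units.
// Kernel truncated at 3.5 sigma, renormalised; reflected boundary.
// [[Rcpp::export(name = ".cpp_gaussian_smooth3d")]]
NumericVector cpp_gaussian_smooth3d(NumericVector arr, IntegerVector dims,
                                    NumericVector sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector src = clone(arr);
  NumericVector dst(n);
  int nd[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};

  for (int ax = 0; ax < 3; ax++) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.5 * s);
    std::vector<double> k(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; t++) {
      k[t + r] = std::exp(-0.5 * (double)t * t / (s * s));
      tot += k[t + r];
    }
    for (int t = 0; t <= 2 * r; t++) k[t] /= tot;

    int len = nd[ax];
    R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    int d1 = (ax == 0) ? 1 : 0;
    int d2 = (ax == 2) ? 1 : 2;
    for (int b = 0; b < nd[d2]; b++) {
      for (int a = 0; a < nd[d1]; a++) {
        R_xlen_t base = (R_xlen_t)a * stride[d1] + (R_xlen_t)b * stride[d2];
        for (int p = 0; p < len; p++) {
          double acc = 0;
          for (int t = -r; t <= r; t++) {
            int q = p + t;
            if (q < 0) q = -q - 1;            // reflect
            if (q >= len) q = 2 * len - q - 1;
            q = clampi(q, 0, len - 1);
            acc += k[t + r] * src[base + (R_xlen_t)q * st];
          }
          dst[base + (R_xlen_t)p * st] = acc;
        }
      }
    }
    std::copy(dst.begin(), dst.end(), src.begin());
  }
  return src;
}

// 3D Sobel gradient magnitude. Component along each axis is the derivative
// kernel [-1,0,1] combined with [1,2,1] smoothing on the two orthogonal
// axes; components are scaled by 1/spacing to give a physical gradient.
// Replicated boundary.
// [[Rcpp::export(name = ".cpp_sobel_magnitude3d")]]
NumericVector cpp_sobel_magnitude3d(NumericVector arr, IntegerVector dims,
                                    NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  double w[3] = {1.0, 2.0, 1.0};
  double inv[3] = {1.0 / spacing[0], 1.0 / spacing[1], 1.0 / spacing[2]};

  for (int kz = 0; kz < nz; kz++) {
    for (int jy = 0; jy < ny; jy++) {
      for (int ix = 0; ix < nx; ix++) {
        double g[3] = {0, 0, 0};
        for (int dz = -1; dz <= 1; dz++) {
          int z = clampi(kz + dz, 0, nz - 1);
          for (int dy = -1; dy <= 1; dy++) {
            int y = clampi(jy + dy, 0, ny - 1);
            for (int dx = -1; dx <= 1; dx++) {
              int x = clampi(ix + dx, 0, nx - 1);
              double v = arr[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
              g[0] += dx * w[dy + 1] * w[dz + 1] * v;
              g[1] += dy * w[dx + 1] * w[dz + 1] * v;
              g[2] += dz * w[dx + 1] * w[dy + 1] * v;
            }
          }
        }
        g[0] *= inv[0]; g[1] *= inv[1]; g[2] *= inv[2];
        out[ix + (R_xlen_t)nx * (jy + (R_xlen_t)ny * kz)] =
          std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
      }
    }
  }
  return out;
}

// Binary dilation by an arbitrary structuring element given as an m x 3
// matrix of integer voxel offsets. Stamps offsets from each set voxel, so
// cost scales with the number of set voxels.
// [[Rcpp::export(name = ".cpp_dilate_offsets")]]
LogicalVector cpp_dilate_offsets(LogicalVector mask, IntegerVector dims,
                                 IntegerMatrix offsets) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int m = offsets.nrow();
  LogicalVector out(n);
  for (int kz = 0; kz < nz; kz++) {
    for (int jy = 0; jy < ny; jy++) {
      for (int ix = 0; ix < nx; ix++) {
        if (!mask[ix + (R_xlen_t)nx * (jy + (R_xlen_t)ny * kz)]) continue;
        for (int t = 0; t < m; t++) {
          int x = ix + offsets(t, 0);
          int y = jy + offsets(t, 1);
          int z = kz + offsets(t, 2);
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
            continue;
          out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = true;
        }
      }
    }
  }
  return out;
}

// Count of face-connected (6-neighbourhood) set neighbours per voxel.
// [[Rcpp::export(name = ".cpp_count_neighbors6")]]
IntegerVector cpp_count_neighbors6(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n);
  int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int kz = 0; kz < nz; kz++)
    for (int jy = 0; jy < ny; jy++)
      for (int ix = 0; ix < nx; ix++) {
        int c = 0;
        for (int t = 0; t < 6; t++) {
          int x = ix + off[t][0], y = jy + off[t][1], z = kz + off[t][2];
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
            continue;
          if (mask[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)]) c++;
        }
        out[ix + (R_xlen_t)nx * (jy + (R_xlen_t)ny * kz)] = c;
      }
  return out;
}

// Connected-component labelling (BFS). Components are numbered 1,2,... in
// raster-scan order of their first voxel, so component 1 contains the
// smallest linear index among voxels of any component.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    cur++;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int ix = (int)(v % nx);
      int jy = (int)((v / nx) % ny);
      int kz = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t t = 0; t < offs.size(); t++) {
        int x = ix + offs[t][0], y = jy + offs[t][1], z = kz + offs[t][2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
          continue;
        R_xlen_t w = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (mask[w] && !lab[w]) { lab[w] = cur; q.push(w); }
      }
    }
  }
  return lab;
}
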