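#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 3D voxel primitives used by the segmentation stage. These operate on
// flat vectors in R's column-major order with an explicit dim triple;
// connectivity is 6-neighbour (face-adjacent), the standard choice for
// anisotropic confocal stacks.

static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        if (!mask[i] || labels[i] != 0) continue;
        ++current;
        labels[i] = current;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t j = stack.back();
          stack.pop_back();
          int jz = (int)(j / ((R_xlen_t)nx * ny));
          int rem = (int)(j % ((R_xlen_t)nx * ny));
          int jy = rem / nx, jx = rem % nx;
          for (int k = 0; k < 6; ++k) {
            int ax = jx + dx[k], ay = jy + dy[k], az = jz + dz[k];
            if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz)
              continue;
            R_xlen_t a = idx3(ax, ay, az, nx, ny);
            if (mask[a] && labels[a] == 0) {
              labels[a] = current;
              stack.push_back(a);
            }
          }
        }
      }
  labels.attr("max_label") = current;
  return labels;
}

// Fill interior cavities: flood the background from every frame face;
// any voxel reachable neither as foreground nor as outside background
// is a hole and becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && y != 0 && z != 0 && x != nx - 1 && y != ny - 1 &&
            z != nz - 1)
          continue;
        R_xlen_t i = idx3(x, y, z, nx, ny);
        if (!mask[i] && !outside[i]) {
          outside[i] = 1;
          stack.push_back(i);
        }
      }
  while (!stack.empty()) {
    R_xlen_t j = stack.back();
    stack.pop_back();
    int jz = (int)(j / ((R_xlen_t)nx * ny));
    int rem = (int)(j % ((R_xlen_t)nx * ny));
    int jy = rem / nx, jx = rem % nx;
    for (int k = 0; k < 6; ++k) {
      int ax = jx + dx[k], ay = jy + dy[k], az = jz + dz[k];
      if (ax < 0 || ay < 0 || az < 0 || ax >= nx || ay >= ny || az >= nz)
        continue;
      R_xlen_t a = idx3(ax, ay, az, nx, ny);
      if (!mask[a] && !outside[a]) {
        outside[a] = 1;
        stack.push_back(a);
      }
    }
  }
  LogicalVector filled(n);
  for (R_xlen_t i = 0; i < n; ++i) filled[i] = mask[i] || !outside[i];
  return filled;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(4.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    double v = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    k[i + r] = v;
    s += v;
  }
  for (double& v : k) v /= s;
  return k;
}

// Separable Gaussian blur with reflecting boundaries; sigma is given in
// voxels per axis, zero sigma skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3d(NumericVector arr, IntegerVector dim,
                               NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (arr.size() != n) stop("array length does not match dim");
  std::vector<double> cur(arr.begin(), arr.end()), nxt(n);
  const int nd[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    std::vector<double> k = gauss_kernel(s);
    int r = ((int)k.size() - 1) / 2;
    int len = nd[axis];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double acc = 0.0;
          int pos = (axis == 0) ? x : (axis == 1) ? y : z;
          for (int t = -r; t <= r; ++t) {
            int p = pos + t;
            if (p < 0) p = -p - 1;            // reflect
            if (p >= len) p = 2 * len - p - 1;
            R_xlen_t j = (axis == 0)   ? idx3(p, y, z, nx, ny)
                         : (axis == 1) ? idx3(x, p, z, nx, ny)
                                       : idx3(x, y, p, nx, ny);
            acc += k[t + r] * cur[j];
          }
          nxt[idx3(x, y, z, nx, ny)] = acc;
        }
    cur.swap(nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}
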