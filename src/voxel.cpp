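#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Axis order throughout is (z, y, x): the first array dimension varies
// fastest in R's linear storage, so linear index = z + nz*(y + ny*x).

// Trilinear sampling of a 3D array at fractional 1-based (z,y,x) coordinates.
// Samples whose 2x2x2 support leaves the array are flagged invalid and
// returned as `fill`.
// [[Rcpp::export]]
List cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                          NumericMatrix coords, double fill) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  LogicalVector ok(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double z = coords(i, 0) - 1.0, y = coords(i, 1) - 1.0, x = coords(i, 2) - 1.0;
    int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
    // allow exact upper boundary: treat coordinate == dim as the last cell
    if (z0 == nz - 1 && z == (double)z0) z0--;
    if (y0 == ny - 1 && y == (double)y0) y0--;
    if (x0 == nx - 1 && x == (double)x0) x0--;
    if (nz == 1) z0 = 0;
    if (ny == 1) y0 = 0;
    if (nx == 1) x0 = 0;
    if (z0 < 0 || y0 < 0 || x0 < 0 ||
        z0 + 1 > nz - 1 + (nz == 1) || y0 + 1 > ny - 1 + (ny == 1) ||
        x0 + 1 > nx - 1 + (nx == 1)) {
      out[i] = fill; ok[i] = false; continue;
    }
    int z1 = (nz == 1) ? z0 : z0 + 1;
    int y1 = (ny == 1) ? y0 : y0 + 1;
    int x1 = (nx == 1) ? x0 : x0 + 1;
    double fz = z - z0, fy = y - y0, fx = x - x0;
    if (nz == 1) fz = 0.0;
    if (ny == 1) fy = 0.0;
    if (nx == 1) fx = 0.0;
    #define V(zz, yy, xx) vol[(zz) + (R_xlen_t)nz * ((yy) + (R_xlen_t)ny * (xx))]
    double c00 = V(z0, y0, x0) * (1 - fz) + V(z1, y0, x0) * fz;
    double c01 = V(z0, y0, x1) * (1 - fz) + V(z1, y0, x1) * fz;
    double c10 = V(z0, y1, x0) * (1 - fz) + V(z1, y1, x0) * fz;
    double c11 = V(z0, y1, x1) * (1 - fz) + V(z1, y1, x1) * fz;
    #undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fx) + c1 * fx;
    ok[i] = true;
  }
  return List::create(_["values"] = out, _["inside"] = ok);
}

// Nearest-neighbour sampling (for integer label volumes).
// [[Rcpp::export]]
List cpp_sample_nearest(IntegerVector vol, IntegerVector dim,
                        NumericMatrix coords, int fill) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = coords.nrow();
  IntegerVector out(n);
  LogicalVector ok(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int z = (int)std::floor(coords(i, 0) - 1.0 + 0.5);
    int y = (int)std::floor(coords(i, 1) - 1.0 + 0.5);
    int x = (int)std::floor(coords(i, 2) - 1.0 + 0.5);
    if (z < 0 || y < 0 || x < 0 || z >= nz || y >= ny || x >= nx) {
      out[i] = fill; ok[i] = false; continue;
    }
    out[i] = vol[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
    ok[i] = true;
  }
  return List::create(_["values"] = out, _["inside"] = ok);
}

// Bilinear sampling of a matrix at fractional 1-based (row, col) coordinates.
// [[Rcpp::export]]
List cpp_sample_bilinear(NumericMatrix img, NumericMatrix coords, double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  LogicalVector ok(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double r = coords(i, 0) - 1.0, c = coords(i, 1) - 1.0;
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    if (r0 == nr - 1 && r == (double)r0) r0--;
    if (c0 == nc - 1 && c == (double)c0) c0--;
    if (r0 < 0 || c0 < 0 || r0 + 1 > nr - 1 || c0 + 1 > nc - 1) {
      out[i] = fill; ok[i] = false; continue;
    }
    double fr = r - r0, fc = c - c0;
    double v0 = img(r0, c0) * (1 - fr) + img(r0 + 1, c0) * fr;
    double v1 = img(r0, c0 + 1) * (1 - fr) + img(r0 + 1, c0 + 1) * fr;
    out[i] = v0 * (1 - fc) + v1 * fc;
    ok[i] = true;
  }
  return List::create(_["values"] = out, _["inside"] = ok);
}

// 26-connected component labelling of a binary mask (flood fill with an
// explicit stack). Components are numbered in order of their first voxel in
// R linear scan order; the caller re-orders as needed.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);  // zero-initialised
  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++current;
    lab[start] = current;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int z = (int)(idx % nz);
      R_xlen_t rest = idx / nz;
      int y = (int)(rest % ny);
      int x = (int)(rest / ny);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[j] && !lab[j]) {
              lab[j] = current;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = current;
  return lab;
}

// Per-component exposed-face counts (6-neighbourhood) and surface-voxel
// flags for a component-labelled volume. A face is exposed when the
// neighbour carries a different component id (or lies outside the array).
// [[Rcpp::export]]
List cpp_component_surfaces(IntegerVector lab, IntegerVector dim, int ncomp) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector faces(ncomp);
  LogicalVector surf(n);
  const int dzs[6] = {-1, 1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, -1, 1, 0, 0};
  const int dxs[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    int id = lab[idx];
    if (!id) continue;
    int z = (int)(idx % nz);
    R_xlen_t rest = idx / nz;
    int y = (int)(rest % ny);
    int x = (int)(rest / ny);
    int exposed = 0;
    for (int k = 0; k < 6; ++k) {
      int zz = z + dzs[k], yy = y + dys[k], xx = x + dxs[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) {
        ++exposed;
        continue;
      }
      if (lab[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)] != id) ++exposed;
    }
    if (exposed) {
      faces[id - 1] += exposed;
      surf[idx] = true;
    }
  }
  return List::create(_["faces"] = faces, _["surface"] = surf);
}

// Voxelize the quadratic form x^T M x <= 1 on a centred cubic grid:
// returns a logical vector over an n^3 grid (n = 2*half + 1) marking
// voxel centres inside the ellipsoid. Coordinates are (offset * voxel_um).
// [[Rcpp::export]]
LogicalVector cpp_ellipsoid_mask(int half, double voxel_um,
                                 NumericMatrix M) {
  const int n = 2 * half + 1;
  LogicalVector out((R_xlen_t)n * n * n);
  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2);
  const double m11 = M(1, 1), m12 = M(1, 2), m22 = M(2, 2);
  R_xlen_t idx = 0;
  // R linear order: first index (z) fastest
  for (int x = -half; x <= half; ++x) {
    double px = x * voxel_um;
    for (int y = -half; y <= half; ++y) {
      double py = y * voxel_um;
      double cyy = m11 * py * py + m22 * px * px + 2.0 * m12 * py * px;
      double lin = 2.0 * (m01 * py + m02 * px);
      for (int z = -half; z <= half; ++z, ++idx) {
        double pz = z * voxel_um;
        out[idx] = (m00 * pz * pz + lin * pz + cyy) <= 1.0;
      }
    }
  }
  return out;
}

// (z,y,x) 1-based coordinates of surface voxels of a binary mask
// (any 6-neighbour outside the mask or outside the array).
// [[Rcpp::export]]
IntegerMatrix cpp_surface_coords(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> zs, ys, xs;
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!mask[idx]) continue;
    int z = (int)(idx % nz);
    R_xlen_t rest = idx / nz;
    int y = (int)(rest % ny);
    int x = (int)(rest / ny);
    bool surf =
      z == 0 || z == nz - 1 || y == 0 || y == ny - 1 ||
      x == 0 || x == nx - 1 ||
      !mask[idx - 1] || !mask[idx + 1] ||
      !mask[idx - nz] || !mask[idx + nz] ||
      !mask[idx - (R_xlen_t)nz * ny] || !mask[idx + (R_xlen_t)nz * ny];
    if (surf) { zs.push_back(z + 1); ys.push_back(y + 1); xs.push_back(x + 1); }
  }
  IntegerMatrix out(zs.size(), 3);
  for (size_t i = 0; i < zs.size(); ++i) {
    out(i, 0) = zs[i]; out(i, 1) = ys[i]; out(i, 2) = xs[i];
  }
  return out;
}
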