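// Texture-matrix accumulation for IBSI-style radiomic features.
// Images arrive as flattened integer grids of discretized gray levels
// (1..nbins inside the region, 0 outside). Grids are copied once into a
// sentinel-padded buffer and scanned through a foreground index list, so
// the inner loops carry no bounds checks. The same code serves 3D regions
// (13 directions, 26-connectivity) and 2D windows (4 directions,
// 8-connectivity) by choice of offset sets.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct PaddedGrid {
  std::vector<int> pad;     // (nx+2)(ny+2)(nz+2), 0 border
  std::vector<int> fg;      // padded flat indices of foreground voxels
  int px, py, pz;
  void build(const IntegerVector &bins, const IntegerVector &dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    px = nx + 2; py = ny + 2; pz = nz + 2;
    pad.assign((size_t)px * py * pz, 0);
    fg.clear();
    int i = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++i) {
          int v = bins[i];
          if (v > 0) {
            int j = (x + 1) + px * ((y + 1) + py * (z + 1));
            pad[j] = v;
            fg.push_back(j);
          }
        }
  }
  int off(int ox, int oy, int oz) const { return ox + px * (oy + py * oz); }
};

static NumericMatrix glcm_from(const PaddedGrid &g, int nbins,
                               const IntegerMatrix &dirs) {
  int nd = dirs.nrow();
  NumericMatrix out(nbins, nbins);
  double *m = out.begin();
  for (int d = 0; d < nd; ++d) {
    int off = g.off(dirs(d, 0), dirs(d, 1), dirs(d, 2));
    for (size_t t = 0; t < g.fg.size(); ++t) {
      int a = g.pad[g.fg[t]];
      int b = g.pad[g.fg[t] + off];
      if (b > 0) {
        m[(a - 1) + nbins * (b - 1)] += 1.0;
        m[(b - 1) + nbins * (a - 1)] += 1.0;
      }
    }
  }
  return out;
}

static NumericMatrix glrlm_from(const PaddedGrid &g, int nbins,
                                const IntegerMatrix &dirs,
                                const IntegerVector &dims) {
  int nd = dirs.nrow();
  int maxlen = std::max(dims[0], std::max(dims[1], dims[2]));
  NumericMatrix out(nbins, maxlen);
  for (int d = 0; d < nd; ++d) {
    int off = g.off(dirs(d, 0), dirs(d, 1), dirs(d, 2));
    for (size_t t = 0; t < g.fg.size(); ++t) {
      int j = g.fg[t];
      int a = g.pad[j];
      if (g.pad[j - off] == a) continue; // not a run start
      int len = 1;
      for (int k = j + off; g.pad[k] == a; k += off) ++len;
      if (len > maxlen) len = maxlen;
      out(a - 1, len - 1) += 1.0;
    }
  }
  return out;
}

// Connected components of equal-valued voxels (value 0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector vals, IntegerVector dims,
                                   IntegerMatrix offs) {
  PaddedGrid g; g.build(vals, dims);
  int no = offs.nrow();
  std::vector<int> off(no);
  for (int o = 0; o < no; ++o) off[o] = g.off(offs(o, 0), offs(o, 1), offs(o, 2));
  std::vector<int> lab(g.pad.size(), 0);
  int cur = 0;
  std::vector<int> stack;
  for (size_t t = 0; t < g.fg.size(); ++t) {
    int j = g.fg[t];
    if (lab[j] != 0) continue;
    int v = g.pad[j];
    lab[j] = ++cur;
    stack.clear();
    stack.push_back(j);
    while (!stack.empty()) {
      int q = stack.back(); stack.pop_back();
      for (int o = 0; o < no; ++o) {
        int k = q + off[o];
        if (g.pad[k] == v && lab[k] == 0) { lab[k] = cur; stack.push_back(k); }
      }
    }
  }
  // unpad
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector res((size_t)nx * ny * nz);
  int i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i)
        res[i] = lab[(x + 1) + g.px * ((y + 1) + g.py * (z + 1))];
  res.attr("dim") = dims;
  return res;
}

// Gray-level size-zone pairs: one row per zone (gray level, zone size),
// via flood fill on the padded grid.
static IntegerMatrix glszm_from(const PaddedGrid &g, const IntegerMatrix &offs) {
  int no = offs.nrow();
  std::vector<int> off(no);
  for (int o = 0; o < no; ++o) off[o] = g.off(offs(o, 0), offs(o, 1), offs(o, 2));
  std::vector<int> lab(g.pad.size(), 0);
  std::vector<int> gray, size;
  std::vector<int> stack;
  int cur = 0;
  for (size_t t = 0; t < g.fg.size(); ++t) {
    int j = g.fg[t];
    if (lab[j] != 0) continue;
    int v = g.pad[j];
    lab[j] = ++cur;
    int sz = 0;
    stack.clear(); stack.push_back(j);
    while (!stack.empty()) {
      int q = stack.back(); stack.pop_back();
      ++sz;
      for (int o = 0; o < no; ++o) {
        int k = q + off[o];
        if (g.pad[k] == v && lab[k] == 0) { lab[k] = cur; stack.push_back(k); }
      }
    }
    gray.push_back(v); size.push_back(sz);
  }
  IntegerMatrix out(cur, 2);
  for (int z = 0; z < cur; ++z) { out(z, 0) = gray[z]; out(z, 1) = size[z]; }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector bins, IntegerVector dims,
                        IntegerMatrix offs) {
  PaddedGrid g; g.build(bins, dims);
  return glszm_from(g, offs);
}

// Dependence matrix: D(i, j+1) = #voxels with gray i and j neighbors whose
// gray level differs by at most alpha (neighbors outside the region ignored).
static NumericMatrix gldm_from(const PaddedGrid &g, int nbins,
                               const IntegerMatrix &offs, int alpha) {
  int no = offs.nrow();
  std::vector<int> off(no);
  for (int o = 0; o < no; ++o) off[o] = g.off(offs(o, 0), offs(o, 1), offs(o, 2));
  NumericMatrix out(nbins, no + 1);
  for (size_t t = 0; t < g.fg.size(); ++t) {
    int j = g.fg[t];
    int a = g.pad[j];
    int dep = 0;
    for (int o = 0; o < no; ++o) {
      int b = g.pad[j + off[o]];
      if (b > 0 && std::abs(a - b) <= alpha) ++dep;
    }
    out(a - 1, dep) += 1.0;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector bins, IntegerVector dims, int nbins,
                       IntegerMatrix offs, int alpha) {
  PaddedGrid g; g.build(bins, dims);
  return gldm_from(g, nbins, offs, alpha);
}

// Neighborhood gray-tone difference: per gray level i, n_i (voxel count) and
// s_i = sum over those voxels of |i - mean(in-region neighbors)|.
static NumericMatrix ngtdm_from(const PaddedGrid &g, int nbins,
                                const IntegerMatrix &offs) {
  int no = offs.nrow();
  std::vector<int> off(no);
  for (int o = 0; o < no; ++o) off[o] = g.off(offs(o, 0), offs(o, 1), offs(o, 2));
  NumericMatrix out(nbins, 2); // col 0: n_i, col 1: s_i
  for (size_t t = 0; t < g.fg.size(); ++t) {
    int j = g.fg[t];
    int a = g.pad[j];
    double sum = 0.0; int cnt = 0;
    for (int o = 0; o < no; ++o) {
      int b = g.pad[j + off[o]];
      if (b > 0) { sum += b; ++cnt; }
    }
    out(a - 1, 0) += 1.0;
    if (cnt > 0) out(a - 1, 1) += std::fabs(a - sum / cnt);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector bins, IntegerVector dims, int nbins,
                        IntegerMatrix offs) {
  PaddedGrid g; g.build(bins, dims);
  return ngtdm_from(g, nbins, offs);
}

// All five texture matrices from one shared padded grid / foreground scan.
// [[Rcpp::export]]
List cpp_texture_all(IntegerVector bins, IntegerVector dims, int nbins,
                     IntegerMatrix dirs, IntegerMatrix offs, int alpha) {
  PaddedGrid g; g.build(bins, dims);
  return List::create(
    _["glcm"] = glcm_from(g, nbins, dirs),
    _["glrlm"] = glrlm_from(g, nbins, dirs, dims),
    _["glszm"] = glszm_from(g, offs),
    _["gldm"] = gldm_from(g, nbins, offs, alpha),
    _["ngtdm"] = ngtdm_from(g, nbins, offs));
}

// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector bins, IntegerVector dims, int nbins,
                       IntegerMatrix dirs) {
  PaddedGrid g; g.build(bins, dims);
  return glcm_from(g, nbins, dirs);
}

// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector bins, IntegerVector dims, int nbins,
                        IntegerMatrix dirs) {
  PaddedGrid g; g.build(bins, dims);
  return glrlm_from(g, nbins, dirs, dims);
}

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Surface area from exposed voxel faces (physical units from spacing).
// [[Rcpp::export]]
double cpp_surface_area(IntegerVector mask, IntegerVector dims,
                        NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double axy = spacing[0] * spacing[1];
  double axz = spacing[0] * spacing[2];
  double ayz = spacing[1] * spacing[2];
  double area = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (mask[idx3(x, y, z, nx, ny)] <= 0) continue;
        if (x == 0 || mask[idx3(x - 1, y, z, nx, ny)] <= 0) area += ayz;
        if (x == nx - 1 || mask[idx3(x + 1, y, z, nx, ny)] <= 0) area += ayz;
        if (y == 0 || mask[idx3(x, y - 1, z, nx, ny)] <= 0) area += axz;
        if (y == ny - 1 || mask[idx3(x, y + 1, z, nx, ny)] <= 0) area += axz;
        if (z == 0 || mask[idx3(x, y, z - 1, nx, ny)] <= 0) area += axy;
        if (z == nz - 1 || mask[idx3(x, y, z + 1, nx, ny)] <= 0) area += axy;
      }
  return area;
}

// Maximum pairwise diameters over boundary voxel centers:
// [max3d, max within axial plane (shared z), coronal (shared y), sagittal (shared x)]
// [[Rcpp::export]]
NumericVector cpp_max_diameters(NumericMatrix pts) {
  int n = pts.nrow();
  const double *X = pts.begin(), *Y = X + n, *Z = Y + n;
  double d3 = 0, dz = 0, dy = 0, dx = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double ux = X[i] - X[j];
      double uy = Y[i] - Y[j];
      double uz = Z[i] - Z[j];
      double d = ux * ux + uy * uy + uz * uz;
      if (d > d3) d3 = d;
      if (Z[i] == Z[j] && ux * ux + uy * uy > dz) dz = ux * ux + uy * uy;
      if (Y[i] == Y[j] && ux * ux + uz * uz > dy) dy = ux * ux + uz * uz;
      if (X[i] == X[j] && uy * uy + uz * uz > dx) dx = uy * uy + uz * uz;
    }
  return NumericVector::create(std::sqrt(d3), std::sqrt(dz), std::sqrt(dy),
                               std::sqrt(dx));
}
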