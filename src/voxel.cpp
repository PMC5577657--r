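#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Volumes are R arrays in (z, y, x) order: linear index = z + nz*(y + ny*x),
// z fastest (column-major). All routines take the dim vector explicitly.

static inline R_xlen_t lin(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// neighbourhood offsets for a connectivity class (6 = faces, 18 = faces+edges,
// 26 = full 3x3x3 shell)
static void conn_offsets(int connectivity, std::vector<int> &dz,
                         std::vector<int> &dy, std::vector<int> &dx) {
  dz.clear(); dy.clear(); dx.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim, int steps,
                         int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> dz, dy, dx;
  conn_offsets(connectivity, dz, dy, dx);
  int k = (int)dz.size();
  LogicalVector cur = clone(mask);
  for (int s = 0; s < steps; ++s) {
    LogicalVector nxt = clone(cur);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          if (!cur[lin(z, y, x, nz, ny)]) continue;
          for (int i = 0; i < k; ++i) {
            int zz = z + dz[i], yy = y + dy[i], xx = x + dx[i];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            nxt[lin(zz, yy, xx, nz, ny)] = TRUE;
          }
        }
    cur = nxt;
  }
  cur.attr("dim") = dim;
  return cur;
}

// connected-component labelling; labels are 1..n in first-encounter order,
// background stays 0
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim,
                        int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> dz, dy, dx;
  conn_offsets(connectivity, dz, dy, dx);
  int k = (int)dz.size();
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t j = stack.back(); stack.pop_back();
      int z = (int)(j % nz);
      R_xlen_t r = j / nz;
      int y = (int)(r % ny), x = (int)(r / ny);
      for (int t = 0; t < k; ++t) {
        int zz = z + dz[t], yy = y + dy[t], xx = x + dx[t];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t jj = lin(zz, yy, xx, nz, ny);
        if (mask[jj] && !lab[jj]) { lab[jj] = next; stack.push_back(jj); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// 1-D squared-distance lower envelope (Felzenszwalb & Huttenlocher)
static void dt1d(std::vector<double> &f, int n) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1), d(n);
  int kk = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[kk]] == INF) { v[kk] = q; continue; }
    double s = ((f[q] + (double)q * q) - (f[v[kk]] + (double)v[kk] * v[kk])) /
               (2.0 * q - 2.0 * v[kk]);
    while (kk > 0 && s <= zb[kk]) {
      --kk;
      s = ((f[q] + (double)q * q) - (f[v[kk]] + (double)v[kk] * v[kk])) /
          (2.0 * q - 2.0 * v[kk]);
    }
    ++kk; v[kk] = q; zb[kk] = s; zb[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (zb[kk + 1] < q) ++kk;
    double dq = (double)q - v[kk];
    d[q] = dq * dq + f[v[kk]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// exact squared Euclidean distance of every voxel to the nearest TRUE voxel
// (Inf when the mask is empty)
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  const double INF = std::numeric_limits<double>::infinity();
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;
  std::vector<double> line;
  line.resize(std::max(nz, std::max(ny, nx)));
  for (int x = 0; x < nx; ++x)          // along z
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) line[z] = d[lin(z, y, x, nz, ny)];
      dt1d(line, nz);
      for (int z = 0; z < nz; ++z) d[lin(z, y, x, nz, ny)] = line[z];
    }
  for (int x = 0; x < nx; ++x)          // along y
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) line[y] = d[lin(z, y, x, nz, ny)];
      dt1d(line, ny);
      for (int y = 0; y < ny; ++y) d[lin(z, y, x, nz, ny)] = line[y];
    }
  for (int y = 0; y < ny; ++y)          // along x
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) line[x] = d[lin(z, y, x, nz, ny)];
      dt1d(line, nx);
      for (int x = 0; x < nx; ++x) d[lin(z, y, x, nz, ny)] = line[x];
    }
  d.attr("dim") = dim;
  return d;
}

// separable Gaussian blur with mirrored boundaries
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vol, IntegerVector dim,
                             double sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  if (sigma <= 0) { NumericVector out = clone(vol); out.attr("dim") = dim; return out; }
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (auto &w : ker) w /= s;
  NumericVector cur = clone(vol);
  auto mirror = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  for (int ax = 0; ax < 3; ++ax) {
    NumericVector nxt((R_xlen_t)nz * ny * nx);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          double acc = 0;
          for (int i = -r; i <= r; ++i) {
            int zz = z, yy = y, xx = x;
            if (ax == 0) zz = mirror(z + i, nz);
            else if (ax == 1) yy = mirror(y + i, ny);
            else xx = mirror(x + i, nx);
            acc += ker[i + r] * cur[lin(zz, yy, xx, nz, ny)];
          }
          nxt[lin(z, y, x, nz, ny)] = acc;
        }
    cur = nxt;
  }
  cur.attr("dim") = dim;
  return cur;
}

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                 u[0] * v[1] - u[1] * v[0]};
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

static inline void interp(const double p[3], const double q[3], double vp,
                          double vq, double level, double out[3]) {
  double t = (level - vp) / (vq - vp);
  for (int i = 0; i < 3; ++i) out[i] = p[i] + t * (q[i] - p[i]);
}

// iso-surface area (in voxel-unit^2) at `level` by marching tetrahedra:
// each grid cell splits into 6 tetrahedra around the main diagonal
// [[Rcpp::export]]
double cpp_mesh_area(NumericVector vol, IntegerVector dim, double level) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  // cube corner offsets (z,y,x); corner 0 at origin, corner 6 opposite
  static const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {{0,5,1,6},{0,1,2,6},{0,2,3,6},
                                 {0,3,7,6},{0,7,4,6},{0,4,5,6}};
  double area = 0.0;
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        double cv[8]; double cp[8][3];
        double vmin = 1e300, vmax = -1e300;
        for (int i = 0; i < 8; ++i) {
          cv[i] = vol[lin(z + co[i][0], y + co[i][1], x + co[i][2], nz, ny)];
          cp[i][0] = z + co[i][0]; cp[i][1] = y + co[i][1]; cp[i][2] = x + co[i][2];
          if (cv[i] < vmin) vmin = cv[i];
          if (cv[i] > vmax) vmax = cv[i];
        }
        if (vmin > level || vmax <= level) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int above[4], nab = 0, below[4], nbe = 0;
          for (int i = 0; i < 4; ++i) {
            if (cv[id[i]] > level) above[nab++] = id[i];
            else below[nbe++] = id[i];
          }
          if (nab == 0 || nab == 4) continue;
          if (nab == 1 || nab == 3) {
            int apex = (nab == 1) ? above[0] : below[0];
            int *base = (nab == 1) ? below : above;
            double p1[3], p2[3], p3[3];
            interp(cp[apex], cp[base[0]], cv[apex], cv[base[0]], level, p1);
            interp(cp[apex], cp[base[1]], cv[apex], cv[base[1]], level, p2);
            interp(cp[apex], cp[base[2]], cv[apex], cv[base[2]], level, p3);
            area += tri_area(p1, p2, p3);
          } else {  // 2 above, 2 below: quad split into two triangles
            double q1[3], q2[3], q3[3], q4[3];
            interp(cp[above[0]], cp[below[0]], cv[above[0]], cv[below[0]], level, q1);
            interp(cp[above[0]], cp[below[1]], cv[above[0]], cv[below[1]], level, q2);
            interp(cp[above[1]], cp[below[1]], cv[above[1]], cv[below[1]], level, q3);
            interp(cp[above[1]], cp[below[0]], cv[above[1]], cv[below[0]], level, q4);
            area += tri_area(q1, q2, q3) + tri_area(q1, q3, q4);
          }
        }
      }
  return area;
}
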