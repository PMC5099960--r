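// Exact Euclidean distance transform on a 3-D binary mask with anisotropic
// voxel spacing, via the separable lower-envelope (parabola) algorithm
// applied axis by axis to squared distances.  Distances are measured from
// each foreground voxel centre to the nearest background voxel centre, in
// mm; background voxels get 0.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform along a strided line with physical step
// s.  Parabolas at INF (no background reached yet in previous passes) are
// skipped; a line with no finite value stays INF.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s) {
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double sq = (double)q * s;
    double sep = 0.0;
    while (k >= 0) {
      double sv = (double)v[k] * s;
      sep = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2 * sq - 2 * sv);
      if (sep <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      ++k; v[k] = q; z[k] = sep; z[k + 1] = INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (z[j + 1] < sq) ++j;
    double sv = (double)v[j] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[j]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
      for (int xx = 0; xx < nx; ++xx) f[xx] = g[base + xx];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int xx = 0; xx < nx; ++xx) g[base + xx] = d[xx];
    }
  // pass along y (stride nx)
  for (int zz = 0; zz < nz; ++zz)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + xx;
      for (int yy = 0; yy < ny; ++yy) f[yy] = g[base + (R_xlen_t)yy * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int yy = 0; yy < ny; ++yy) g[base + (R_xlen_t)yy * nx] = d[yy];
    }
  // pass along z (stride nx*ny)
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      R_xlen_t base = (R_xlen_t)yy * nx + xx;
      for (int zz = 0; zz < nz; ++zz)
        f[zz] = g[base + (R_xlen_t)zz * nx * ny];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int zz = 0; zz < nz; ++zz)
        g[base + (R_xlen_t)zz * nx * ny] = d[zz];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] == INF) ? INF : std::sqrt(g[i]);
  return out;
}

// Trilinear interpolation of a double field at world-coordinate points.
// Points outside the grid are clamped to the border.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector field, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int np = pts.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double fx = (pts(i, 0) - origin[0]) / spacing[0];
    double fy = (pts(i, 1) - origin[1]) / spacing[1];
    double fz = (pts(i, 2) - origin[2]) / spacing[2];
    fx = std::min(std::max(fx, 0.0), (double)(nx - 1));
    fy = std::min(std::max(fy, 0.0), (double)(ny - 1));
    fz = std::min(std::max(fz, 0.0), (double)(nz - 1));
    int x0 = std::min((int)fx, nx - 2 < 0 ? 0 : nx - 2);
    int y0 = std::min((int)fy, ny - 2 < 0 ? 0 : ny - 2);
    int z0 = std::min((int)fz, nz - 2 < 0 ? 0 : nz - 2);
    double tx = fx - x0, ty = fy - y0, tz = fz - z0;
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          int xi = std::min(x0 + dx, nx - 1);
          int yi = std::min(y0 + dy, ny - 1);
          int zi = std::min(z0 + dz, nz - 1);
          double w = (dx ? tx : 1 - tx) * (dy ? ty : 1 - ty) *
                     (dz ? tz : 1 - tz);
          acc += w * field[(R_xlen_t)zi * nx * ny + (R_xlen_t)yi * nx + xi];
        }
    out[i] = acc;
  }
  return out;
}
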