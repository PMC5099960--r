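// Distance-ordered homotopic thinning of a 3-D binary volume to a
// one-voxel-wide 26-connected curve skeleton.
//
// Border foreground voxels are peeled in increasing order of their
// Euclidean distance transform (deepest last), removing only *simple*
// points -- voxels whose deletion preserves the topology of both the
// 26-connected foreground and the 6-connected background (the
// Bertrand/Malandain characterisation: exactly one 26-component of
// foreground in the 26-neighbourhood, and exactly one 6-component of
// background in the 18-neighbourhood that touches a face neighbour).
// Curve endpoints (voxels with at most one foreground 26-neighbour) are
// preserved so branch tips survive.  Processing order is deterministic
// (distance, then linear index).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>

using namespace Rcpp;

namespace {

struct QItem {
  double d;
  R_xlen_t idx;
  bool operator>(const QItem& o) const {
    if (d != o.d) return d > o.d;
    return idx > o.idx;
  }
};

// Neighbourhood extraction: nb[27] with index (dz+1)*9 + (dy+1)*3 + (dx+1);
// centre is 13; outside the array counts as background.
inline void neighbourhood(const std::vector<uint8_t>& fg, int nx, int ny,
                          int nz, int x, int y, int z, bool nb[27]) {
  int c = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++c) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[c] = (xx >= 0 && xx < nx && yy >= 0 && yy < ny &&
                 zz >= 0 && zz < nz)
          ? fg[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx] != 0
          : false;
      }
}

inline int n_fg_neighbours(const bool nb[27]) {
  int n = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++n;
  return n;
}

// number of 26-connected components of foreground within the 26-neighbourhood
int count_fg_components(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++comps;
    // BFS
    int stack[27]; int sp = 0;
    stack[sp++] = i; seen[i] = true;
    while (sp) {
      int cur = stack[--sp];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || seen[j] || !nb[j]) continue;
        int jx = j % 3, jy = (j / 3) % 3, jz = j / 9;
        if (std::abs(jx - cx) <= 1 && std::abs(jy - cy) <= 1 &&
            std::abs(jz - cz) <= 1) {
          seen[j] = true; stack[sp++] = j;
        }
      }
    }
  }
  return comps;
}

// number of 6-connected components of background within the
// 18-neighbourhood that contain at least one face neighbour
int count_bg_components(const bool nb[27]) {
  auto in18 = [](int i) {
    if (i == 13) return false;
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    return std::abs(x) + std::abs(y) + std::abs(z) <= 2;
  };
  auto isface = [](int i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    return std::abs(x) + std::abs(y) + std::abs(z) == 1;
  };
  bool seen[27] = {false};
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (!isface(s) || nb[s] || seen[s]) continue;  // seeds: background faces
    ++comps;
    int stack[27]; int sp = 0;
    stack[sp++] = s; seen[s] = true;
    while (sp) {
      int cur = stack[--sp];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int j = 0; j < 27; ++j) {
        if (seen[j] || nb[j] || !in18(j)) continue;
        int dx = std::abs(j % 3 - cx), dy = std::abs((j / 3) % 3 - cy),
            dz = std::abs(j / 9 - cz);
        if (dx + dy + dz == 1) { seen[j] = true; stack[sp++] = j; }
      }
    }
  }
  return comps;
}

inline bool is_simple(const bool nb[27]) {
  return count_fg_components(nb) == 1 && count_bg_components(nb) == 1;
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dim,
                       NumericVector spacing, NumericVector edt) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  std::vector<uint8_t> fg(n);
  for (R_xlen_t i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;

  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem>> pq;
  bool nb[27];
  auto coords = [&](R_xlen_t i, int& x, int& y, int& z) {
    x = (int)(i % nx); y = (int)((i / nx) % ny); z = (int)(i / ((R_xlen_t)nx * ny));
  };

  // seed with boundary foreground voxels (any background 26-neighbour)
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!fg[i]) continue;
    int x, y, z; coords(i, x, y, z);
    neighbourhood(fg, nx, ny, nz, x, y, z, nb);
    if (n_fg_neighbours(nb) < 26) pq.push({edt[i], i});
  }

  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    if (!fg[it.idx]) continue;
    int x, y, z; coords(it.idx, x, y, z);
    neighbourhood(fg, nx, ny, nz, x, y, z, nb);
    int nn = n_fg_neighbours(nb);
    if (nn <= 1) continue;          // curve endpoint: preserve
    if (nn == 26) continue;         // interior (no background contact yet)
    if (!is_simple(nb)) continue;   // would change topology
    fg[it.idx] = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
          if (fg[j]) pq.push({edt[j], j});
        }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] != 0;
  out.attr("dim") = dim;
  return out;
}
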