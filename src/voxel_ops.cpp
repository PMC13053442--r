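// Low-level voxel operations for capillary volume processing.
// Conventions: volumes are x-fastest arrays (nx, ny, nz), 0-based voxel
// (i,j,k) has its centre at world coordinate ((i+0.5)dx, (j+0.5)dy, (k+0.5)dz).
// All routines pad internally by one background voxel so that the array
// boundary behaves as background.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

namespace {

struct Pad {
  int nx, ny, nz;      // original dims
  int px, py, pz;      // padded dims
  std::vector<unsigned char> v;

  Pad(const IntegerVector& vol, const IntegerVector& dims) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    px = nx + 2; py = ny + 2; pz = nz + 2;
    v.assign((size_t)px * py * pz, 0);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const int* src = &vol[(size_t)k * nx * ny + (size_t)j * nx];
        unsigned char* dst = &v[idx(1, j + 1, k + 1)];
        for (int i = 0; i < nx; ++i) dst[i] = src[i] ? 1 : 0;
      }
  }
  inline size_t idx(int i, int j, int k) const {
    return (size_t)k * px * py + (size_t)j * px + i;
  }
  IntegerVector unpad() const {
    IntegerVector out((size_t)nx * ny * nz);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const unsigned char* src = &v[idx(1, j + 1, k + 1)];
        int* dst = &out[(size_t)k * nx * ny + (size_t)j * nx];
        for (int i = 0; i < nx; ++i) dst[i] = src[i];
      }
    return out;
  }
};

// 26-neighbourhood offsets for a padded array, plus the 6 face offsets first.
static void make_offsets(int px, int py, long off26[26], long off6[6]) {
  long step[3] = {1, px, (long)px * py};
  int n6 = 0, n26 = 0;
  long tmp[26];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        long o = dx * step[0] + dy * step[1] + dz * step[2];
        tmp[n26++] = o;
        if (std::abs(dx) + std::abs(dy) + std::abs(dz) == 1 && n6 < 6)
          off6[n6++] = o;
      }
  std::memcpy(off26, tmp, sizeof(tmp));
}

// ---- simple-point machinery (26-connected foreground, 6-connected background)

// Local 3x3x3 cell index: l = (dx+1) + 3(dy+1) + 9(dz+1); centre = 13.
struct LocalTables {
  // 26-adjacency among the 26 non-centre cells (condition 1)
  std::vector<int> adj26[27];
  // 6-adjacency among the 18-neighbourhood cells (condition 2)
  std::vector<int> adj6[27];
  bool in18[27];
  bool face[27];

  LocalTables() {
    int d[27][3];
    for (int l = 0; l < 27; ++l) {
      d[l][0] = l % 3 - 1; d[l][1] = (l / 3) % 3 - 1; d[l][2] = l / 9 - 1;
      int s = std::abs(d[l][0]) + std::abs(d[l][1]) + std::abs(d[l][2]);
      in18[l] = (s >= 1 && s <= 2);
      face[l] = (s == 1);
    }
    for (int a = 0; a < 27; ++a) {
      if (a == 13) continue;
      for (int b = 0; b < 27; ++b) {
        if (b == 13 || b == a) continue;
        int ddx = std::abs(d[a][0] - d[b][0]);
        int ddy = std::abs(d[a][1] - d[b][1]);
        int ddz = std::abs(d[a][2] - d[b][2]);
        if (ddx <= 1 && ddy <= 1 && ddz <= 1) adj26[a].push_back(b);
        if (in18[a] && in18[b] && ddx + ddy + ddz == 1) adj6[a].push_back(b);
      }
    }
  }
};

static const LocalTables LT;

// Gather the 27-cell neighbourhood of padded index c.
inline void gather(const std::vector<unsigned char>& v, size_t c,
                   long px, long pxy, unsigned char nb[27]) {
  int l = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++l)
        nb[l] = v[c + dx + dy * px + dz * pxy];
}

inline int count26(const unsigned char nb[27]) {
  int n = 0;
  for (int l = 0; l < 27; ++l) if (l != 13 && nb[l]) ++n;
  return n;
}

// Condition 1: exactly one 26-component of foreground in N26.
inline bool one_fg_component(const unsigned char nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0, stack[26], top;
  for (int l = 0; l < 27; ++l) {
    if (l == 13 || !nb[l] || seen[l]) continue;
    if (++ncomp > 1) return false;
    top = 0; stack[top++] = l; seen[l] = true;
    while (top) {
      int a = stack[--top];
      for (int b : LT.adj26[a])
        if (nb[b] && !seen[b]) { seen[b] = true; stack[top++] = b; }
    }
  }
  return ncomp == 1;
}

// Condition 2: exactly one 6-component of background in N18 touching a face.
inline bool one_bg_component(const unsigned char nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0, stack[18], top;
  for (int l = 0; l < 27; ++l) {
    if (!LT.face[l] || nb[l] || seen[l]) continue;   // seed only from faces
    if (++ncomp > 1) return false;
    top = 0; stack[top++] = l; seen[l] = true;
    while (top) {
      int a = stack[--top];
      for (int b : LT.adj6[a])
        if (!nb[b] && !seen[b]) { seen[b] = true; stack[top++] = b; }
    }
  }
  return ncomp == 1;
}

inline bool is_simple(const std::vector<unsigned char>& v, size_t c,
                      long px, long pxy) {
  unsigned char nb[27];
  gather(v, c, px, pxy, nb);
  return one_fg_component(nb) && one_bg_component(nb);
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_rasterise_tubes(NumericMatrix segs, IntegerVector dims,
                                  NumericVector vox, double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = vox[0], dy = vox[1], dz = vox[2];
  IntegerVector out((size_t)nx * ny * nz);
  const double r2 = radius * radius;
  for (int s = 0; s < segs.nrow(); ++s) {
    double p1[3] = {segs(s, 0), segs(s, 1), segs(s, 2)};
    double p2[3] = {segs(s, 3), segs(s, 4), segs(s, 5)};
    double u[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
    double len2 = u[0] * u[0] + u[1] * u[1] + u[2] * u[2];
    double d3[3] = {dx, dy, dz};
    int lo[3], hi[3], n3[3] = {nx, ny, nz};
    for (int a = 0; a < 3; ++a) {
      double mn = std::min(p1[a], p2[a]) - radius;
      double mx = std::max(p1[a], p2[a]) + radius;
      lo[a] = std::max(0, (int)std::floor(mn / d3[a] - 0.5));
      hi[a] = std::min(n3[a] - 1, (int)std::ceil(mx / d3[a] - 0.5));
    }
    for (int k = lo[2]; k <= hi[2]; ++k) {
      double cz = (k + 0.5) * dz;
      for (int j = lo[1]; j <= hi[1]; ++j) {
        double cy = (j + 0.5) * dy;
        for (int i = lo[0]; i <= hi[0]; ++i) {
          double cx = (i + 0.5) * dx;
          double w[3] = {cx - p1[0], cy - p1[1], cz - p1[2]};
          double t = 0.0;
          if (len2 > 0) {
            t = (w[0] * u[0] + w[1] * u[1] + w[2] * u[2]) / len2;
            t = std::max(0.0, std::min(1.0, t));
          }
          double ex = w[0] - t * u[0], ey = w[1] - t * u[1], ez = w[2] - t * u[2];
          if (ex * ex + ey * ey + ez * ez <= r2)
            out[(size_t)k * nx * ny + (size_t)j * nx + i] = 1;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_label_components(IntegerVector vol, IntegerVector dims,
                          int connectivity) {
  Pad p(vol, dims);
  long off26[26], off6[6];
  make_offsets(p.px, p.py, off26, off6);
  const long* off = (connectivity == 6) ? off6 : off26;
  const int noff = (connectivity == 6) ? 6 : 26;

  std::vector<int> lab(p.v.size(), 0);
  std::vector<size_t> stack;
  int ncomp = 0;
  std::vector<double> sizes;
  for (size_t c = 0; c < p.v.size(); ++c) {
    if (!p.v[c] || lab[c]) continue;
    ++ncomp;
    double sz = 0;
    stack.clear(); stack.push_back(c); lab[c] = ncomp;
    while (!stack.empty()) {
      size_t a = stack.back(); stack.pop_back();
      ++sz;
      for (int o = 0; o < noff; ++o) {
        size_t b = a + off[o];
        if (p.v[b] && !lab[b]) { lab[b] = ncomp; stack.push_back(b); }
      }
    }
    sizes.push_back(sz);
  }
  IntegerVector labels((size_t)p.nx * p.ny * p.nz);
  for (int k = 0; k < p.nz; ++k)
    for (int j = 0; j < p.ny; ++j) {
      const int* src = &lab[p.idx(1, j + 1, k + 1)];
      int* dst = &labels[(size_t)k * p.nx * p.ny + (size_t)j * p.nx];
      for (int i = 0; i < p.nx; ++i) dst[i] = src[i];
    }
  return List::create(_["labels"] = labels, _["n"] = ncomp,
                      _["sizes"] = wrap(sizes));
}

// Morphological closing with the radius-1 Euclidean ball (6-cross + centre).
// [[Rcpp::export]]
IntegerVector cpp_closing_ball1(IntegerVector vol, IntegerVector dims) {
  Pad p(vol, dims);
  long off26[26], off6[6];
  make_offsets(p.px, p.py, off26, off6);
  std::vector<unsigned char> dil(p.v.size(), 0);
  // dilation (skip outermost pad layer so we never write out of bounds)
  for (int k = 1; k <= p.nz; ++k)
    for (int j = 1; j <= p.ny; ++j)
      for (int i = 1; i <= p.nx; ++i) {
        size_t c = p.idx(i, j, k);
        if (!p.v[c]) continue;
        dil[c] = 1;
        for (int o = 0; o < 6; ++o) dil[c + off6[o]] = 1;
      }
  // clear pad layer: erosion treats outside as background, but dilation may
  // have spilled into the pad; that spill must not survive (image boundary
  // is background, yet closing should not erode objects touching the edge).
  // We emulate closing on an image extended by replication: a dilated pad
  // voxel is kept for the erosion test only.
  std::vector<unsigned char> out(p.v.size(), 0);
  for (int k = 1; k <= p.nz; ++k)
    for (int j = 1; j <= p.ny; ++j)
      for (int i = 1; i <= p.nx; ++i) {
        size_t c = p.idx(i, j, k);
        if (!dil[c]) continue;
        bool keep = true;
        for (int o = 0; o < 6 && keep; ++o)
          if (!dil[c + off6[o]]) keep = false;
        if (keep) out[c] = 1;
      }
  p.v = out;
  return p.unpad();
}

// Topology-preserving curve thinning: six directional subiterations
// (U, D, N, S, E, W); within each subiteration, border points that are
// simple and not curve endpoints are deleted sequentially (simplicity
// re-checked at deletion time), which preserves digital topology in the
// (26, 6) adjacency pair. Curve endpoints (exactly one 26-neighbour) are
// retained, yielding a unit-width curve skeleton.
// [[Rcpp::export]]
IntegerVector cpp_thin3d(IntegerVector vol, IntegerVector dims) {
  Pad p(vol, dims);
  long off26[26], off6[6];
  make_offsets(p.px, p.py, off26, off6);
  const long pxl = p.px, pxyl = (long)p.px * p.py;

  std::vector<size_t> fg;
  fg.reserve(1 << 16);
  for (size_t c = 0; c < p.v.size(); ++c) if (p.v[c]) fg.push_back(c);

  std::vector<size_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      long bd = off6[d];
      cand.clear();
      for (size_t c : fg) {
        if (!p.v[c] || p.v[c + bd]) continue;      // border in direction d
        unsigned char nb[27];
        gather(p.v, c, pxl, pxyl, nb);
        int n = count26(nb);
        if (n <= 1) continue;                      // endpoint or isolated
        if (one_fg_component(nb) && one_bg_component(nb)) cand.push_back(c);
      }
      for (size_t c : cand) {                      // sequential re-check
        if (!p.v[c] || p.v[c + bd]) continue;
        unsigned char nb[27];
        gather(p.v, c, pxl, pxyl, nb);
        int n = count26(nb);
        if (n <= 1) continue;
        if (one_fg_component(nb) && one_bg_component(nb)) {
          p.v[c] = 0;
          changed = true;
        }
      }
    }
    if (changed) {
      size_t w = 0;
      for (size_t r = 0; r < fg.size(); ++r)
        if (p.v[fg[r]]) fg[w++] = fg[r];
      fg.resize(w);
    }
  }
  return p.unpad();
}
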