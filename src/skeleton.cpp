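#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sequential 3D thinning to a curve skeleton. A voxel may be deleted iff it
// is "simple" in the (26, 6) sense of Bertrand & Malandain (1994):
//   (a) exactly one 26-connected component of object voxels in the 26
//       neighbourhood, and
//   (b) exactly one 6-connected component of background voxels in the 18
//       neighbourhood that is 6-adjacent to the centre.
// Deleting a simple point preserves topology. Border voxels are removed in
// ascending order of a priority field (distance to background), so erosion
// proceeds from the outside in and the surviving curve is approximately
// centred. Endpoints (<= 1 object neighbour) are never removed, preserving
// segment extremities.

static const int DX[26] = {-1,0,1,-1,0,1,-1,0,1, -1,0,1,-1,1,-1,0,1, -1,0,1,-1,0,1,-1,0,1};
static const int DY[26] = {-1,-1,-1,0,0,0,1,1,1, -1,-1,-1,0,0,1,1,1, -1,-1,-1,0,0,0,1,1,1};
static const int DZ[26] = {-1,-1,-1,-1,-1,-1,-1,-1,-1, 0,0,0,0,0,0,0,0, 1,1,1,1,1,1,1,1,1};

struct Grid {
  std::vector<unsigned char> v;
  int nx, ny, nz;
  inline bool at(int x, int y, int z) const {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
    return v[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] != 0;
  }
  inline void set(int x, int y, int z, unsigned char val) {
    v[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] = val;
  }
};

// local 3x3x3 cube, index (dx+1) + 3*(dy+1) + 9*(dz+1); centre = 13
static void fill_cube(const Grid& g, int x, int y, int z, bool cube[27]) {
  int idx = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        cube[idx++] = g.at(x + dx, y + dy, z + dz);
}

static inline int cx(int i) { return i % 3 - 1; }
static inline int cy(int i) { return (i / 3) % 3 - 1; }
static inline int cz(int i) { return i / 9 - 1; }

// number of 26-components of object voxels among the 26 neighbours
static int count_object_components(const bool cube[27]) {
  int label[27];
  for (int i = 0; i < 27; ++i) label[i] = 0;
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !cube[s] || label[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    label[s] = ncomp;
    while (top) {
      const int c = stack[--top];
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || t == c || !cube[t] || label[t]) continue;
        if (std::abs(cx(t) - cx(c)) <= 1 && std::abs(cy(t) - cy(c)) <= 1 &&
            std::abs(cz(t) - cz(c)) <= 1) {
          label[t] = ncomp;
          stack[top++] = t;
        }
      }
    }
  }
  return ncomp;
}

// number of 6-components of background voxels within the 18-neighbourhood
// that touch a face neighbour of the centre
static int count_background_components(const bool cube[27]) {
  int label[27];
  for (int i = 0; i < 27; ++i) label[i] = 0;
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || cube[s] || label[s]) continue;
    const int ax = std::abs(cx(s)), ay = std::abs(cy(s)), az = std::abs(cz(s));
    if (ax + ay + az != 1) continue;  // seed only from face neighbours
    if (label[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    label[s] = ncomp;
    while (top) {
      const int c = stack[--top];
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || cube[t] || label[t]) continue;
        const int bx = std::abs(cx(t)), by = std::abs(cy(t)), bz = std::abs(cz(t));
        if (bx + by + bz > 2) continue;  // restrict to 18-neighbourhood
        if (std::abs(cx(t) - cx(c)) + std::abs(cy(t) - cy(c)) +
            std::abs(cz(t) - cz(c)) == 1) {
          label[t] = ncomp;
          stack[top++] = t;
        }
      }
    }
  }
  return ncomp;
}

static bool is_simple(const Grid& g, int x, int y, int z) {
  bool cube[27];
  fill_cube(g, x, y, z, cube);
  if (count_object_components(cube) != 1) return false;
  if (count_background_components(cube) != 1) return false;
  return true;
}

static bool is_border(const Grid& g, int x, int y, int z) {
  return !g.at(x - 1, y, z) || !g.at(x + 1, y, z) || !g.at(x, y - 1, z) ||
         !g.at(x, y + 1, z) || !g.at(x, y, z - 1) || !g.at(x, y, z + 1);
}

static int n_object_neighbours(const Grid& g, int x, int y, int z) {
  int n = 0;
  for (int i = 0; i < 26; ++i)
    if (g.at(x + DX[i], y + DY[i], z + DZ[i])) ++n;
  return n;
}

// [[Rcpp::export(name = ".skeletonize3d_cpp")]]
LogicalVector skeletonize3d_cpp(LogicalVector mask, IntegerVector dims,
                                NumericVector priority) {
  Grid g;
  g.nx = dims[0];
  g.ny = dims[1];
  g.nz = dims[2];
  const size_t n = (size_t)g.nx * g.ny * g.nz;
  g.v.assign(n, 0);
  for (size_t i = 0; i < n; ++i) g.v[i] = mask[i] ? 1 : 0;

  struct Cand { double pr; int x, y, z; };
  bool changed = true;
  while (changed) {
    changed = false;
    std::vector<Cand> cands;
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y)
        for (int x = 0; x < g.nx; ++x) {
          if (!g.at(x, y, z)) continue;
          if (!is_border(g, x, y, z)) continue;
          const size_t idx = (size_t)x + (size_t)g.nx * (y + (size_t)g.ny * z);
          cands.push_back({priority[idx], x, y, z});
        }
    std::stable_sort(cands.begin(), cands.end(),
                     [](const Cand& a, const Cand& b) { return a.pr < b.pr; });
    for (const Cand& c : cands) {
      if (!g.at(c.x, c.y, c.z)) continue;
      const int nn = n_object_neighbours(g, c.x, c.y, c.z);
      if (nn <= 1) continue;  // endpoint or isolated voxel
      if (!is_simple(g, c.x, c.y, c.z)) continue;
      g.set(c.x, c.y, c.z, 0);
      changed = true;
    }
  }

  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = g.v[i] != 0;
  out.attr("dim") = dims;
  return out;
}
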