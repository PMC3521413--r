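#include <Rcpp.h>
#include <map>
#include <array>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D Delaunay tessellation by incremental Bowyer-Watson insertion.
// Brute-force cavity search (scan all live tetrahedra per insertion); fine
// for the point counts seen on single antigen surfaces (<= a few thousand).

namespace {

struct Tet {
  int v[4];
  bool alive;
};

typedef std::vector<std::array<double,3> > Pts;

inline double orient3d(const Pts &p, int a, int b, int c, int d) {
  double ax = p[b][0]-p[a][0], ay = p[b][1]-p[a][1], az = p[b][2]-p[a][2];
  double bx = p[c][0]-p[a][0], by = p[c][1]-p[a][1], bz = p[c][2]-p[a][2];
  double cx = p[d][0]-p[a][0], cy = p[d][1]-p[a][1], cz = p[d][2]-p[a][2];
  return ax*(by*cz-bz*cy) - ay*(bx*cz-bz*cx) + az*(bx*cy-by*cx);
}

// < 0 when e lies strictly inside the circumsphere of a positively
// oriented tetrahedron (a,b,c,d)
inline double insphere(const Pts &p, int a, int b, int c, int d, int e) {
  double m[4][4];
  int idx[4] = {a, b, c, d};
  for (int i = 0; i < 4; ++i) {
    double dx = p[idx[i]][0]-p[e][0];
    double dy = p[idx[i]][1]-p[e][1];
    double dz = p[idx[i]][2]-p[e][2];
    m[i][0] = dx; m[i][1] = dy; m[i][2] = dz;
    m[i][3] = dx*dx + dy*dy + dz*dz;
  }
  double det = 0.0;
  for (int col = 0; col < 4; ++col) {
    double sub[3][3];
    for (int r = 1; r < 4; ++r) {
      int cc = 0;
      for (int c2 = 0; c2 < 4; ++c2) {
        if (c2 == col) continue;
        sub[r-1][cc++] = m[r][c2];
      }
    }
    double d3 = sub[0][0]*(sub[1][1]*sub[2][2]-sub[1][2]*sub[2][1])
              - sub[0][1]*(sub[1][0]*sub[2][2]-sub[1][2]*sub[2][0])
              + sub[0][2]*(sub[1][0]*sub[2][1]-sub[1][1]*sub[2][0]);
    det += ((col % 2 == 0) ? 1.0 : -1.0) * m[0][col] * d3;
  }
  return det;
}

struct FaceKey {
  int a, b, c;
  FaceKey(int x, int y, int z) {
    int v[3] = {x, y, z};
    if (v[0] > v[1]) std::swap(v[0], v[1]);
    if (v[1] > v[2]) std::swap(v[1], v[2]);
    if (v[0] > v[1]) std::swap(v[0], v[1]);
    a = v[0]; b = v[1]; c = v[2];
  }
  bool operator<(const FaceKey &o) const {
    if (a != o.a) return a < o.a;
    if (b != o.b) return b < o.b;
    return c < o.c;
  }
};

} // namespace

// [[Rcpp::export(name = ".delaunay_edges_cpp")]]
IntegerMatrix delaunay_edges_cpp(NumericMatrix coords) {
  const int n = coords.nrow();
  if (n < 4) stop("Delaunay tessellation needs at least 4 points");

  Pts p(n + 4);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      p[i][k] = coords(i, k);
      if (p[i][k] < lo[k]) lo[k] = p[i][k];
      if (p[i][k] > hi[k]) hi[k] = p[i][k];
    }
  }
  double span = 1.0;
  double ctr[3];
  for (int k = 0; k < 3; ++k) {
    double s = hi[k] - lo[k];
    if (s > span) span = s;
    ctr[k] = 0.5 * (hi[k] + lo[k]);
  }
  // enclosing super-tetrahedron, generously sized
  double L = 100.0 * span;
  int s0 = n, s1 = n + 1, s2 = n + 2, s3 = n + 3;
  p[s0][0] = ctr[0] - L;     p[s0][1] = ctr[1] - L;     p[s0][2] = ctr[2] - L;
  p[s1][0] = ctr[0] + 3 * L; p[s1][1] = ctr[1] - L;     p[s1][2] = ctr[2] - L;
  p[s2][0] = ctr[0];         p[s2][1] = ctr[1] + 3 * L; p[s2][2] = ctr[2] - L;
  p[s3][0] = ctr[0];         p[s3][1] = ctr[1];         p[s3][2] = ctr[2] + 3 * L;

  std::vector<Tet> tets;
  {
    Tet t;
    t.v[0] = s0; t.v[1] = s1; t.v[2] = s2; t.v[3] = s3;
    t.alive = true;
    if (orient3d(p, t.v[0], t.v[1], t.v[2], t.v[3]) < 0) std::swap(t.v[2], t.v[3]);
    tets.push_back(t);
  }

  for (int ip = 0; ip < n; ++ip) {
    std::vector<int> bad;
    for (size_t it = 0; it < tets.size(); ++it) {
      if (!tets[it].alive) continue;
      const Tet &t = tets[it];
      if (insphere(p, t.v[0], t.v[1], t.v[2], t.v[3], ip) < 0.0)
        bad.push_back((int)it);
    }
    if (bad.empty())
      stop("Delaunay insertion failed (degenerate or duplicated input)");

    std::map<FaceKey, std::pair<int,int> > faces; // count, opposite vertex order kept via first-seen
    static const int fidx[4][3] = {{1,2,3},{0,3,2},{0,1,3},{0,2,1}};
    for (size_t b = 0; b < bad.size(); ++b) {
      const Tet &t = tets[bad[b]];
      for (int f = 0; f < 4; ++f) {
        FaceKey key(t.v[fidx[f][0]], t.v[fidx[f][1]], t.v[fidx[f][2]]);
        std::map<FaceKey, std::pair<int,int> >::iterator it = faces.find(key);
        if (it == faces.end()) faces[key] = std::make_pair(1, 0);
        else it->second.first += 1;
      }
      tets[bad[b]].alive = false;
    }
    for (std::map<FaceKey, std::pair<int,int> >::iterator it = faces.begin();
         it != faces.end(); ++it) {
      if (it->second.first != 1) continue; // interior face of the cavity
      Tet nt;
      nt.v[0] = it->first.a; nt.v[1] = it->first.b; nt.v[2] = it->first.c;
      nt.v[3] = ip;
      double o = orient3d(p, nt.v[0], nt.v[1], nt.v[2], nt.v[3]);
      if (o == 0.0)
        stop("Delaunay insertion produced a degenerate cell");
      if (o < 0) std::swap(nt.v[0], nt.v[1]);
      nt.alive = true;
      tets.push_back(nt);
    }
    // periodically compact the tetrahedron list
    if (tets.size() > 8 * (size_t)(n + 4)) {
      std::vector<Tet> keep;
      keep.reserve(tets.size() / 2);
      for (size_t it = 0; it < tets.size(); ++it)
        if (tets[it].alive) keep.push_back(tets[it]);
      tets.swap(keep);
    }
  }

  std::map<std::pair<int,int>, bool> edges;
  bool any = false;
  for (size_t it = 0; it < tets.size(); ++it) {
    if (!tets[it].alive) continue;
    const Tet &t = tets[it];
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    any = true;
    for (int a = 0; a < 4; ++a)
      for (int b = a + 1; b < 4; ++b) {
        int u = t.v[a], v = t.v[b];
        if (u > v) std::swap(u, v);
        edges[std::make_pair(u, v)] = true;
      }
  }
  if (!any)
    stop("Delaunay tessellation is degenerate (points coplanar or collinear)");

  IntegerMatrix out((int)edges.size(), 2);
  int row = 0;
  for (std::map<std::pair<int,int>, bool>::iterator it = edges.begin();
       it != edges.end(); ++it, ++row) {
    out(row, 0) = it->first.first + 1;  // 1-based for R
    out(row, 1) = it->first.second + 1;
  }
  return out;
}
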