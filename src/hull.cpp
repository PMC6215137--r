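#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Incremental 3D convex hull for points in general position (all hull
// vertices, as for lattice points on a sphere). O(n * F) visibility scans;
// fine for the mesh sizes used here (<= a few thousand nodes).

namespace {

struct Face {
  int a, b, c;      // vertex indices, counter-clockwise seen from outside
  double nx, ny, nz; // outward normal (not normalised)
  double off;        // plane offset: n . x = off on the face plane
  bool alive;
};

inline void face_plane(const std::vector<double> &px,
                       const std::vector<double> &py,
                       const std::vector<double> &pz, Face &f) {
  double ux = px[f.b] - px[f.a], uy = py[f.b] - py[f.a], uz = pz[f.b] - pz[f.a];
  double vx = px[f.c] - px[f.a], vy = py[f.c] - py[f.a], vz = pz[f.c] - pz[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * px[f.a] + f.ny * py[f.a] + f.nz * pz[f.a];
}

} // namespace

// [[Rcpp::export(name = ".convex_hull3d")]]
IntegerMatrix convex_hull3d(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3D hull");
  std::vector<double> px(n), py(n), pz(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
    scale = std::max(scale, std::fabs(px[i]) + std::fabs(py[i]) + std::fabs(pz[i]));
  }
  const double eps = 1e-10 * std::max(scale, 1.0) * std::max(scale, 1.0);

  // initial simplex: farthest pair, then farthest from line, then from plane
  int i0 = 0, i1 = 1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d = (px[i] - px[0]) * (px[i] - px[0]) +
               (py[i] - py[0]) * (py[i] - py[0]) +
               (pz[i] - pz[0]) * (pz[i] - pz[0]);
    if (d > best) { best = d; i1 = i; }
  }
  int i2 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double ax = px[i1] - px[i0], ay = py[i1] - py[i0], az = pz[i1] - pz[i0];
    double bx = px[i] - px[i0], by = py[i] - py[i0], bz = pz[i] - pz[i0];
    double cx = ay * bz - az * by, cy = az * bx - ax * bz, cz = ax * by - ay * bx;
    double d = cx * cx + cy * cy + cz * cz;
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0 || best < eps * eps) stop("degenerate point set (collinear)");
  Face base{i0, i1, i2, 0, 0, 0, 0, true};
  face_plane(px, py, pz, base);
  int i3 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double d = std::fabs(base.nx * px[i] + base.ny * py[i] + base.nz * pz[i] - base.off);
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate point set (coplanar)");

  std::vector<Face> faces;
  faces.reserve(4 * n);
  {
    // orient the 4 starting faces outward w.r.t. the simplex centroid
    double gx = (px[i0] + px[i1] + px[i2] + px[i3]) / 4.0;
    double gy = (py[i0] + py[i1] + py[i2] + py[i3]) / 4.0;
    double gz = (pz[i0] + pz[i1] + pz[i2] + pz[i3]) / 4.0;
    int tris[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
    for (int t = 0; t < 4; ++t) {
      Face f{tris[t][0], tris[t][1], tris[t][2], 0, 0, 0, 0, true};
      face_plane(px, py, pz, f);
      if (f.nx * gx + f.ny * gy + f.nz * gz - f.off > 0) {
        std::swap(f.b, f.c);
        face_plane(px, py, pz, f);
      }
      faces.push_back(f);
    }
  }

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;

  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    // visible faces
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double d = faces[f].nx * px[p] + faces[f].ny * py[p] + faces[f].nz * pz[p] - faces[f].off;
      if (d > eps) vis.push_back((int)f);
    }
    if (vis.empty()) continue; // inside current hull (should not happen on a sphere)
    // horizon: directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int, int> > edges;
    for (int fv : vis) {
      const Face &f = faces[fv];
      edges.push_back(std::make_pair(f.a, f.b));
      edges.push_back(std::make_pair(f.b, f.c));
      edges.push_back(std::make_pair(f.c, f.a));
    }
    std::vector<std::pair<int, int> > horizon;
    for (size_t e = 0; e < edges.size(); ++e) {
      bool internal = false;
      for (size_t g = 0; g < edges.size(); ++g) {
        if (edges[g].first == edges[e].second && edges[g].second == edges[e].first) {
          internal = true; break;
        }
      }
      if (!internal) horizon.push_back(edges[e]);
    }
    for (int fv : vis) faces[fv].alive = false;
    for (size_t h = 0; h < horizon.size(); ++h) {
      // horizon edge (u,v) was CCW on a visible face; new face (u,v,p) is CCW
      Face f{horizon[h].first, horizon[h].second, p, 0, 0, 0, 0, true};
      face_plane(px, py, pz, f);
      faces.push_back(f);
    }
    used[p] = true;
  }

  int nf = 0;
  for (size_t f = 0; f < faces.size(); ++f) if (faces[f].alive) ++nf;
  IntegerMatrix out(nf, 3);
  int k = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    out(k, 0) = faces[f].a;
    out(k, 1) = faces[f].b;
    out(k, 2) = faces[f].c;
    ++k;
  }
  return out; // 0-based, outward-oriented
}
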