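#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Reduced-unit conventions: kT = 1 energy unit unless overridden; lengths in
// units of the mesh length scale; element order in all state arrays is
// [outer blobs | inner blobs | nanoparticles].

namespace mps {

struct Topology {
  std::vector<int> edge_i, edge_j;     // mesh springs, global indices
  std::vector<double> r0_edge;
  std::vector<int> tri_a, tri_b, tri_c;
  std::vector<double> S0;
  std::vector<int> teth_i, teth_j;     // outer<->inner tethers
  std::vector<double> r0_teth;
  int n_out, n_in, n_mnp;
  std::vector<std::vector<int> > excl; // bonded pairs excluded from WCA
  int n_blob() const { return n_out + n_in; }
  int n_total() const { return n_out + n_in + n_mnp; }
  void build_exclusions() {
    excl.assign(n_total(), std::vector<int>());
    for (size_t k = 0; k < edge_i.size(); ++k) {
      excl[edge_i[k]].push_back(edge_j[k]);
      excl[edge_j[k]].push_back(edge_i[k]);
    }
    for (size_t k = 0; k < teth_i.size(); ++k) {
      excl[teth_i[k]].push_back(teth_j[k]);
      excl[teth_j[k]].push_back(teth_i[k]);
    }
  }
  bool excluded(int i, int j) const {
    const std::vector<int> &e = excl[i];
    for (size_t k = 0; k < e.size(); ++k)
      if (e[k] == j) return true;
    return false;
  }
};

struct Params {
  double ks, kal, kh, eps, lambda, a_red;
  double xi;
  double h[3];                 // field direction (unit)
  double k_trap, trap_c[3];    // optional harmonic trap on nanoparticles
  std::vector<double> diam;    // per-element soft-sphere diameter
  bool magnetics;              // dipole + Zeeman switch
};

// xoshiro256++ noise stream for the thermostat. Seeded from R's RNG on
// first use and carried in the state object afterwards, so trajectories
// are reproducible through set.seed() and exactly restartable.
struct NoiseStream {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  void fill_norm(double *buf, int len) {
    for (int i = 0; i < len; i += 2) {
      double u1 = unif(), u2 = unif();
      double r = std::sqrt(-2.0 * std::log(u1)), th = 6.283185307179586 * u2;
      buf[i] = r * std::cos(th);
      if (i + 1 < len) buf[i + 1] = r * std::sin(th);
    }
  }
  void seed_from_r() {
    uint64_t x = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
                 (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  IntegerVector pack() const {
    IntegerVector v(8);
    for (int i = 0; i < 4; ++i) {
      v[2 * i] = (int32_t)(s[i] & 0xFFFFFFFFULL);
      v[2 * i + 1] = (int32_t)(s[i] >> 32);
    }
    return v;
  }
  void unpack(IntegerVector v) {
    for (int i = 0; i < 4; ++i)
      s[i] = ((uint64_t)(uint32_t)v[2 * i + 1] << 32) |
             (uint64_t)(uint32_t)v[2 * i];
  }
};

inline double g_neo(double x) {
  // neo-Hookean nonlinearity factor (x = r/r0)
  return (std::sqrt(x) + std::pow(x, -2.5)) / (x + 1.0 / (x * x * x));
}

// --- cell list over all elements, used for excluded-volume pairs ----------

struct CellList {
  double x0, y0, z0, h;
  int nx, ny, nz;
  std::vector<int> head, nxt;
  void build(const std::vector<double> &p, int n, double cell) {
    h = cell;
    double xmax, ymax, zmax;
    x0 = xmax = p[0]; y0 = ymax = p[1]; z0 = zmax = p[2];
    for (int i = 1; i < n; ++i) {
      x0 = std::min(x0, p[3 * i]);     xmax = std::max(xmax, p[3 * i]);
      y0 = std::min(y0, p[3 * i + 1]); ymax = std::max(ymax, p[3 * i + 1]);
      z0 = std::min(z0, p[3 * i + 2]); zmax = std::max(zmax, p[3 * i + 2]);
    }
    nx = std::max(1, (int)((xmax - x0) / h) + 1);
    ny = std::max(1, (int)((ymax - y0) / h) + 1);
    nz = std::max(1, (int)((zmax - z0) / h) + 1);
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(p[3 * i], p[3 * i + 1], p[3 * i + 2]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  int cell_of(double x, double y, double z) const {
    int cx = std::min(nx - 1, std::max(0, (int)((x - x0) / h)));
    int cy = std::min(ny - 1, std::max(0, (int)((y - y0) / h)));
    int cz = std::min(nz - 1, std::max(0, (int)((z - z0) / h)));
    return (cz * ny + cy) * nx + cx;
  }
};

// --- forces ---------------------------------------------------------------

// fills f (3N) and tq (3M); returns nothing. e may be empty when n_mnp == 0.
inline void compute_forces(const std::vector<double> &p,
                           const std::vector<double> &e,
                           const Topology &T, const Params &P,
                           std::vector<double> &f, std::vector<double> &tq,
                           CellList &cl) {
  const int N = T.n_total(), M = T.n_mnp, nb = T.n_blob();
  std::fill(f.begin(), f.end(), 0.0);
  std::fill(tq.begin(), tq.end(), 0.0);

  // neo-Hookean mesh springs
  for (size_t k = 0; k < T.edge_i.size(); ++k) {
    int i = T.edge_i[k], j = T.edge_j[k];
    double dx = p[3 * j] - p[3 * i], dy = p[3 * j + 1] - p[3 * i + 1],
           dz = p[3 * j + 2] - p[3 * i + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double r0 = T.r0_edge[k];
    double x = r / r0;
    double fmag = P.ks * g_neo(x) * (r - r0) / r0; // >0 => attraction
    double s = fmag / r;
    f[3 * i] += s * dx; f[3 * i + 1] += s * dy; f[3 * i + 2] += s * dz;
    f[3 * j] -= s * dx; f[3 * j + 1] -= s * dy; f[3 * j + 2] -= s * dz;
  }

  // local-area constraint: -kal (S - S0)/S along centroid->vertex
  for (size_t k = 0; k < T.tri_a.size(); ++k) {
    int a = T.tri_a[k], b = T.tri_b[k], c = T.tri_c[k];
    double ux = p[3 * b] - p[3 * a], uy = p[3 * b + 1] - p[3 * a + 1],
           uz = p[3 * b + 2] - p[3 * a + 2];
    double vx = p[3 * c] - p[3 * a], vy = p[3 * c + 1] - p[3 * a + 1],
           vz = p[3 * c + 2] - p[3 * a + 2];
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    double S = 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
    double gx = (p[3 * a] + p[3 * b] + p[3 * c]) / 3.0;
    double gy = (p[3 * a + 1] + p[3 * b + 1] + p[3 * c + 1]) / 3.0;
    double gz = (p[3 * a + 2] + p[3 * b + 2] + p[3 * c + 2]) / 3.0;
    double coef = -P.kal * (S - T.S0[k]) / S;
    int vidx[3] = {a, b, c};
    for (int v = 0; v < 3; ++v) {
      int i = vidx[v];
      double wx = p[3 * i] - gx, wy = p[3 * i + 1] - gy, wz = p[3 * i + 2] - gz;
      double wn = std::sqrt(wx * wx + wy * wy + wz * wz);
      f[3 * i] += coef * wx / wn;
      f[3 * i + 1] += coef * wy / wn;
      f[3 * i + 2] += coef * wz / wn;
    }
  }

  // harmonic tethers between paired shell nodes
  for (size_t k = 0; k < T.teth_i.size(); ++k) {
    int i = T.teth_i[k], j = T.teth_j[k];
    double dx = p[3 * j] - p[3 * i], dy = p[3 * j + 1] - p[3 * i + 1],
           dz = p[3 * j + 2] - p[3 * i + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double s = P.kh * (r - T.r0_teth[k]) / r;
    f[3 * i] += s * dx; f[3 * i + 1] += s * dy; f[3 * i + 2] += s * dz;
    f[3 * j] -= s * dx; f[3 * j + 1] -= s * dy; f[3 * j + 2] -= s * dz;
  }

  // WCA excluded volume over all element pairs (blobs and nanoparticles),
  // except directly bonded pairs (mesh edges, tethers): overlapping blob
  // diameters tile each surface so nanoparticles cannot squeeze through,
  // and non-bonded blob-blob repulsion keeps the tensionless network from
  // crumpling and the two shells from interpenetrating.
  if (P.eps > 0 && N > 1) {
    double dmax = 0.0;
    for (int i = 0; i < N; ++i) dmax = std::max(dmax, P.diam[i]);
    cl.build(p, N, dmax);
    for (int m = 0; m < N; ++m) {
      int cx = (int)((p[3 * m] - cl.x0) / cl.h);
      int cy = (int)((p[3 * m + 1] - cl.y0) / cl.h);
      int cz = (int)((p[3 * m + 2] - cl.z0) / cl.h);
      for (int dz1 = -1; dz1 <= 1; ++dz1)
        for (int dy1 = -1; dy1 <= 1; ++dy1)
          for (int dx1 = -1; dx1 <= 1; ++dx1) {
            int ex = cx + dx1, ey = cy + dy1, ez = cz + dz1;
            if (ex < 0 || ey < 0 || ez < 0 || ex >= cl.nx || ey >= cl.ny || ez >= cl.nz)
              continue;
            int j = cl.head[(ez * cl.ny + ey) * cl.nx + ex];
            for (; j >= 0; j = cl.nxt[j]) {
              if (j <= m) continue; // each pair once
              double dx = p[3 * j] - p[3 * m], dy = p[3 * j + 1] - p[3 * m + 1],
                     dz = p[3 * j + 2] - p[3 * m + 2];
              double Rc = 0.5 * (P.diam[m] + P.diam[j]);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 >= Rc * Rc) continue;
              if (T.excluded(m, j)) continue;
              double sig6 = std::pow(Rc, 6) / 2.0; // sigma^6 = Rc^6 / 2
              double inv_r2 = 1.0 / r2;
              double sr6 = sig6 * inv_r2 * inv_r2 * inv_r2;
              double fmag_r = 24.0 * P.eps * (2.0 * sr6 * sr6 - sr6) * inv_r2;
              // repulsive: force on m points away from j
              f[3 * m] -= fmag_r * dx; f[3 * m + 1] -= fmag_r * dy; f[3 * m + 2] -= fmag_r * dz;
              f[3 * j] += fmag_r * dx; f[3 * j + 1] += fmag_r * dy; f[3 * j + 2] += fmag_r * dz;
            }
          }
    }
  }

  // magnetics: dipole-dipole (direct sum, single box) + Zeeman
  if (M > 0 && P.magnetics) {
    const double C = P.lambda * P.a_red * P.a_red * P.a_red;
    std::vector<double> b(3 * M, 0.0); // reduced field conjugate to e_i
    if (P.lambda > 0) {
      for (int mi = 0; mi < M; ++mi) {
        int i = nb + mi;
        for (int mj = mi + 1; mj < M; ++mj) {
          int j = nb + mj;
          double rx = p[3 * j] - p[3 * i], ry = p[3 * j + 1] - p[3 * i + 1],
                 rz = p[3 * j + 2] - p[3 * i + 2];
          double r2 = rx * rx + ry * ry + rz * rz;
          double r = std::sqrt(r2);
          double inv_r2 = 1.0 / r2, inv_r3 = inv_r2 / r, inv_r5 = inv_r3 * inv_r2;
          const double *ei = &e[3 * mi], *ej = &e[3 * mj];
          double eiej = ei[0] * ej[0] + ei[1] * ej[1] + ei[2] * ej[2];
          double eir = ei[0] * rx + ei[1] * ry + ei[2] * rz;
          double ejr = ej[0] * rx + ej[1] * ry + ej[2] * rz;
          // F_i = 3C r^-5 [ -(ei.ej) r - (ej.r) ei - (ei.r) ej + 5 (ei.r)(ej.r) r / r^2 ]
          double c5 = 3.0 * C * inv_r5;
          double rad = -eiej + 5.0 * eir * ejr * inv_r2;
          double fx = c5 * (rad * rx - ejr * ei[0] - eir * ej[0]);
          double fy = c5 * (rad * ry - ejr * ei[1] - eir * ej[1]);
          double fz = c5 * (rad * rz - ejr * ei[2] - eir * ej[2]);
          f[3 * i] += fx; f[3 * i + 1] += fy; f[3 * i + 2] += fz;
          f[3 * j] -= fx; f[3 * j + 1] -= fy; f[3 * j + 2] -= fz;
          // dipolar field: b_i += C r^-3 [ 3 (ej.r) r / r^2 - ej ]
          double bi = C * inv_r3, t_i = 3.0 * ejr * inv_r2, t_j = 3.0 * eir * inv_r2;
          b[3 * mi] += bi * (t_i * rx - ej[0]);
          b[3 * mi + 1] += bi * (t_i * ry - ej[1]);
          b[3 * mi + 2] += bi * (t_i * rz - ej[2]);
          // r_ji = -r, but (ei . rhat_ji) rhat_ji = (ei . rhat) rhat
          b[3 * mj] += bi * (t_j * rx - ei[0]);
          b[3 * mj + 1] += bi * (t_j * ry - ei[1]);
          b[3 * mj + 2] += bi * (t_j * rz - ei[2]);
        }
      }
    }
    for (int mi = 0; mi < M; ++mi) {
      b[3 * mi] += P.xi * P.h[0];
      b[3 * mi + 1] += P.xi * P.h[1];
      b[3 * mi + 2] += P.xi * P.h[2];
      // torque = e x b (rigid-dipole law conjugate to the energy)
      const double *ei = &e[3 * mi];
      tq[3 * mi] = ei[1] * b[3 * mi + 2] - ei[2] * b[3 * mi + 1];
      tq[3 * mi + 1] = ei[2] * b[3 * mi] - ei[0] * b[3 * mi + 2];
      tq[3 * mi + 2] = ei[0] * b[3 * mi + 1] - ei[1] * b[3 * mi];
    }
  }

  // optional harmonic trap on nanoparticles (calibration/testing aid)
  if (M > 0 && P.k_trap > 0) {
    for (int m = nb; m < N; ++m) {
      f[3 * m] -= P.k_trap * (p[3 * m] - P.trap_c[0]);
      f[3 * m + 1] -= P.k_trap * (p[3 * m + 1] - P.trap_c[1]);
      f[3 * m + 2] -= P.k_trap * (p[3 * m + 2] - P.trap_c[2]);
    }
  }
}

// --- energies (sampling path, not needed every step) ----------------------

// 16-point Gauss-Legendre nodes/weights on [-1, 1]
static const double GL_X[16] = {
  -0.9894009349916499, -0.9445750230732326, -0.8656312023878318,
  -0.7554044083550030, -0.6178762444026438, -0.4580167776572274,
  -0.2816035507792589, -0.0950125098376374, 0.0950125098376374,
  0.2816035507792589, 0.4580167776572274, 0.6178762444026438,
  0.7554044083550030, 0.8656312023878318, 0.9445750230732326,
  0.9894009349916499};
static const double GL_W[16] = {
  0.0271524594117541, 0.0622535239386479, 0.0951585116824928,
  0.1246289712555339, 0.1495959888165767, 0.1691565193950025,
  0.1826034150449236, 0.1894506104550685, 0.1894506104550685,
  0.1826034150449236, 0.1691565193950025, 0.1495959888165767,
  0.1246289712555339, 0.0951585116824928, 0.0622535239386479,
  0.0271524594117541};

inline double neo_energy(double r, double r0, double ks) {
  // U(r) = ks * r0 * Int_1^{r/r0} g(u) (u - 1) du   (quadrature; no closed form)
  double x = r / r0;
  double mid = 0.5 * (1.0 + x), half = 0.5 * (x - 1.0);
  double s = 0.0;
  for (int q = 0; q < 16; ++q) {
    double u = mid + half * GL_X[q];
    s += GL_W[q] * g_neo(u) * (u - 1.0);
  }
  return ks * r0 * half * s;
}

inline NumericVector compute_energies(const std::vector<double> &p,
                                      const std::vector<double> &e,
                                      const Topology &T, const Params &P) {
  const int N = T.n_total(), M = T.n_mnp, nb = T.n_blob();
  double u_stretch = 0, u_area = 0, u_teth = 0, u_wca = 0, u_dd = 0,
         u_zee = 0, u_trap = 0;
  for (size_t k = 0; k < T.edge_i.size(); ++k) {
    int i = T.edge_i[k], j = T.edge_j[k];
    double dx = p[3 * j] - p[3 * i], dy = p[3 * j + 1] - p[3 * i + 1],
           dz = p[3 * j + 2] - p[3 * i + 2];
    u_stretch += neo_energy(std::sqrt(dx * dx + dy * dy + dz * dz), T.r0_edge[k], P.ks);
  }
  for (size_t k = 0; k < T.tri_a.size(); ++k) {
    int a = T.tri_a[k], b = T.tri_b[k], c = T.tri_c[k];
    double ux = p[3 * b] - p[3 * a], uy = p[3 * b + 1] - p[3 * a + 1],
           uz = p[3 * b + 2] - p[3 * a + 2];
    double vx = p[3 * c] - p[3 * a], vy = p[3 * c + 1] - p[3 * a + 1],
           vz = p[3 * c + 2] - p[3 * a + 2];
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
    double S = 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
    double d = S - T.S0[k];
    u_area += 0.5 * P.kal * d * d / T.S0[k]; // bookkeeping proxy for the constraint
  }
  for (size_t k = 0; k < T.teth_i.size(); ++k) {
    int i = T.teth_i[k], j = T.teth_j[k];
    double dx = p[3 * j] - p[3 * i], dy = p[3 * j + 1] - p[3 * i + 1],
           dz = p[3 * j + 2] - p[3 * i + 2];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz) - T.r0_teth[k];
    u_teth += 0.5 * P.kh * d * d;
  }
  if (P.eps > 0) {
    for (int m = 0; m < N; ++m) {
      for (int j = m + 1; j < N; ++j) {
        double dx = p[3 * j] - p[3 * m], dy = p[3 * j + 1] - p[3 * m + 1],
               dz = p[3 * j + 2] - p[3 * m + 2];
        double Rc = 0.5 * (P.diam[m] + P.diam[j]);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= Rc * Rc) continue;
        if (T.excluded(m, j)) continue;
        double sig6 = std::pow(Rc, 6) / 2.0;
        double inv_r6 = 1.0 / (r2 * r2 * r2);
        double sr6 = sig6 * inv_r6;
        u_wca += 4.0 * P.eps * (sr6 * sr6 - sr6) + P.eps;
      }
    }
  }
  if (M > 0 && P.magnetics) {
    const double C = P.lambda * P.a_red * P.a_red * P.a_red;
    for (int mi = 0; mi < M; ++mi) {
      int i = nb + mi;
      for (int mj = mi + 1; mj < M; ++mj) {
        int j = nb + mj;
        double rx = p[3 * j] - p[3 * i], ry = p[3 * j + 1] - p[3 * i + 1],
               rz = p[3 * j + 2] - p[3 * i + 2];
        double r2 = rx * rx + ry * ry + rz * rz;
        double r = std::sqrt(r2);
        double inv_r3 = 1.0 / (r2 * r), inv_r2 = 1.0 / r2;
        const double *ei = &e[3 * mi], *ej = &e[3 * mj];
        double eiej = ei[0] * ej[0] + ei[1] * ej[1] + ei[2] * ej[2];
        double eir = ei[0] * rx + ei[1] * ry + ei[2] * rz;
        double ejr = ej[0] * rx + ej[1] * ry + ej[2] * rz;
        u_dd += C * inv_r3 * (eiej - 3.0 * eir * ejr * inv_r2);
      }
      const double *ei = &e[3 * mi];
      u_zee -= P.xi * (ei[0] * P.h[0] + ei[1] * P.h[1] + ei[2] * P.h[2]);
    }
  }
  if (M > 0 && P.k_trap > 0) {
    for (int m = nb; m < N; ++m) {
      double dx = p[3 * m] - P.trap_c[0], dy = p[3 * m + 1] - P.trap_c[1],
             dz = p[3 * m + 2] - P.trap_c[2];
      u_trap += 0.5 * P.k_trap * (dx * dx + dy * dy + dz * dz);
    }
  }
  NumericVector out = NumericVector::create(
      _["stretch"] = u_stretch, _["area"] = u_area, _["tether"] = u_teth,
      _["wca"] = u_wca, _["dipole"] = u_dd, _["zeeman"] = u_zee,
      _["trap"] = u_trap);
  return out;
}

// --- marshalling ----------------------------------------------------------

inline Topology topo_from_list(List tl) {
  Topology T;
  IntegerMatrix ed = tl["edges"];
  for (int k = 0; k < ed.nrow(); ++k) {
    T.edge_i.push_back(ed(k, 0));
    T.edge_j.push_back(ed(k, 1));
  }
  NumericVector r0e = tl["r0_edge"];
  T.r0_edge.assign(r0e.begin(), r0e.end());
  IntegerMatrix tr = tl["triangles"];
  for (int k = 0; k < tr.nrow(); ++k) {
    T.tri_a.push_back(tr(k, 0));
    T.tri_b.push_back(tr(k, 1));
    T.tri_c.push_back(tr(k, 2));
  }
  NumericVector s0 = tl["S0"];
  T.S0.assign(s0.begin(), s0.end());
  IntegerMatrix th = tl["tethers"];
  for (int k = 0; k < th.nrow(); ++k) {
    T.teth_i.push_back(th(k, 0));
    T.teth_j.push_back(th(k, 1));
  }
  NumericVector r0t = tl["r0_tether"];
  T.r0_teth.assign(r0t.begin(), r0t.end());
  T.n_out = as<int>(tl["n_out"]);
  T.n_in = as<int>(tl["n_in"]);
  T.n_mnp = as<int>(tl["n_mnp"]);
  T.build_exclusions();
  IntegerMatrix ex = tl["extra_excl"];
  for (int k = 0; k < ex.nrow(); ++k) {
    T.excl[ex(k, 0)].push_back(ex(k, 1));
    T.excl[ex(k, 1)].push_back(ex(k, 0));
  }
  return T;
}

inline Params params_from_list(List pl) {
  Params P;
  P.ks = as<double>(pl["ks"]);
  P.kal = as<double>(pl["kal"]);
  P.kh = as<double>(pl["kh"]);
  P.eps = as<double>(pl["eps"]);
  P.lambda = as<double>(pl["lambda"]);
  P.a_red = as<double>(pl["a_red"]);
  P.xi = as<double>(pl["xi"]);
  NumericVector h = pl["h"];
  P.h[0] = h[0]; P.h[1] = h[1]; P.h[2] = h[2];
  P.k_trap = as<double>(pl["k_trap"]);
  NumericVector tc = pl["trap_center"];
  P.trap_c[0] = tc[0]; P.trap_c[1] = tc[1]; P.trap_c[2] = tc[2];
  NumericVector dm = pl["diam"];
  P.diam.assign(dm.begin(), dm.end());
  P.magnetics = as<bool>(pl["magnetics"]);
  return P;
}

inline std::vector<double> flatten(NumericMatrix m) {
  std::vector<double> v(3 * m.nrow());
  for (int i = 0; i < m.nrow(); ++i)
    for (int d = 0; d < 3; ++d) v[3 * i + d] = m(i, d);
  return v;
}

inline NumericMatrix unflatten(const std::vector<double> &v, int n) {
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) m(i, d) = v[3 * i + d];
  return m;
}

} // namespace mps

// [[Rcpp::export(name = ".ff_forces")]]
List ff_forces(NumericMatrix pos, NumericMatrix orient, List topo, List params) {
  mps::Topology T = mps::topo_from_list(topo);
  mps::Params P = mps::params_from_list(params);
  std::vector<double> p = mps::flatten(pos), e = mps::flatten(orient);
  std::vector<double> f(3 * T.n_total()), tq(3 * std::max(T.n_mnp, 1));
  mps::CellList cl;
  mps::compute_forces(p, e, T, P, f, tq, cl);
  return List::create(_["forces"] = mps::unflatten(f, T.n_total()),
                      _["torques"] = mps::unflatten(tq, T.n_mnp));
}

// [[Rcpp::export(name = ".ff_energies")]]
NumericVector ff_energies(NumericMatrix pos, NumericMatrix orient, List topo,
                          List params) {
  mps::Topology T = mps::topo_from_list(topo);
  mps::Params P = mps::params_from_list(params);
  std::vector<double> p = mps::flatten(pos), e = mps::flatten(orient);
  return mps::compute_energies(p, e, T, P);
}

// [[Rcpp::export(name = ".neo_hookean_energy")]]
NumericVector neo_hookean_energy_cpp(NumericVector r, double r0, double ks) {
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i) out[i] = mps::neo_energy(r[i], r0, ks);
  return out;
}

// BAOAB Langevin integrator over translational + rotational degrees of
// freedom. Noise is drawn from R's RNG, so trajectories are reproducible
// (and restartable) through set.seed()/.Random.seed.
// [[Rcpp::export(name = ".sim_run")]]
List sim_run(NumericMatrix pos, NumericMatrix vel, NumericMatrix orient,
             NumericMatrix angvel, List topo, List params, List cfg,
             int n_steps, int sample_every, IntegerVector rng_state) {
  mps::Topology T = mps::topo_from_list(topo);
  mps::Params P = mps::params_from_list(params);
  const int N = T.n_total(), M = T.n_mnp, nb = T.n_blob();
  const double dt = as<double>(cfg["dt"]);
  const double kT = as<double>(cfg["kT"]);
  const double mass = as<double>(cfg["mass"]);
  const double zeta_t = as<double>(cfg["zeta_t"]);
  const double zeta_r = as<double>(cfg["zeta_r"]);
  const double inertia = as<double>(cfg["inertia"]);

  std::vector<double> p = mps::flatten(pos), v = mps::flatten(vel);
  std::vector<double> e = mps::flatten(orient), w = mps::flatten(angvel);
  std::vector<double> f(3 * N), tq(3 * std::max(M, 1));

  // per-element OU coefficients; friction scales with soft-sphere diameter
  // (Stokes drag proportional to size), referenced to the nanoparticle
  std::vector<double> c1(N), c2(N);
  for (int i = 0; i < N; ++i) {
    double zi = zeta_t * P.diam[i] / P.a_red;
    c1[i] = std::exp(-zi * dt / mass);
    c2[i] = std::sqrt((1.0 - c1[i] * c1[i]) * kT / mass);
  }
  const double c1r = std::exp(-zeta_r * dt / inertia);
  const double c2r = std::sqrt((1.0 - c1r * c1r) * kT / inertia);

  mps::NoiseStream rng;
  if (rng_state.size() == 8) rng.unpack(rng_state);
  else rng.seed_from_r();
  std::vector<double> noise(3 * N), noise_r(3 * std::max(M, 1));

  mps::CellList cl;
  mps::compute_forces(p, e, T, P, f, tq, cl);

  const int n_samp = (sample_every > 0) ? n_steps / sample_every : 0;
  NumericVector samp_time(n_samp);
  NumericMatrix samp_mnp(n_samp, 3 * M), samp_e(n_samp, 3 * M);
  NumericMatrix samp_out(n_samp, 3 * T.n_out);
  NumericMatrix samp_energy(n_samp, 8);
  int ks_ = 0;

  auto rotate_e = [&](int m, double hdt) {
    // rotate e_m about angular velocity by |w| * hdt
    double wx = w[3 * m], wy = w[3 * m + 1], wz = w[3 * m + 2];
    double wn = std::sqrt(wx * wx + wy * wy + wz * wz);
    if (wn < 1e-300) return;
    double th = wn * hdt, c = std::cos(th), s = std::sin(th);
    double ax = wx / wn, ay = wy / wn, az = wz / wn;
    double ex = e[3 * m], ey = e[3 * m + 1], ez = e[3 * m + 2];
    double ad = ax * ex + ay * ey + az * ez;
    double cx = ay * ez - az * ey, cy = az * ex - ax * ez, cz = ax * ey - ay * ex;
    e[3 * m] = ex * c + cx * s + ax * ad * (1 - c);
    e[3 * m + 1] = ey * c + cy * s + ay * ad * (1 - c);
    e[3 * m + 2] = ez * c + cz * s + az * ad * (1 - c);
  };

  for (int step = 0; step < n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < 3 * N; ++i) v[i] += 0.5 * dt * f[i] / mass;
    for (int i = 0; i < 3 * M; ++i) w[i] += 0.5 * dt * tq[i] / inertia;
    // A: half drift
    for (int i = 0; i < 3 * N; ++i) p[i] += 0.5 * dt * v[i];
    for (int m = 0; m < M; ++m) rotate_e(m, 0.5 * dt);
    // O: Ornstein-Uhlenbeck on velocities
    rng.fill_norm(noise.data(), 3 * N);
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] = c1[i] * v[3 * i + d] + c2[i] * noise[3 * i + d];
    if (M > 0) {
      rng.fill_norm(noise_r.data(), 3 * M);
      for (int i = 0; i < 3 * M; ++i) w[i] = c1r * w[i] + c2r * noise_r[i];
    }
    // A: half drift
    for (int i = 0; i < 3 * N; ++i) p[i] += 0.5 * dt * v[i];
    for (int m = 0; m < M; ++m) rotate_e(m, 0.5 * dt);
    // renormalise orientations
    for (int m = 0; m < M; ++m) {
      double nrm = std::sqrt(e[3 * m] * e[3 * m] + e[3 * m + 1] * e[3 * m + 1] +
                             e[3 * m + 2] * e[3 * m + 2]);
      e[3 * m] /= nrm; e[3 * m + 1] /= nrm; e[3 * m + 2] /= nrm;
    }
    // force recompute + B: half kick
    mps::compute_forces(p, e, T, P, f, tq, cl);
    for (int i = 0; i < 3 * N; ++i) v[i] += 0.5 * dt * f[i] / mass;
    for (int i = 0; i < 3 * M; ++i) w[i] += 0.5 * dt * tq[i] / inertia;

    if (sample_every > 0 && (step + 1) % sample_every == 0) {
      samp_time[ks_] = (step + 1) * dt;
      for (int i = 0; i < 3 * M; ++i) {
        samp_mnp(ks_, i) = p[3 * nb + i];
        samp_e(ks_, i) = e[i];
      }
      for (int i = 0; i < 3 * T.n_out; ++i) samp_out(ks_, i) = p[i];
      NumericVector en = mps::compute_energies(p, e, T, P);
      for (int q = 0; q < 7; ++q) samp_energy(ks_, q) = en[q];
      double ke = 0.0;
      for (int i = 0; i < 3 * N; ++i) ke += 0.5 * mass * v[i] * v[i];
      samp_energy(ks_, 7) = ke;
      if (!std::isfinite(ke) || !std::isfinite(p[0]))
        stop("non-finite state detected at step %d", step + 1);
      ++ks_;
    }
  }

  return List::create(
      _["pos"] = mps::unflatten(p, N), _["vel"] = mps::unflatten(v, N),
      _["orient"] = mps::unflatten(e, M), _["angvel"] = mps::unflatten(w, M),
      _["rng_state"] = rng.pack(),
      _["samples"] = List::create(
          _["time"] = samp_time, _["mnp_pos"] = samp_mnp,
          _["mnp_orient"] = samp_e, _["outer_pos"] = samp_out,
          _["energy"] = samp_energy));
}
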