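#ifndef WTPET_SCENE_H
#define WTPET_SCENE_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

// All lengths in mm, energies in keV, attenuation coefficients in 1/mm.

static const double E511 = 511.0;
static const double C_MM_PER_PS = 0.299792458; // speed of light
static const double C_MM_PER_S  = 2.99792458e11;

// ---- energy scaling of cross sections -------------------------------------
// Total Klein-Nishina cross section per electron, in units where the
// constant prefactor cancels (only ratios are used).
inline double kn_total(double alpha) {
  double a = alpha;
  double l = std::log(1.0 + 2.0 * a);
  double t1 = (1.0 + a) / (a * a) * (2.0 * (1.0 + a) / (1.0 + 2.0 * a) - l / a);
  double t2 = l / (2.0 * a);
  double t3 = -(1.0 + 3.0 * a) / ((1.0 + 2.0 * a) * (1.0 + 2.0 * a));
  return t1 + t2 + t3;
}

inline double kn_ratio_511(double E) {
  static const double s511 = kn_total(1.0);
  return kn_total(E / E511) / s511;
}

struct Materials {
  std::vector<double> muInc; // incoherent (Compton) linear atten at 511 keV, 1/mm
  std::vector<double> muPe;  // photoelectric linear atten at 511 keV, 1/mm
  std::vector<double> peExp; // photoelectric energy exponent (511/E)^n
  double inc(int m, double E) const { return muInc[m] * kn_ratio_511(E); }
  double pe(int m, double E) const {
    return muPe[m] * std::pow(E511 / E, peExp[m]);
  }
  double total(int m, double E) const { return inc(m, E) + pe(m, E); }
  // probability that an interaction at energy E is Compton (vs photoelectric)
  double comptonFrac(int m, double E) const {
    double i = inc(m, E), p = pe(m, E);
    return (i + p) > 0.0 ? i / (i + p) : 1.0;
  }
};

inline Materials materials_from(const Rcpp::NumericVector& muInc511,
                                const Rcpp::NumericVector& muPe511,
                                const Rcpp::NumericVector& peExp) {
  Materials M;
  M.muInc.assign(muInc511.begin(), muInc511.end());
  M.muPe.assign(muPe511.begin(), muPe511.end());
  M.peExp.assign(peExp.begin(), peExp.end());
  return M;
}

// ---- geometric primitives --------------------------------------------------
// shape codes: 1 sphere (p1=r); 2 cylinder / 3 capsule (axis z, p1=r, p2=half
// length; capsules are thin cylinders); 4 box (p1,p2,p3 = half extents);
// 5 elliptical cylinder (p1=rx, p2=ry, p3=half length).
struct Scene {
  std::vector<int> shape;
  std::vector<double> cx, cy, cz, p1, p2, p3;
  std::vector<int> mat; // 0-based material index
  std::vector<double> act;
  int background;       // material index of the surrounding medium (air)
  int n() const { return (int)shape.size(); }
};

inline Scene scene_from_matrix(const Rcpp::NumericMatrix& P, int background) {
  Scene s;
  s.background = background;
  int n = P.nrow();
  for (int i = 0; i < n; ++i) {
    s.shape.push_back((int)P(i, 0));
    s.cx.push_back(P(i, 1)); s.cy.push_back(P(i, 2)); s.cz.push_back(P(i, 3));
    s.p1.push_back(P(i, 4)); s.p2.push_back(P(i, 5)); s.p3.push_back(P(i, 6));
    s.mat.push_back((int)P(i, 7));
    s.act.push_back(P(i, 8));
  }
  return s;
}

inline bool point_in_prim(const Scene& s, int i, double x, double y, double z) {
  double dx = x - s.cx[i], dy = y - s.cy[i], dz = z - s.cz[i];
  switch (s.shape[i]) {
  case 1: return dx * dx + dy * dy + dz * dz <= s.p1[i] * s.p1[i];
  case 2:
  case 3: return dx * dx + dy * dy <= s.p1[i] * s.p1[i] && std::fabs(dz) <= s.p2[i];
  case 4: return std::fabs(dx) <= s.p1[i] && std::fabs(dy) <= s.p2[i] &&
                 std::fabs(dz) <= s.p3[i];
  case 5: {
    double u = dx / s.p1[i], v = dy / s.p2[i];
    return u * u + v * v <= 1.0 && std::fabs(dz) <= s.p3[i];
  }
  }
  return false;
}

// painter's rule: the last primitive listed that contains the point wins
inline int material_at(const Scene& s, double x, double y, double z) {
  for (int i = s.n() - 1; i >= 0; --i)
    if (point_in_prim(s, i, x, y, z)) return s.mat[i];
  return s.background;
}

inline int prim_at(const Scene& s, double x, double y, double z) {
  for (int i = s.n() - 1; i >= 0; --i)
    if (point_in_prim(s, i, x, y, z)) return i;
  return -1;
}

// intersect the running interval [t0,t1] with the slab lo <= p + t*d <= hi
inline bool slab_clip(double p, double d, double lo, double hi,
                      double& t0, double& t1) {
  if (std::fabs(d) < 1e-15) return p >= lo && p <= hi;
  double a = (lo - p) / d, b = (hi - p) / d;
  if (a > b) std::swap(a, b);
  if (a > t0) t0 = a;
  if (b < t1) t1 = b;
  return t0 < t1;
}

// quadratic helper: intersect interval with {t : A t^2 + B t + C <= 0}
inline bool quad_clip(double A, double B, double C, double& t0, double& t1) {
  if (A < 1e-18) return C <= 0.0; // direction parallel to axis
  double disc = B * B - 4.0 * A * C;
  if (disc <= 0.0) return false;
  double sq = std::sqrt(disc);
  double a = (-B - sq) / (2.0 * A), b = (-B + sq) / (2.0 * A);
  if (a > t0) t0 = a;
  if (b < t1) t1 = b;
  return t0 < t1;
}

// ray (p + t d) vs primitive i; on success returns clipped [t0,t1]
inline bool ray_prim(const Scene& s, int i, const double* p, const double* d,
                     double& t0, double& t1) {
  t0 = -1e30; t1 = 1e30;
  double px = p[0] - s.cx[i], py = p[1] - s.cy[i], pz = p[2] - s.cz[i];
  switch (s.shape[i]) {
  case 1: {
    double A = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    double B = 2.0 * (px * d[0] + py * d[1] + pz * d[2]);
    double C = px * px + py * py + pz * pz - s.p1[i] * s.p1[i];
    return quad_clip(A, B, C, t0, t1);
  }
  case 2:
  case 3: {
    double A = d[0] * d[0] + d[1] * d[1];
    double B = 2.0 * (px * d[0] + py * d[1]);
    double C = px * px + py * py - s.p1[i] * s.p1[i];
    if (!quad_clip(A, B, C, t0, t1)) return false;
    return slab_clip(pz, d[2], -s.p2[i], s.p2[i], t0, t1);
  }
  case 4:
    if (!slab_clip(px, d[0], -s.p1[i], s.p1[i], t0, t1)) return false;
    if (!slab_clip(py, d[1], -s.p2[i], s.p2[i], t0, t1)) return false;
    return slab_clip(pz, d[2], -s.p3[i], s.p3[i], t0, t1);
  case 5: {
    double ux = px / s.p1[i], vy = py / s.p2[i];
    double ex = d[0] / s.p1[i], ey = d[1] / s.p2[i];
    double A = ex * ex + ey * ey;
    double B = 2.0 * (ux * ex + vy * ey);
    double C = ux * ux + vy * vy - 1.0;
    if (!quad_clip(A, B, C, t0, t1)) return false;
    return slab_clip(pz, d[2], -s.p3[i], s.p3[i], t0, t1);
  }
  }
  return false;
}

struct Seg { double a, b; int mat; };

// Piecewise-constant material segments along p + t d for t in [0, tmax].
// tmax < 0 means "up to the last primitive exit" (propagation mode: trailing
// background is irrelevant because nothing attenuates there).
inline void scene_segments(const Scene& s, const double* p, const double* d,
                           double tmax, std::vector<Seg>& out) {
  out.clear();
  std::vector<double> bnd;
  double tlast = 0.0;
  for (int i = 0; i < s.n(); ++i) {
    double a, b;
    if (!ray_prim(s, i, p, d, a, b)) continue;
    if (b <= 0.0) continue;
    if (a < 0.0) a = 0.0;
    if (tmax >= 0.0) { if (a >= tmax) continue; if (b > tmax) b = tmax; }
    bnd.push_back(a); bnd.push_back(b);
    if (b > tlast) tlast = b;
  }
  double tend = (tmax >= 0.0) ? tmax : tlast;
  if (tend <= 0.0) return;
  bnd.push_back(0.0); bnd.push_back(tend);
  std::sort(bnd.begin(), bnd.end());
  for (size_t k = 0; k + 1 < bnd.size(); ++k) {
    double a = bnd[k], b = bnd[k + 1];
    if (b - a < 1e-9) continue;
    double tm = 0.5 * (a + b);
    int m = material_at(s, p[0] + tm * d[0], p[1] + tm * d[1], p[2] + tm * d[2]);
    if (!out.empty() && out.back().mat == m && std::fabs(out.back().b - a) < 1e-9)
      out.back().b = b;
    else
      out.push_back({a, b, m});
  }
}

// line integral of mu(E) between two points (includes background medium)
inline double line_integral_mu(const Scene& s, const Materials& M,
                               const double* p1, const double* p2, double E) {
  double d[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L <= 0.0) return 0.0;
  double u[3] = {d[0] / L, d[1] / L, d[2] / L};
  std::vector<Seg> segs;
  scene_segments(s, p1, u, L, segs);
  double tot = 0.0, covered = 0.0;
  for (const Seg& g : segs) {
    tot += (g.b - g.a) * M.total(g.mat, E);
    covered += (g.b - g.a);
  }
  if (L - covered > 1e-9) tot += (L - covered) * M.total(s.background, E);
  return tot;
}

// ---- Compton scattering ----------------------------------------------------
// Kahn's rejection method for the Klein-Nishina angular distribution.
// Uses R's RNG (caller must hold an RNGScope).
inline double sample_kn_costheta(double E) {
  double a = E / E511;
  for (int it = 0; it < 10000; ++it) {
    double r1 = unif_rand(), r2 = unif_rand(), r3 = unif_rand();
    if (r1 <= (1.0 + 2.0 * a) / (9.0 + 2.0 * a)) {
      double eta = 1.0 + 2.0 * a * r2;
      if (r3 <= 4.0 * (1.0 / eta - 1.0 / (eta * eta)))
        return 1.0 - (eta - 1.0) / a;
    } else {
      double eta = (1.0 + 2.0 * a) / (1.0 + 2.0 * a * r2);
      double c = 1.0 - (eta - 1.0) / a;
      if (r3 <= 0.5 * (c * c + 1.0 / eta)) return c;
    }
  }
  return 1.0; // unreachable in practice
}

// rotate unit vector d by polar angle (cosT) about itself, azimuth phi
inline void rotate_direction(double* d, double cosT, double phi) {
  double sinT = std::sqrt(std::max(0.0, 1.0 - cosT * cosT));
  double ax = 0.0, ay = 0.0, az = 1.0;
  if (std::fabs(d[2]) > 0.9) { ax = 1.0; az = 0.0; }
  // e1 = normalize(d x a), e2 = d x e1
  double e1x = d[1] * az - d[2] * ay;
  double e1y = d[2] * ax - d[0] * az;
  double e1z = d[0] * ay - d[1] * ax;
  double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
  e1x /= n1; e1y /= n1; e1z /= n1;
  double e2x = d[1] * e1z - d[2] * e1y;
  double e2y = d[2] * e1x - d[0] * e1z;
  double e2z = d[0] * e1y - d[1] * e1x;
  double cp = std::cos(phi), sp = std::sin(phi);
  double nx = cosT * d[0] + sinT * (cp * e1x + sp * e2x);
  double ny = cosT * d[1] + sinT * (cp * e1y + sp * e2y);
  double nz = cosT * d[2] + sinT * (cp * e1z + sp * e2z);
  double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
  d[0] = nx / nn; d[1] = ny / nn; d[2] = nz / nn;
}

#endif
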