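#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "scene.h"
#include "scanner.h"
using namespace Rcpp;

struct Grid {
  double ox, oy, oz;   // low corner (mm)
  double sx, sy, sz;   // voxel size (mm)
  int nx, ny, nz;
  long nvox() const { return (long)nx * ny * nz; }
};

static Grid grid_from(const NumericVector& origin, const NumericVector& spacing,
                      const IntegerVector& dims) {
  Grid g;
  g.ox = origin[0]; g.oy = origin[1]; g.oz = origin[2];
  g.sx = spacing[0]; g.sy = spacing[1]; g.sz = spacing[2];
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  return g;
}

// Amanatides-Woo voxel traversal from p1 to p2; appends (linear index, length)
static void trace_ray(const Grid& g, const double* p1, const double* p2,
                      std::vector<int>& idx, std::vector<double>& len) {
  idx.clear(); len.clear();
  double d[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L <= 0.0) return;
  double t0 = 0.0, t1 = 1.0;
  double lo[3] = {g.ox, g.oy, g.oz};
  double hi[3] = {g.ox + g.nx * g.sx, g.oy + g.ny * g.sy, g.oz + g.nz * g.sz};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-15) {
      if (p1[a] < lo[a] || p1[a] > hi[a]) return;
    } else {
      double ta = (lo[a] - p1[a]) / d[a], tb = (hi[a] - p1[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t1 <= t0) return;
  double sp[3] = {g.sx, g.sy, g.sz};
  int nn[3] = {g.nx, g.ny, g.nz};
  double start[3];
  int iv[3];
  double teps = 1e-10 * (t1 - t0);
  for (int a = 0; a < 3; ++a) {
    start[a] = p1[a] + (t0 + teps) * d[a];
    iv[a] = (int)std::floor((start[a] - lo[a]) / sp[a]);
    if (iv[a] < 0) iv[a] = 0;
    if (iv[a] >= nn[a]) iv[a] = nn[a] - 1;
  }
  double tMax[3], tDelta[3];
  int step[3];
  for (int a = 0; a < 3; ++a) {
    if (d[a] > 1e-15) {
      step[a] = 1;
      tMax[a] = ((lo[a] + (iv[a] + 1) * sp[a]) - p1[a]) / d[a];
      tDelta[a] = sp[a] / d[a];
    } else if (d[a] < -1e-15) {
      step[a] = -1;
      tMax[a] = ((lo[a] + iv[a] * sp[a]) - p1[a]) / d[a];
      tDelta[a] = -sp[a] / d[a];
    } else {
      step[a] = 0;
      tMax[a] = 1e30;
      tDelta[a] = 1e30;
    }
  }
  double t = t0;
  int guard = 3 * (g.nx + g.ny + g.nz) + 6;
  while (t < t1 - 1e-12 && guard-- > 0) {
    int a = 0;
    if (tMax[1] < tMax[a]) a = 1;
    if (tMax[2] < tMax[a]) a = 2;
    double tn = std::min(tMax[a], t1);
    if (tn > t) {
      idx.push_back(iv[0] + g.nx * (iv[1] + (long)g.ny * iv[2]));
      len.push_back((tn - t) * L);
    }
    if (tMax[a] >= t1) break;
    t = tMax[a];
    tMax[a] += tDelta[a];
    iv[a] += step[a];
    if (iv[a] < 0 || iv[a] >= nn[a]) break;
  }
}

// [[Rcpp::export]]
List cpp_trace_lor(const NumericVector& p1, const NumericVector& p2,
                   const NumericVector& origin, const NumericVector& spacing,
                   const IntegerVector& dims) {
  Grid g = grid_from(origin, spacing, dims);
  std::vector<int> idx;
  std::vector<double> len;
  double a[3] = {p1[0], p1[1], p1[2]}, b[3] = {p2[0], p2[1], p2[2]};
  trace_ray(g, a, b, idx, len);
  return List::create(Named("index") = wrap(idx), Named("length") = wrap(len));
}

// attenuation survival probability along LORs through a voxelized mu map
// (mu in 1/mm, same grid layout as images)
// [[Rcpp::export]]
NumericVector cpp_atten_map_factors(const NumericMatrix& P1,
                                    const NumericMatrix& P2,
                                    const NumericVector& mu,
                                    const NumericVector& origin,
                                    const NumericVector& spacing,
                                    const IntegerVector& dims) {
  Grid g = grid_from(origin, spacing, dims);
  int n = P1.nrow();
  NumericVector out(n);
  std::vector<int> idx;
  std::vector<double> len;
  for (int i = 0; i < n; ++i) {
    double a[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    double b[3] = {P2(i, 0), P2(i, 1), P2(i, 2)};
    trace_ray(g, a, b, idx, len);
    double s = 0.0;
    for (size_t k = 0; k < idx.size(); ++k) s += mu[idx[k]] * len[k];
    out[i] = std::exp(-s);
  }
  return out;
}

// TOF-weighted list-mode MLEM.
// events columns: x1 y1 z1 x2 y2 z2 dtPs weight
// Convention: dt = t1 - t2; the annihilation estimate sits at
// s = -c*dt/2 from the LOR midpoint toward endpoint 1.
// [[Rcpp::export]]
List cpp_mlem(const NumericMatrix& events, const NumericVector& origin,
              const NumericVector& spacing, const IntegerVector& dims,
              const NumericVector& sens, double tofSigmaMm, int nIter,
              Nullable<NumericVector> init) {
  Grid g = grid_from(origin, spacing, dims);
  long nv = g.nvox();
  if (sens.size() != nv) stop("sensitivity image does not match the grid");
  std::vector<double> x(nv), accum(nv), sn(sens.begin(), sens.end());
  if (init.isNotNull()) {
    NumericVector x0(init);
    if ((long)x0.size() != nv) stop("initial image does not match the grid");
    bool any = false;
    for (long j = 0; j < nv; ++j) { x[j] = x0[j]; any = any || x[j] > 0; }
    if (!any) stop("initial image is all zero");
  } else {
    for (long j = 0; j < nv; ++j) x[j] = sn[j] > 0 ? 1.0 : 0.0;
  }
  int n = events.nrow();
  if (n == 0) stop("empty listmode");
  NumericVector loglik(nIter);
  int skipped = 0;
  std::vector<int> idx;
  std::vector<double> len, w;
  idx.reserve(1024); len.reserve(1024); w.reserve(1024);
  for (int it = 0; it < nIter; ++it) {
    std::fill(accum.begin(), accum.end(), 0.0);
    double ll = 0.0;
    int skip = 0;
    for (int i = 0; i < n; ++i) {
      double a[3] = {events(i, 0), events(i, 1), events(i, 2)};
      double b[3] = {events(i, 3), events(i, 4), events(i, 5)};
      trace_ray(g, a, b, idx, len);
      if (idx.empty()) { ++skip; continue; }
      w.resize(idx.size());
      if (tofSigmaMm > 0.0) {
        double m[3] = {0.5 * (a[0] + b[0]), 0.5 * (a[1] + b[1]), 0.5 * (a[2] + b[2])};
        double u[3] = {a[0] - m[0], a[1] - m[1], a[2] - m[2]};
        double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
        u[0] /= un; u[1] /= un; u[2] /= un;
        double sTof = -0.5 * C_MM_PER_PS * events(i, 6);
        for (size_t k = 0; k < idx.size(); ++k) {
          long v = idx[k];
          int izv = (int)(v / ((long)g.nx * g.ny));
          int iyv = (int)((v / g.nx) % g.ny);
          int ixv = (int)(v % g.nx);
          double cx = g.ox + (ixv + 0.5) * g.sx - m[0];
          double cy = g.oy + (iyv + 0.5) * g.sy - m[1];
          double cz = g.oz + (izv + 0.5) * g.sz - m[2];
          double sk = cx * u[0] + cy * u[1] + cz * u[2];
          double dlt = (sk - sTof) / tofSigmaMm;
          w[k] = (std::fabs(dlt) <= 3.0) ? len[k] * std::exp(-0.5 * dlt * dlt) : 0.0;
        }
      } else {
        for (size_t k = 0; k < idx.size(); ++k) w[k] = len[k];
      }
      double f = 0.0;
      for (size_t k = 0; k < idx.size(); ++k) f += w[k] * x[idx[k]];
      if (f <= 0.0) { ++skip; continue; }
      double wev = events(i, 7);
      ll += wev * std::log(f);
      double r = wev / f;
      for (size_t k = 0; k < idx.size(); ++k) accum[idx[k]] += w[k] * r;
    }
    double sx = 0.0;
    for (long j = 0; j < nv; ++j) sx += sn[j] * x[j];
    loglik[it] = ll - sx; // list-mode log likelihood at the current image
    if (it == 0) skipped = skip;
    for (long j = 0; j < nv; ++j)
      x[j] = sn[j] > 0 ? x[j] * accum[j] / sn[j] : 0.0;
    Rcpp::checkUserInterrupt();
  }
  return List::create(Named("image") = wrap(x), Named("loglik") = loglik,
                      Named("skipped") = skipped);
}

// Sensitivity image: detection probability of an emission at each point.
// At every control point of a coarse lattice spanning the grid, a shared
// set of isotropic emission directions is tested for detection by a
// valid crystal pair (both front faces hit, geometric validity rule),
// optionally weighted by the analytic attenuation factor through the
// scene; the acceptance is then interpolated trilinearly onto the voxel
// grid and normalized to its maximum. Crystal stopping power is treated
// as direction-independent (it varies slowly over any local grid).

// detection endpoints of the line through p along +/- d; returns false
// when the line is not accepted
static bool detect_line(const Scanner& sc, const double* p, const double* d,
                        int minTangSep, double* q1, double* q2) {
  if (sc.type == 1) {
    if (std::fabs(d[1]) < 1e-12) return false;
    if (std::fabs(p[1]) >= sc.halfGap) return false; // not between the panels
    double zmax = sc.z0 + (sc.nbz - 1) * sc.pitchZ + sc.blockZ;
    for (int side = 0; side < 2; ++side) {
      double yface = (side == 0) ? sc.halfGap : -sc.halfGap;
      double t = (yface - p[1]) / d[1];
      double* q = (((side == 0) == (d[1] > 0.0))) ? q1 : q2;
      q[0] = p[0] + t * d[0];
      q[1] = yface;
      q[2] = p[2] + t * d[2];
      if (std::fabs(q[0]) > sc.halfX) return false;
      if (q[2] < sc.z0 || q[2] > zmax) return false;
      if (!flat_in_block_z(sc, q[2])) return false;
    }
    return true;
  }
  // cylindrical: line vs inner cylinder radius
  double A = d[0] * d[0] + d[1] * d[1];
  if (A < 1e-18) return false;
  double B = 2.0 * (p[0] * d[0] + p[1] * d[1]);
  double C = p[0] * p[0] + p[1] * p[1] - sc.rIn * sc.rIn;
  if (C >= 0.0) return false; // emission point outside the crystal ring
  double disc = B * B - 4.0 * A * C;
  if (disc <= 0.0) return false;
  double sq = std::sqrt(disc);
  double tp = (-B + sq) / (2.0 * A), tm = (-B - sq) / (2.0 * A);
  for (int k = 0; k < 3; ++k) {
    q1[k] = p[k] + tp * d[k];
    q2[k] = p[k] + tm * d[k];
  }
  if (std::fabs(q1[2]) > sc.zHalf || std::fabs(q2[2]) > sc.zHalf) return false;
  if (minTangSep > 0) {
    double ph1 = std::atan2(q1[1], q1[0]);
    double ph2 = std::atan2(q2[1], q2[0]);
    if (ph1 < 0) ph1 += 2.0 * M_PI;
    if (ph2 < 0) ph2 += 2.0 * M_PI;
    int i1 = (int)std::floor(ph1 / sc.dPhi);
    int i2 = (int)std::floor(ph2 / sc.dPhi);
    int dd = std::abs(i1 - i2);
    dd = std::min(dd, sc.nTang - dd);
    if (dd < minTangSep) return false;
  }
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_sensitivity_image(const List& scanner,
                                    const NumericVector& origin,
                                    const NumericVector& spacing,
                                    const IntegerVector& dims, int nDirs,
                                    int nControl, int minTangSep,
                                    Nullable<NumericMatrix> sceneMat,
                                    const NumericVector& muInc511,
                                    const NumericVector& muPe511,
                                    const NumericVector& muPeExp,
                                    int background) {
  Scanner sc = scanner_from_list(scanner);
  Grid g = grid_from(origin, spacing, dims);
  bool useScene = sceneMat.isNotNull();
  Scene scn;
  Materials M;
  if (useScene) {
    scn = scene_from_matrix(NumericMatrix(sceneMat), background);
    M = materials_from(muInc511, muPe511, muPeExp);
  }
  // shared isotropic direction set (common random numbers keep the
  // control-point estimates smoothly correlated)
  std::vector<double> dirs(3 * nDirs);
  for (int i = 0; i < nDirs; ++i) {
    double cz = 2.0 * unif_rand() - 1.0;
    double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
    double ph = 2.0 * M_PI * unif_rand();
    dirs[3 * i] = sz * std::cos(ph);
    dirs[3 * i + 1] = sz * std::sin(ph);
    dirs[3 * i + 2] = cz;
  }
  int nc = std::max(2, nControl);
  std::vector<double> cpos[3];
  for (int a = 0; a < 3; ++a) {
    double lo = (&g.ox)[a], sp = (&g.sx)[a];
    int n = (&g.nx)[a];
    for (int k = 0; k < nc; ++k)
      cpos[a].push_back(lo + k * (n * sp) / (nc - 1));
  }
  std::vector<double> ctrl((size_t)nc * nc * nc);
  double q1[3], q2[3];
  for (int kz = 0; kz < nc; ++kz)
    for (int ky = 0; ky < nc; ++ky)
      for (int kx = 0; kx < nc; ++kx) {
        double p[3] = {cpos[0][kx], cpos[1][ky], cpos[2][kz]};
        double acc = 0.0;
        for (int i = 0; i < nDirs; ++i) {
          if (!detect_line(sc, p, &dirs[3 * i], minTangSep, q1, q2)) continue;
          double w = 1.0;
          if (useScene) w = std::exp(-line_integral_mu(scn, M, q1, q2, E511));
          acc += w;
        }
        ctrl[kx + (size_t)nc * (ky + (size_t)nc * kz)] = acc / nDirs;
        Rcpp::checkUserInterrupt();
      }
  // trilinear interpolation onto the voxel grid
  NumericVector out((R_xlen_t)g.nvox());
  double ext[3] = {g.nx * g.sx, g.ny * g.sy, g.nz * g.sz};
  for (int iz = 0; iz < g.nz; ++iz)
    for (int iy = 0; iy < g.ny; ++iy)
      for (int ix = 0; ix < g.nx; ++ix) {
        double u[3] = {(ix + 0.5) * g.sx / ext[0] * (nc - 1),
                       (iy + 0.5) * g.sy / ext[1] * (nc - 1),
                       (iz + 0.5) * g.sz / ext[2] * (nc - 1)};
        int k0[3];
        double f[3];
        for (int a = 0; a < 3; ++a) {
          k0[a] = std::min((int)std::floor(u[a]), nc - 2);
          f[a] = u[a] - k0[a];
        }
        double v = 0.0;
        for (int c = 0; c < 8; ++c) {
          int ax = k0[0] + (c & 1), ay = k0[1] + ((c >> 1) & 1),
              az = k0[2] + ((c >> 2) & 1);
          double wgt = ((c & 1) ? f[0] : 1 - f[0]) *
                       (((c >> 1) & 1) ? f[1] : 1 - f[1]) *
                       (((c >> 2) & 1) ? f[2] : 1 - f[2]);
          v += wgt * ctrl[ax + (size_t)nc * (ay + (size_t)nc * az)];
        }
        out[ix + (R_xlen_t)g.nx * (iy + (R_xlen_t)g.ny * iz)] = v;
      }
  double mx = 0.0;
  for (R_xlen_t j = 0; j < out.size(); ++j) mx = std::max(mx, out[j]);
  if (mx > 0) for (R_xlen_t j = 0; j < out.size(); ++j) out[j] /= mx;
  return out;
}
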