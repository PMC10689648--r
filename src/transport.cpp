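#include <Rcpp.h>
#include "scene.h"
#include "scanner.h"
using namespace Rcpp;

// Photon matrix layout (columns):
// 0:x 1:y 2:z 3:dx 4:dy 5:dz 6:E 7:eventId 8:scattered 9:alive 10:path 11:t0
static const int PX = 0, PDX = 3, PE_ = 6, PID = 7, PSC = 8, PAL = 9,
                 PPATH = 10, PT0 = 11;

// [[Rcpp::export]]
NumericVector cpp_sample_kn(int n, double energyKeV) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_kn_costheta(energyKeV);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_emit_pairs(const NumericMatrix& decays, double acollFwhmMrad) {
  int n = decays.nrow();
  NumericMatrix ph(2 * n, 12);
  double sigAcoll = acollFwhmMrad / 2.354820045 * 1e-3; // rad
  for (int i = 0; i < n; ++i) {
    double cz = 2.0 * unif_rand() - 1.0;
    double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
    double phi = 2.0 * M_PI * unif_rand();
    double d1[3] = {sz * std::cos(phi), sz * std::sin(phi), cz};
    double d2[3] = {-d1[0], -d1[1], -d1[2]};
    if (sigAcoll > 0.0) {
      double th = std::fabs(norm_rand()) * sigAcoll;
      rotate_direction(d2, std::cos(th), 2.0 * M_PI * unif_rand());
    }
    for (int k = 0; k < 2; ++k) {
      int r = 2 * i + k;
      const double* d = (k == 0) ? d1 : d2;
      ph(r, 0) = decays(i, 0); ph(r, 1) = decays(i, 1); ph(r, 2) = decays(i, 2);
      ph(r, 3) = d[0]; ph(r, 4) = d[1]; ph(r, 5) = d[2];
      ph(r, PE_) = E511;
      ph(r, PID) = decays(i, 4);
      ph(r, PSC) = 0.0;
      ph(r, PAL) = 1.0;
      ph(r, PPATH) = 0.0;
      ph(r, PT0) = decays(i, 3);
    }
  }
  return ph;
}

// track one photon through the phantom scene; updates pos/dir/E/flags in place
static void propagate_one(double* row, const Scene& sc, const Materials& M,
                          double cutoffKeV) {
  std::vector<Seg> segs;
  double* pos = row + PX;
  double* dir = row + PDX;
  for (int inter = 0; inter < 50; ++inter) {
    scene_segments(sc, pos, dir, -1.0, segs);
    if (segs.empty()) return; // escaped
    double tau = -std::log(unif_rand());
    double acc = 0.0, tHit = -1.0;
    int mHit = -1;
    for (const Seg& g : segs) {
      double mu = M.total(g.mat, row[PE_]);
      double dtau = mu * (g.b - g.a);
      if (acc + dtau >= tau) {
        tHit = g.a + (tau - acc) / mu;
        mHit = g.mat;
        break;
      }
      acc += dtau;
    }
    if (tHit < 0.0) {
      // escapes the scene: advance just past the last boundary
      double tEnd = segs.back().b + 1e-6;
      for (int k = 0; k < 3; ++k) pos[k] += tEnd * dir[k];
      row[PPATH] += tEnd;
      return;
    }
    for (int k = 0; k < 3; ++k) pos[k] += tHit * dir[k];
    row[PPATH] += tHit;
    if (unif_rand() >= M.comptonFrac(mHit, row[PE_])) { // photoelectric
      row[PAL] = 0.0;
      return;
    }
    double cosT = sample_kn_costheta(row[PE_]);
    double Eout = row[PE_] / (1.0 + (row[PE_] / E511) * (1.0 - cosT));
    row[PSC] = 1.0;
    row[PE_] = Eout;
    if (Eout < cutoffKeV) { row[PAL] = 0.0; return; }
    rotate_direction(dir, cosT, 2.0 * M_PI * unif_rand());
  }
  row[PAL] = 0.0; // safety: too many scatters
}

// [[Rcpp::export]]
NumericMatrix cpp_propagate_phantom(NumericMatrix photons,
                                    const NumericMatrix& sceneMat,
                                    const NumericVector& muInc511,
                                    const NumericVector& muPe511,
                                    const NumericVector& muPeExp,
                                    int background, double cutoffKeV) {
  Scene sc = scene_from_matrix(sceneMat, background);
  Materials M = materials_from(muInc511, muPe511, muPeExp);
  NumericMatrix ph = clone(photons);
  int n = ph.nrow();
  std::vector<double> row(12);
  for (int i = 0; i < n; ++i) {
    if (ph(i, PAL) == 0.0) continue;
    for (int k = 0; k < 12; ++k) row[k] = ph(i, k);
    propagate_one(row.data(), sc, M, cutoffKeV);
    for (int k = 0; k < 12; ++k) ph(i, k) = row[k];
  }
  return ph;
}

struct SingleRec {
  double eventId, det, ia, ib, x, y, z, edep, tdet, scattered;
};

// interaction chain in the crystal volumes; returns true if energy deposited
static bool detect_one(const double* rowIn, const Scanner& sc,
                       const Materials& M, SingleRec& out) {
  double pos[3] = {rowIn[PX], rowIn[PX + 1], rowIn[PX + 2]};
  double dir[3] = {rowIn[PDX], rowIn[PDX + 1], rowIn[PDX + 2]};
  double E = rowIn[PE_];
  double path = rowIn[PPATH];
  double pathFirst = -1.0;
  double depE[3], depX[3], depY[3], depZ[3];
  int nDep = 0;
  long firstRegion = -1;
  std::vector<CrystalInterval> ivs;
  for (int inter = 0; inter < 3; ++inter) {
    crystal_intervals(sc, pos, dir, ivs);
    if (ivs.empty()) break;
    double mu = M.total(sc.mat, E);
    double tau = -std::log(unif_rand());
    double acc = 0.0, tHit = -1.0;
    for (const CrystalInterval& g : ivs) {
      double dtau = mu * (g.b - g.a);
      if (acc + dtau >= tau) { tHit = g.a + (tau - acc) / mu; break; }
      acc += dtau;
    }
    if (tHit < 0.0) break; // traverses all crystals uninteracted
    for (int k = 0; k < 3; ++k) pos[k] += tHit * dir[k];
    path += tHit;
    if (pathFirst < 0.0) pathFirst = path;
    // deposits are merged per readout region (adder + readout):
    // an interaction outside the first region would form a separate,
    // sub-window single, so the chain stops there
    long reg = readout_region(sc, pos[0], pos[1], pos[2]);
    if (nDep == 0) firstRegion = reg;
    else if (reg != firstRegion) break;
    bool photoelectric = unif_rand() >= M.comptonFrac(sc.mat, E);
    if (photoelectric) {
      depE[nDep] = E; depX[nDep] = pos[0]; depY[nDep] = pos[1]; depZ[nDep] = pos[2];
      ++nDep;
      break;
    }
    double cosT = sample_kn_costheta(E);
    double Eout = E / (1.0 + (E / E511) * (1.0 - cosT));
    depE[nDep] = E - Eout; depX[nDep] = pos[0]; depY[nDep] = pos[1]; depZ[nDep] = pos[2];
    ++nDep;
    if (Eout < 100.0) {
      // mean free path below ~0.5 mm in BGO/LSO: deposit locally and stop
      depE[nDep - 1] += Eout;
      break;
    }
    E = Eout;
    if (nDep >= 3) break; // residual energy escapes
    rotate_direction(dir, cosT, 2.0 * M_PI * unif_rand());
  }
  if (nDep == 0) return false;
  double eSum = 0.0, wx = 0.0, wy = 0.0, wz = 0.0;
  int iMax = 0;
  for (int k = 0; k < nDep; ++k) {
    eSum += depE[k];
    wx += depE[k] * depX[k]; wy += depE[k] * depY[k]; wz += depE[k] * depZ[k];
    if (depE[k] > depE[iMax]) iMax = k;
  }
  int det, ia, ib;
  crystal_address(sc, depX[iMax], depY[iMax], depZ[iMax], det, ia, ib);
  out.eventId = rowIn[PID];
  out.det = det; out.ia = ia; out.ib = ib;
  out.x = wx / eSum; out.y = wy / eSum; out.z = wz / eSum;
  out.edep = eSum;
  out.tdet = rowIn[PT0] + pathFirst / C_MM_PER_S;
  out.scattered = rowIn[PSC];
  return true;
}

static DataFrame singles_frame(const std::vector<SingleRec>& recs) {
  int n = (int)recs.size();
  NumericVector eventId(n), x(n), y(n), z(n), edep(n), tdet(n);
  IntegerVector det(n), ia(n), ib(n);
  LogicalVector scat(n);
  for (int i = 0; i < n; ++i) {
    eventId[i] = recs[i].eventId;
    det[i] = (int)recs[i].det; ia[i] = (int)recs[i].ia; ib[i] = (int)recs[i].ib;
    x[i] = recs[i].x; y[i] = recs[i].y; z[i] = recs[i].z;
    edep[i] = recs[i].edep; tdet[i] = recs[i].tdet;
    scat[i] = recs[i].scattered != 0.0;
  }
  return DataFrame::create(
      Named("eventId") = eventId, Named("det") = det, Named("ia") = ia,
      Named("ib") = ib, Named("x") = x, Named("y") = y, Named("z") = z,
      Named("edep") = edep, Named("time") = tdet, Named("scatter") = scat);
}

// [[Rcpp::export]]
DataFrame cpp_detect_crystal(const NumericMatrix& photons,
                             const List& scanner,
                             const NumericVector& muInc511,
                             const NumericVector& muPe511,
                             const NumericVector& muPeExp) {
  Scanner sc = scanner_from_list(scanner);
  Materials M = materials_from(muInc511, muPe511, muPeExp);
  std::vector<SingleRec> recs;
  SingleRec rec;
  int n = photons.nrow();
  std::vector<double> row(12);
  for (int i = 0; i < n; ++i) {
    if (photons(i, PAL) == 0.0) continue;
    for (int k = 0; k < 12; ++k) row[k] = photons(i, k);
    if (detect_one(row.data(), sc, M, rec)) recs.push_back(rec);
  }
  return singles_frame(recs);
}

// fused decay -> singles chain (avoids materializing the photon matrix)
// [[Rcpp::export]]
DataFrame cpp_simulate_singles(const NumericMatrix& decays,
                               const NumericMatrix& sceneMat,
                               const List& scanner,
                               const NumericVector& muInc511,
                               const NumericVector& muPe511,
                                    const NumericVector& muPeExp,
                               int background, double cutoffKeV,
                               double acollFwhmMrad) {
  Scene scn = scene_from_matrix(sceneMat, background);
  Scanner sc = scanner_from_list(scanner);
  Materials M = materials_from(muInc511, muPe511, muPeExp);
  std::vector<SingleRec> recs;
  recs.reserve(decays.nrow());
  SingleRec rec;
  double sigAcoll = acollFwhmMrad / 2.354820045 * 1e-3;
  double row[12];
  int n = decays.nrow();
  for (int i = 0; i < n; ++i) {
    double cz = 2.0 * unif_rand() - 1.0;
    double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
    double phi = 2.0 * M_PI * unif_rand();
    double d1[3] = {sz * std::cos(phi), sz * std::sin(phi), cz};
    for (int k = 0; k < 2; ++k) {
      row[PX] = decays(i, 0); row[PX + 1] = decays(i, 1); row[PX + 2] = decays(i, 2);
      if (k == 0) {
        row[PDX] = d1[0]; row[PDX + 1] = d1[1]; row[PDX + 2] = d1[2];
      } else {
        double d2[3] = {-d1[0], -d1[1], -d1[2]};
        if (sigAcoll > 0.0) {
          double th = std::fabs(norm_rand()) * sigAcoll;
          rotate_direction(d2, std::cos(th), 2.0 * M_PI * unif_rand());
        }
        row[PDX] = d2[0]; row[PDX + 1] = d2[1]; row[PDX + 2] = d2[2];
      }
      row[PE_] = E511; row[PID] = decays(i, 4); row[PSC] = 0.0;
      row[PAL] = 1.0; row[PPATH] = 0.0; row[PT0] = decays(i, 3);
      propagate_one(row, scn, M, cutoffKeV);
      if (row[PAL] == 0.0) continue;
      if (detect_one(row, sc, M, rec)) recs.push_back(rec);
    }
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return singles_frame(recs);
}

// [[Rcpp::export]]
NumericVector cpp_scene_line_mu(const NumericMatrix& P1, const NumericMatrix& P2,
                                const NumericMatrix& sceneMat,
                                const NumericVector& muInc511,
                                const NumericVector& muPe511,
                                    const NumericVector& muPeExp,
                                int background, double energyKeV) {
  Scene sc = scene_from_matrix(sceneMat, background);
  Materials M = materials_from(muInc511, muPe511, muPeExp);
  int n = P1.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double a[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    double b[3] = {P2(i, 0), P2(i, 1), P2(i, 2)};
    out[i] = line_integral_mu(sc, M, a, b, energyKeV);
  }
  return out;
}

// 1-based primitive index at each point (0 = background), painter's rule
// [[Rcpp::export]]
IntegerVector cpp_point_prims(const NumericMatrix& pts,
                              const NumericMatrix& sceneMat) {
  Scene sc = scene_from_matrix(sceneMat, 0);
  int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = prim_at(sc, pts(i, 0), pts(i, 1), pts(i, 2)) + 1;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_point_materials(const NumericMatrix& pts,
                                  const NumericMatrix& sceneMat,
                                  int background) {
  Scene sc = scene_from_matrix(sceneMat, background);
  int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = material_at(sc, pts(i, 0), pts(i, 1), pts(i, 2)) + 1; // 1-based
  return out;
}
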