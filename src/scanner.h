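#ifndef WTPET_SCANNER_H
#define WTPET_SCANNER_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "scene.h"

// Internal scanner description, all lengths in mm.
// type 1: two flat panels, inner faces at y = +/- halfGap, crystal depth
//         along +|y|; blocks tile x contiguously and z with a pitch that can
//         exceed the block size (axial inter-block gaps).
// type 2: idealized gapless cylindrical ring, crystals between rIn and rOut.
struct Scanner {
  int type;
  int mat; // crystal material index
  // flat panel
  double halfGap, depth, blockX, blockZ, pitchZ, z0, halfX;
  int nbx, nbz;
  // cylindrical
  double rIn, rOut, zHalf, pitchZc, dPhi;
  int nRings, nTang;
};

inline Scanner scanner_from_list(const Rcpp::List& L) {
  Scanner sc;
  sc.type = Rcpp::as<int>(L["type"]);
  sc.mat = Rcpp::as<int>(L["mat"]);
  if (sc.type == 1) {
    sc.halfGap = Rcpp::as<double>(L["halfGap"]);
    sc.depth = Rcpp::as<double>(L["depth"]);
    sc.blockX = Rcpp::as<double>(L["blockX"]);
    sc.blockZ = Rcpp::as<double>(L["blockZ"]);
    sc.pitchZ = Rcpp::as<double>(L["pitchZ"]);
    sc.z0 = Rcpp::as<double>(L["z0"]);
    sc.halfX = Rcpp::as<double>(L["halfX"]);
    sc.nbx = Rcpp::as<int>(L["nbx"]);
    sc.nbz = Rcpp::as<int>(L["nbz"]);
  } else {
    sc.rIn = Rcpp::as<double>(L["rIn"]);
    sc.rOut = Rcpp::as<double>(L["rOut"]);
    sc.zHalf = Rcpp::as<double>(L["zHalf"]);
    sc.pitchZc = Rcpp::as<double>(L["pitchZ"]);
    sc.nRings = Rcpp::as<int>(L["nRings"]);
    sc.nTang = Rcpp::as<int>(L["nTang"]);
    sc.dPhi = 2.0 * M_PI / sc.nTang;
  }
  return sc;
}

struct CrystalInterval { double a, b; };

// is z inside some block of the flat panel's axial tiling?
inline bool flat_in_block_z(const Scanner& sc, double z) {
  double w = z - sc.z0;
  if (w < 0.0) return false;
  int k = (int)std::floor(w / sc.pitchZ);
  if (k >= sc.nbz) return false;
  return (w - k * sc.pitchZ) <= sc.blockZ;
}

// in-crystal intervals along ray p + t d, t > tstart, sorted by entry
inline void crystal_intervals(const Scanner& sc, const double* p,
                              const double* d, std::vector<CrystalInterval>& out) {
  out.clear();
  if (sc.type == 1) {
    double zmax = sc.z0 + (sc.nbz - 1) * sc.pitchZ + sc.blockZ;
    for (int side = 0; side < 2; ++side) {
      double ylo = (side == 0) ? sc.halfGap : -(sc.halfGap + sc.depth);
      double yhi = (side == 0) ? sc.halfGap + sc.depth : -sc.halfGap;
      double t0 = 1e-9, t1 = 1e30;
      if (!slab_clip(p[1], d[1], ylo, yhi, t0, t1)) continue;
      if (!slab_clip(p[0], d[0], -sc.halfX, sc.halfX, t0, t1)) continue;
      if (!slab_clip(p[2], d[2], sc.z0, zmax, t0, t1)) continue;
      if (t1 <= t0) continue;
      if (std::fabs(d[2]) < 1e-12) {
        if (flat_in_block_z(sc, p[2])) out.push_back({t0, t1});
        continue;
      }
      // partition [t0,t1] at every axial block edge crossing
      std::vector<double> ts;
      ts.push_back(t0); ts.push_back(t1);
      for (int k = 0; k < sc.nbz; ++k) {
        double e1 = sc.z0 + k * sc.pitchZ;
        double e2 = e1 + sc.blockZ;
        for (double e : {e1, e2}) {
          double t = (e - p[2]) / d[2];
          if (t > t0 && t < t1) ts.push_back(t);
        }
      }
      std::sort(ts.begin(), ts.end());
      for (size_t k = 0; k + 1 < ts.size(); ++k) {
        double a = ts[k], b = ts[k + 1];
        if (b - a < 1e-9) continue;
        double zm = p[2] + 0.5 * (a + b) * d[2];
        if (flat_in_block_z(sc, zm)) out.push_back({a, b});
      }
    }
    std::sort(out.begin(), out.end(),
              [](const CrystalInterval& x, const CrystalInterval& y) {
                return x.a < y.a;
              });
  } else {
    // annulus rIn..rOut clipped by |z| <= zHalf
    double A = d[0] * d[0] + d[1] * d[1];
    double B = 2.0 * (p[0] * d[0] + p[1] * d[1]);
    double Co = p[0] * p[0] + p[1] * p[1] - sc.rOut * sc.rOut;
    double o0 = 1e-9, o1 = 1e30;
    if (!quad_clip(A, B, Co, o0, o1)) return;
    if (!slab_clip(p[2], d[2], -sc.zHalf, sc.zHalf, o0, o1)) return;
    if (o1 <= o0) return;
    // subtract the inner cylinder
    double Ci = p[0] * p[0] + p[1] * p[1] - sc.rIn * sc.rIn;
    double i0 = -1e30, i1 = 1e30;
    bool hitInner = quad_clip(A, B, Ci, i0, i1);
    if (!hitInner) { out.push_back({o0, o1}); return; }
    if (i0 > o0 + 1e-9) out.push_back({o0, std::min(i0, o1)});
    if (i1 < o1 - 1e-9 && i1 > o0) out.push_back({std::max(i1, o0), o1});
    if (i1 <= o0 || i0 >= o1) { out.clear(); out.push_back({o0, o1}); }
  }
}

// readout-region id of a point: deposits are merged per region, matching
// an adder+readout digitizer. For flat panels the region is the
// monolithic block; for the cylindrical scanner the detector block.
inline long readout_region(const Scanner& sc, double x, double y, double z) {
  if (sc.type == 1) {
    int det = (y > 0.0) ? 0 : 1;
    int ia = (int)std::floor((x + sc.halfX) / sc.blockX);
    int ib = (int)std::floor((z - sc.z0) / sc.pitchZ);
    return ((long)det * sc.nbx + ia) * (sc.nbz + 1) + ib;
  }
  // pixelated readout: detector block of 10 x 10 crystals (~33 x 33 mm),
  // the energy-summing scope of the block-level readout electronics
  double phi = std::atan2(y, x);
  if (phi < 0.0) phi += 2.0 * M_PI;
  int ia = (int)std::floor(phi / sc.dPhi) / 10;
  int ib = (int)std::floor((z + sc.zHalf) / sc.pitchZc) / 10;
  return (long)ia * 100000L + ib;
}

// crystal address of a point known to lie in (or next to) the detector
inline void crystal_address(const Scanner& sc, double x, double y, double z,
                            int& det, int& ia, int& ib) {
  if (sc.type == 1) {
    det = (y > 0.0) ? 0 : 1;
    ia = (int)std::floor((x + sc.halfX) / sc.blockX);
    if (ia < 0) ia = 0; if (ia >= sc.nbx) ia = sc.nbx - 1;
    ib = (int)std::floor((z - sc.z0) / sc.pitchZ);
    if (ib < 0) ib = 0; if (ib >= sc.nbz) ib = sc.nbz - 1;
  } else {
    det = 0;
    double phi = std::atan2(y, x);
    if (phi < 0.0) phi += 2.0 * M_PI;
    ia = (int)std::floor(phi / sc.dPhi);
    if (ia >= sc.nTang) ia = sc.nTang - 1;
    ib = (int)std::floor((z + sc.zHalf) / sc.pitchZc);
    if (ib < 0) ib = 0; if (ib >= sc.nRings) ib = sc.nRings - 1;
  }
}

#endif
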