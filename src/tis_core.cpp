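// Core numerics for the TIS coarse-grained RNA model:
//   - energy/force evaluation (bond, angle, excluded volume, H-bond,
//     stacking, electrostatics) under the minimum-image convention
//   - underdamped Langevin (BAOAB) and Brownian (Ermak-McCammon) propagators
// Units: kcal/mol, nm, ps, amu, elementary charge.
// 1 kcal/mol = 4.184 amu nm^2/ps^2.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>

using namespace Rcpp;

static const double KCAL2INT = 4.184;    // amu nm^2/ps^2 per kcal/mol

// ---------------------------------------------------------------------------
// counter-based RNG: splitmix64 hash of (seed, step, stream index), so that
// trajectories are reproducible and restartable from any absolute step.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97f4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}
static inline double u01(uint64_t seed, uint64_t step, uint64_t idx) {
  uint64_t h = splitmix64(seed ^ splitmix64(step ^ splitmix64(idx + 0x632BE59BD9B4E019ULL)));
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}
static inline double gaussrn(uint64_t seed, uint64_t step, uint64_t idx) {
  double u1 = u01(seed, step, 2 * idx);
  double u2 = u01(seed, step, 2 * idx + 1);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// ---------------------------------------------------------------------------
struct Sys {
  int n;                       // total sites (RNA beads then ions)
  double box;                  // box edge (nm); <=0 means open boundaries
  std::vector<double> charge, radius;
  std::vector<int> bi, bj;     std::vector<double> br0;
  std::vector<int> ai, aj, ak; std::vector<double> ath0;
  std::unordered_set<int64_t> excl;      // 1-2 and 1-3 pairs
  std::vector<int> baseIdx, sugarIdx;    // per residue, 0-based, -1 if none
  int nres;
  std::vector<int> comp;                 // nres*nres complementarity
  std::unordered_map<int64_t, int> natPair;
  std::vector<double> natR0, natTh1, natTh2, natEps;
  std::vector<int> thbI, thbJ; std::vector<double> thbR0, thbEps;
  std::vector<int> stI, stJ, stTert;  std::vector<double> stR0, stEps;
  std::vector<int> charged;              // indices with charge != 0
  // parameters
  double kBond, kAngle, epsEv, epsHbNN, krHb, kthHb, hbR0, hbTh0, hbCapture;
  int hbMinSep;
  double krSt, eleCutoff, coulPref, kT;
  bool mBond, mAngle, mEv, mHb, mSt, mEle;
};

static inline int64_t pkey(int i, int j) {
  if (i > j) std::swap(i, j);
  return (int64_t)i * 2000003LL + j;
}

static Sys buildSys(const List& s) {
  Sys y;
  y.n = as<int>(s["n"]);
  y.box = as<double>(s["box"]);
  if (!R_finite(y.box)) y.box = -1.0;
  y.charge = as<std::vector<double> >(s["charge"]);
  y.radius = as<std::vector<double> >(s["radius"]);
  y.bi = as<std::vector<int> >(s["bondI"]);  y.bj = as<std::vector<int> >(s["bondJ"]);
  y.br0 = as<std::vector<double> >(s["bondR0"]);
  y.ai = as<std::vector<int> >(s["angI"]);   y.aj = as<std::vector<int> >(s["angJ"]);
  y.ak = as<std::vector<int> >(s["angK"]);   y.ath0 = as<std::vector<double> >(s["angTh0"]);
  y.baseIdx = as<std::vector<int> >(s["baseIdx"]);
  y.sugarIdx = as<std::vector<int> >(s["sugarIdx"]);
  y.nres = (int)y.baseIdx.size();
  y.comp = as<std::vector<int> >(s["comp"]);
  std::vector<int> npI = as<std::vector<int> >(s["natResI"]);
  std::vector<int> npJ = as<std::vector<int> >(s["natResJ"]);
  y.natR0 = as<std::vector<double> >(s["natR0"]);
  y.natTh1 = as<std::vector<double> >(s["natTh1"]);
  y.natTh2 = as<std::vector<double> >(s["natTh2"]);
  y.natEps = as<std::vector<double> >(s["natEps"]);
  for (size_t k = 0; k < npI.size(); ++k) y.natPair[pkey(npI[k], npJ[k])] = (int)k;
  y.thbI = as<std::vector<int> >(s["thbI"]); y.thbJ = as<std::vector<int> >(s["thbJ"]);
  y.thbR0 = as<std::vector<double> >(s["thbR0"]);
  y.thbEps = as<std::vector<double> >(s["thbEps"]);
  y.stI = as<std::vector<int> >(s["stI"]);   y.stJ = as<std::vector<int> >(s["stJ"]);
  y.stTert = as<std::vector<int> >(s["stTert"]);
  y.stR0 = as<std::vector<double> >(s["stR0"]);
  y.stEps = as<std::vector<double> >(s["stEps"]);
  // exclusions: bonds and angle end pairs
  for (size_t k = 0; k < y.bi.size(); ++k) y.excl.insert(pkey(y.bi[k], y.bj[k]));
  for (size_t k = 0; k < y.ai.size(); ++k) {
    y.excl.insert(pkey(y.ai[k], y.ak[k]));
    y.excl.insert(pkey(y.ai[k], y.aj[k]));
    y.excl.insert(pkey(y.aj[k], y.ak[k]));
  }
  for (int i = 0; i < y.n; ++i) if (y.charge[i] != 0.0) y.charged.push_back(i);
  y.kBond = as<double>(s["kBond"]);     y.kAngle = as<double>(s["kAngle"]);
  y.epsEv = as<double>(s["epsEv"]);     y.epsHbNN = as<double>(s["epsHbNonnative"]);
  y.krHb = as<double>(s["krHb"]);       y.kthHb = as<double>(s["kthHb"]);
  y.hbR0 = as<double>(s["hbR0"]);       y.hbTh0 = as<double>(s["hbTheta0"]);
  y.hbCapture = as<double>(s["hbCapture"]);
  y.hbMinSep = as<int>(s["hbMinSep"]);
  y.krSt = as<double>(s["krSt"]);
  y.eleCutoff = as<double>(s["eleCutoff"]);
  y.coulPref = as<double>(s["coulPref"]);
  y.kT = as<double>(s["kT"]);
  y.mBond = y.mAngle = y.mEv = y.mHb = y.mSt = y.mEle = true;
  return y;
}

static inline void mimg(double& dx, double& dy, double& dz, double box) {
  if (box > 0) {
    dx -= box * std::nearbyint(dx / box);
    dy -= box * std::nearbyint(dy / box);
    dz -= box * std::nearbyint(dz / box);
  }
}

struct Vec3 { double x, y, z; };

// cos(angle a-b-c), apex b, and its gradient wrt the three vertices.
// Working in cos(theta) keeps forces regular at straight angles, where the
// gradient of theta itself is singular.
static inline double cosAngleGrad(const double* A, const double* B,
                                  const double* C, double box,
                                  Vec3& gA, Vec3& gB, Vec3& gC) {
  double ux = A[0] - B[0], uy = A[1] - B[1], uz = A[2] - B[2];
  double vx = C[0] - B[0], vy = C[1] - B[1], vz = C[2] - B[2];
  mimg(ux, uy, uz, box); mimg(vx, vy, vz, box);
  double lu = std::sqrt(ux * ux + uy * uy + uz * uz);
  double lv = std::sqrt(vx * vx + vy * vy + vz * vz);
  double ct = (ux * vx + uy * vy + uz * vz) / (lu * lv);
  if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
  gA.x = vx / (lu * lv) - ct * ux / (lu * lu);
  gA.y = vy / (lu * lv) - ct * uy / (lu * lu);
  gA.z = vz / (lu * lv) - ct * uz / (lu * lu);
  gC.x = ux / (lu * lv) - ct * vx / (lv * lv);
  gC.y = uy / (lu * lv) - ct * vy / (lv * lv);
  gC.z = uz / (lu * lv) - ct * vz / (lv * lv);
  gB.x = -(gA.x + gC.x); gB.y = -(gA.y + gC.y); gB.z = -(gA.z + gC.z);
  return ct;
}

struct EnergyOut {
  double bond, angle, ev, hbSec, hbTer, stSec, stTer, ele;
  std::vector<int> pResI, pResJ, pNative;
  std::vector<double> pE;
  std::vector<double> thbE, stE;
};

// full energy/force evaluation; F may be NULL
static EnergyOut energy(const Sys& y, const double* X, double* F) {
  EnergyOut o; o.bond = o.angle = o.ev = o.hbSec = o.hbTer = o.stSec = o.stTer = o.ele = 0.0;
  const double box = y.box;
  int n = y.n;
  auto addF = [&](int i, double fx, double fy, double fz) {
    if (F) { F[3 * i] += fx; F[3 * i + 1] += fy; F[3 * i + 2] += fz; }
  };
  // --- bonds
  if (y.mBond) for (size_t k = 0; k < y.bi.size(); ++k) {
    int i = y.bi[k], j = y.bj[k];
    double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1], dz = X[3 * i + 2] - X[3 * j + 2];
    mimg(dx, dy, dz, box);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - y.br0[k];
    o.bond += y.kBond * dr * dr;
    double c = -2.0 * y.kBond * dr / r;
    addF(i, c * dx, c * dy, c * dz);
    addF(j, -c * dx, -c * dy, -c * dz);
  }
  // --- angles: cosine-harmonic, U = k (cos th - cos th0)^2
  if (y.mAngle) for (size_t k = 0; k < y.ai.size(); ++k) {
    Vec3 gA, gB, gC;
    double ct = cosAngleGrad(X + 3 * y.ai[k], X + 3 * y.aj[k], X + 3 * y.ak[k], box, gA, gB, gC);
    double dct = ct - std::cos(y.ath0[k]);
    o.angle += y.kAngle * dct * dct;
    double c = -2.0 * y.kAngle * dct;
    addF(y.ai[k], c * gA.x, c * gA.y, c * gA.z);
    addF(y.aj[k], c * gB.x, c * gB.y, c * gB.z);
    addF(y.ak[k], c * gC.x, c * gC.y, c * gC.z);
  }
  // --- excluded volume (purely repulsive shifted LJ), all non-excluded pairs
  if (y.mEv) for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = y.radius[i] + y.radius[j];
      double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1], dz = X[3 * i + 2] - X[3 * j + 2];
      mimg(dx, dy, dz, box);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= s * s) continue;
      if (y.excl.count(pkey(i, j))) continue;
      double r = std::sqrt(r2);
      if (r < 1e-6)
        stop("overlapping sites %d and %d (distance < 1e-6 nm)", i + 1, j + 1);
      double q = s / r;
      double q6 = q * q * q; q6 *= q6;
      o.ev += y.epsEv * (q6 * q6 - 2.0 * q6 + 1.0);
      double dUdr = y.epsEv * 12.0 * (-q6 * q6 + q6) / r;
      double c = -dUdr / r;
      addF(i, c * dx, c * dy, c * dz);
      addF(j, -c * dx, -c * dy, -c * dz);
    }
  }
  // --- hydrogen bonds: dynamic secondary pairing + registered tertiary
  if (y.mHb) {
    struct Cand { int ri, rj; double E, r, th1, th2, r0, t10, t20, eps; bool nat, ang; };
    std::vector<Cand> cands;
    for (int ri = 0; ri < y.nres - 1; ++ri) {
      int bi_ = y.baseIdx[ri]; if (bi_ < 0) continue;
      for (int rj = ri + y.hbMinSep; rj < y.nres; ++rj) {
        if (!y.comp[ri * y.nres + rj]) continue;
        int bj_ = y.baseIdx[rj]; if (bj_ < 0) continue;
        double r0 = y.hbR0, t10 = y.hbTh0, t20 = y.hbTh0, eps = y.epsHbNN;
        bool nat = false;
        auto it = y.natPair.find(pkey(ri, rj));
        if (it != y.natPair.end()) {
          nat = true; r0 = y.natR0[it->second];
          t10 = y.natTh1[it->second]; t20 = y.natTh2[it->second];
          eps = y.natEps[it->second];
        }
        double dx = X[3 * bi_] - X[3 * bj_], dy = X[3 * bi_ + 1] - X[3 * bj_ + 1], dz = X[3 * bi_ + 2] - X[3 * bj_ + 2];
        mimg(dx, dy, dz, box);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (std::fabs(r - r0) >= y.hbCapture) continue;
        int si = y.sugarIdx[ri], sj = y.sugarIdx[rj];
        bool ang = (si >= 0 && sj >= 0 && y.kthHb > 0);
        // angular modulation in cos(theta) (regular at straight angles)
        double ct1 = std::cos(t10), ct2 = std::cos(t20);
        if (ang) {
          Vec3 g1, g2, g3;
          ct1 = cosAngleGrad(X + 3 * si, X + 3 * bi_, X + 3 * bj_, box, g1, g2, g3);
          ct2 = cosAngleGrad(X + 3 * bi_, X + 3 * bj_, X + 3 * sj, box, g1, g2, g3);
        }
        double dr = r - r0;
        double d1 = ct1 - std::cos(t10), d2 = ct2 - std::cos(t20);
        double E = -eps * std::exp(-y.krHb * dr * dr - y.kthHb * (d1 * d1 + d2 * d2));
        Cand c; c.ri = ri; c.rj = rj; c.E = E; c.r = r; c.th1 = ct1; c.th2 = ct2;
        c.r0 = r0; c.t10 = std::cos(t10); c.t20 = std::cos(t20);
        c.eps = eps; c.nat = nat; c.ang = ang;
        cands.push_back(c);
      }
    }
    // one secondary partner per base: strongest (most negative) wins,
    // ties broken by lower residue index
    std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
      if (a.E != b.E) return a.E < b.E;
      if (a.ri != b.ri) return a.ri < b.ri;
      return a.rj < b.rj;
    });
    std::vector<char> used(y.nres, 0);
    for (const Cand& c : cands) {
      if (used[c.ri] || used[c.rj]) continue;
      used[c.ri] = used[c.rj] = 1;
      o.hbSec += c.E;
      o.pResI.push_back(c.ri + 1); o.pResJ.push_back(c.rj + 1);
      o.pE.push_back(c.E); o.pNative.push_back(c.nat ? 1 : 0);
      if (F) {
        int bi_ = y.baseIdx[c.ri], bj_ = y.baseIdx[c.rj];
        double dx = X[3 * bi_] - X[3 * bj_], dy = X[3 * bi_ + 1] - X[3 * bj_ + 1], dz = X[3 * bi_ + 2] - X[3 * bj_ + 2];
        mimg(dx, dy, dz, box);
        double r = c.r, dr = r - c.r0;
        // radial part
        double cc = -c.E * 2.0 * y.krHb * dr / r;   // -dU/dr * rhat sign handled below
        addF(bi_, -cc * dx, -cc * dy, -cc * dz);
        addF(bj_, cc * dx, cc * dy, cc * dz);
        if (c.ang) {
          int si = y.sugarIdx[c.ri], sj = y.sugarIdx[c.rj];
          Vec3 gA, gB, gC;
          cosAngleGrad(X + 3 * si, X + 3 * bi_, X + 3 * bj_, box, gA, gB, gC);
          double c1 = c.E * 2.0 * y.kthHb * (c.th1 - c.t10); // = -dU/dcos
          addF(si, c1 * gA.x, c1 * gA.y, c1 * gA.z);
          addF(bi_, c1 * gB.x, c1 * gB.y, c1 * gB.z);
          addF(bj_, c1 * gC.x, c1 * gC.y, c1 * gC.z);
          cosAngleGrad(X + 3 * bi_, X + 3 * bj_, X + 3 * sj, box, gA, gB, gC);
          double c2 = c.E * 2.0 * y.kthHb * (c.th2 - c.t20);
          addF(bi_, c2 * gA.x, c2 * gA.y, c2 * gA.z);
          addF(bj_, c2 * gB.x, c2 * gB.y, c2 * gB.z);
          addF(sj, c2 * gC.x, c2 * gC.y, c2 * gC.z);
        }
      }
    }
    // registered tertiary H-bonds: plain distance wells between beads
    for (size_t k = 0; k < y.thbI.size(); ++k) {
      int i = y.thbI[k], j = y.thbJ[k];
      double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1], dz = X[3 * i + 2] - X[3 * j + 2];
      mimg(dx, dy, dz, box);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dr = r - y.thbR0[k];
      double E = -y.thbEps[k] * std::exp(-y.krHb * dr * dr);
      o.hbTer += E; o.thbE.push_back(E);
      double cc = -E * 2.0 * y.krHb * dr / r;
      addF(i, -cc * dx, -cc * dy, -cc * dz);
      addF(j, cc * dx, cc * dy, cc * dz);
    }
  } else {
    o.thbE.assign(y.thbI.size(), 0.0);
  }
  // --- stacking: distance Gaussian wells
  if (y.mSt) for (size_t k = 0; k < y.stI.size(); ++k) {
    int i = y.stI[k], j = y.stJ[k];
    double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1], dz = X[3 * i + 2] - X[3 * j + 2];
    mimg(dx, dy, dz, box);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - y.stR0[k];
    double E = -y.stEps[k] * std::exp(-y.krSt * dr * dr);
    if (y.stTert[k]) o.stTer += E; else o.stSec += E;
    o.stE.push_back(E);
    double cc = -E * 2.0 * y.krSt * dr / r;
    addF(i, -cc * dx, -cc * dy, -cc * dz);
    addF(j, cc * dx, cc * dy, cc * dz);
  } else {
    o.stE.assign(y.stI.size(), 0.0);
  }
  // --- electrostatics: truncated-and-shifted minimum-image Coulomb
  if (y.mEle) {
    double rc = y.eleCutoff;
    bool useCut = R_finite(rc) && rc > 0;
    for (size_t a = 0; a + 1 < y.charged.size(); ++a) {
      int i = y.charged[a];
      for (size_t b = a + 1; b < y.charged.size(); ++b) {
        int j = y.charged[b];
        if (y.excl.count(pkey(i, j))) continue;
        double dx = X[3 * i] - X[3 * j], dy = X[3 * i + 1] - X[3 * j + 1], dz = X[3 * i + 2] - X[3 * j + 2];
        mimg(dx, dy, dz, box);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (useCut && r2 >= rc * rc) continue;
        double r = std::sqrt(r2);
        if (r < 1e-6)
          stop("overlapping charged sites %d and %d", i + 1, j + 1);
        double qq = y.coulPref * y.charge[i] * y.charge[j];
        o.ele += useCut ? qq * (1.0 / r - 1.0 / rc) : qq / r;
        double c = qq / (r2 * r);   // -dU/dr / r with dU/dr = -qq/r^2
        addF(i, c * dx, c * dy, c * dz);
        addF(j, -c * dx, -c * dy, -c * dz);
      }
    }
  }
  return o;
}

static List outEnergy(const Sys& y, const EnergyOut& o, const double* F, int n) {
  NumericVector terms = NumericVector::create(
    _["bond"] = o.bond, _["angle"] = o.angle, _["ev"] = o.ev,
    _["hbSecondary"] = o.hbSec, _["hbTertiary"] = o.hbTer,
    _["stSecondary"] = o.stSec, _["stTertiary"] = o.stTer, _["ele"] = o.ele);
  double total = o.bond + o.angle + o.ev + o.hbSec + o.hbTer + o.stSec +
    o.stTer + o.ele;
  List out = List::create(
    _["terms"] = terms, _["total"] = total,
    _["pairsResI"] = wrap(o.pResI), _["pairsResJ"] = wrap(o.pResJ),
    _["pairsE"] = wrap(o.pE), _["pairsNative"] = wrap(o.pNative),
    _["thbE"] = wrap(o.thbE), _["stE"] = wrap(o.stE));
  if (F) {
    NumericMatrix Fm(n, 3);
    for (int i = 0; i < n; ++i) {
      Fm(i, 0) = F[3 * i]; Fm(i, 1) = F[3 * i + 1]; Fm(i, 2) = F[3 * i + 2];
    }
    out["forces"] = Fm;
  }
  return out;
}

// [[Rcpp::export(name = ".cg_energy_cpp")]]
List cg_energy_cpp(NumericMatrix coords, List sysList, LogicalVector mask,
                   bool wantForces) {
  Sys y = buildSys(sysList);
  if (mask.size() == 6) {
    y.mBond = mask[0]; y.mAngle = mask[1]; y.mEv = mask[2];
    y.mHb = mask[3]; y.mSt = mask[4]; y.mEle = mask[5];
  }
  int n = y.n;
  if (coords.nrow() != n) stop("coordinate/site count mismatch");
  std::vector<double> X(3 * n), F(3 * n, 0.0);
  for (int i = 0; i < n; ++i) {
    X[3 * i] = coords(i, 0); X[3 * i + 1] = coords(i, 1); X[3 * i + 2] = coords(i, 2);
  }
  EnergyOut o = energy(y, X.data(), wantForces ? F.data() : (double*)nullptr);
  return outEnergy(y, o, wantForces ? F.data() : (double*)nullptr, n);
}

static inline void wrapX(std::vector<double>& X, int n, double box) {
  if (box <= 0) return;
  for (int k = 0; k < 3 * n; ++k) X[k] -= box * std::floor(X[k] / box);
}

// ---------------------------------------------------------------------------
// Brownian dynamics (Ermak-McCammon, free-draining):
//   dx = (D/kT) F dt + sqrt(2 D dt) xi
// with per-site diffusion coefficients D (nm^2/ps) and a safety threshold:
// a step moving any site farther than maxDisp is redrawn at half the step,
// applied twice (recursively, bounded depth).
struct BDCtx {
  const Sys* y;
  const std::vector<double>* D;
  double kTint, maxDisp;
  uint64_t seed;
  int nRejected;
};

static void bdAdvance(BDCtx& c, std::vector<double>& X, uint64_t step,
                      double dt, int depth, uint64_t sub) {
  const Sys& y = *c.y;
  int n = y.n;
  std::vector<double> F(3 * n, 0.0);
  energy(y, X.data(), F.data());
  std::vector<double> dX(3 * n);
  double md2 = c.maxDisp * c.maxDisp;
  bool bad = false;
  for (int i = 0; i < n; ++i) {
    double Di = (*c.D)[i];
    double drift = Di / c.kTint * KCAL2INT * dt;  // F kcal/mol/nm -> internal
    double sig = std::sqrt(2.0 * Di * dt);
    double ddx = 0, dd2 = 0;
    for (int d = 0; d < 3; ++d) {
      ddx = drift * F[3 * i + d] + sig * gaussrn(c.seed, step, sub * 3ULL * n + 3ULL * i + d);
      dX[3 * i + d] = ddx;
      dd2 += ddx * ddx;
    }
    if (dd2 > md2) bad = true;
  }
  if (bad && depth < 6) {
    c.nRejected++;
    bdAdvance(c, X, step, dt / 2, depth + 1, 2 * sub + 1);
    bdAdvance(c, X, step, dt / 2, depth + 1, 2 * sub + 2);
    return;
  }
  if (bad) {
    // recursion exhausted: clamp each site's displacement to the threshold
    for (int i = 0; i < n; ++i) {
      double dd2 = dX[3 * i] * dX[3 * i] + dX[3 * i + 1] * dX[3 * i + 1] +
        dX[3 * i + 2] * dX[3 * i + 2];
      if (dd2 > md2) {
        double sc = c.maxDisp / std::sqrt(dd2);
        dX[3 * i] *= sc; dX[3 * i + 1] *= sc; dX[3 * i + 2] *= sc;
      }
    }
  }
  for (int k = 0; k < 3 * n; ++k) X[k] += dX[k];
  wrapX(X, n, y.box);
}

// [[Rcpp::export(name = ".cg_bd_cpp")]]
List cg_bd_cpp(NumericMatrix coords, List sysList, NumericVector D,
               double dt, int nSteps, int saveEvery, double seed,
               double stepOffset, double maxDisp) {
  Sys y = buildSys(sysList);
  int n = y.n;
  if (coords.nrow() != n || D.size() != n) stop("size mismatch");
  std::vector<double> X(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) X[3 * i + d] = coords(i, d);
  wrapX(X, n, y.box);
  std::vector<double> Dv = as<std::vector<double> >(D);
  BDCtx c; c.y = &y; c.D = &Dv; c.kTint = y.kT * KCAL2INT;
  c.maxDisp = maxDisp; c.seed = (uint64_t)seed; c.nRejected = 0;
  int nSave = nSteps / saveEvery;
  NumericVector frames((R_xlen_t)(nSave + 1) * n * 3);
  frames.attr("dim") = IntegerVector::create(nSave + 1, n, 3);
  int nf = nSave + 1;
  auto store = [&](int f) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        frames[f + (R_xlen_t)nf * i + (R_xlen_t)nf * n * d] = X[3 * i + d];
  };
  store(0);
  for (int s = 1; s <= nSteps; ++s) {
    bdAdvance(c, X, (uint64_t)(stepOffset) + s, dt, 0, 0);
    if (s % saveEvery == 0) store(s / saveEvery);
    if (s % 8192 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["frames"] = frames, _["nRejected"] = c.nRejected,
                      _["finalStep"] = stepOffset + nSteps);
}

// ---------------------------------------------------------------------------
// Underdamped Langevin, BAOAB splitting. mass amu, gamma amu/ps.
// [[Rcpp::export(name = ".cg_langevin_cpp")]]
List cg_langevin_cpp(NumericMatrix coords, NumericMatrix vel, List sysList,
                     NumericVector mass, NumericVector gamma, double dt,
                     int nSteps, int saveEvery, double seed, double stepOffset) {
  Sys y = buildSys(sysList);
  int n = y.n;
  if (coords.nrow() != n || vel.nrow() != n) stop("size mismatch");
  std::vector<double> X(3 * n), V(3 * n), F(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      X[3 * i + d] = coords(i, d); V[3 * i + d] = vel(i, d);
    }
  wrapX(X, n, y.box);
  double kTint = y.kT * KCAL2INT;
  std::vector<double> c1(n), c2(n), halfm(n);
  for (int i = 0; i < n; ++i) {
    c1[i] = std::exp(-gamma[i] / mass[i] * dt);
    c2[i] = std::sqrt(kTint / mass[i] * (1.0 - c1[i] * c1[i]));
    halfm[i] = 0.5 * dt * KCAL2INT / mass[i];
  }
  int nSave = nSteps / saveEvery;
  NumericVector frames((R_xlen_t)(nSave + 1) * n * 3);
  frames.attr("dim") = IntegerVector::create(nSave + 1, n, 3);
  int nf = nSave + 1;
  auto store = [&](int f) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        frames[f + (R_xlen_t)nf * i + (R_xlen_t)nf * n * d] = X[3 * i + d];
  };
  store(0);
  energy(y, X.data(), F.data());
  uint64_t sd = (uint64_t)seed;
  for (int s = 1; s <= nSteps; ++s) {
    uint64_t step = (uint64_t)stepOffset + s;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) V[3 * i + d] += halfm[i] * F[3 * i + d];
    for (int k = 0; k < 3 * n; ++k) X[k] += 0.5 * dt * V[k];
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        V[3 * i + d] = c1[i] * V[3 * i + d] + c2[i] * gaussrn(sd, step, 3ULL * i + d);
    for (int k = 0; k < 3 * n; ++k) X[k] += 0.5 * dt * V[k];
    wrapX(X, n, y.box);
    std::fill(F.begin(), F.end(), 0.0);
    energy(y, X.data(), F.data());
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) V[3 * i + d] += halfm[i] * F[3 * i + d];
    if (s % saveEvery == 0) store(s / saveEvery);
    if (s % 8192 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix Vm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) Vm(i, d) = V[3 * i + d];
  return List::create(_["frames"] = frames, _["finalVel"] = Vm,
                      _["finalStep"] = stepOffset + nSteps);
}
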