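#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise energy accumulation over non-hydrogen atoms within a distance
// cutoff.  Pairs inside one residue or between backbone-adjacent residues of
// the same chain are excluded (they are held rigid or near-rigid by the
// kinematics and would otherwise dominate the repulsive term).
//
// Pair classes:
//   intra : both atoms in the same partner group (light, heavy or antigen)
//   vlvh  : light <-> heavy cross pairs
//   abag  : (light|heavy) <-> antigen cross pairs
//
// Returns a 9-vector: rep/att/elec sums for intra, vlvh, abag.
// rep  = sum max(0, (rsum - d)/rsum)^2            (soft-sphere repulsion)
// att  = sum -exp(-(d - rsum)^2 / (2 sigma^2))    (contact well)
// elec = sum 83 * qi * qj / d^2                    (Coulomb, eps = 4 d)
// [[Rcpp::export]]
NumericVector pairTermsCpp(NumericMatrix xyz, NumericVector vdw,
                           NumericVector charge, IntegerVector group,
                           IntegerVector resUid, IntegerVector resno,
                           IntegerVector chainIdx, LogicalVector heavy,
                           double cutoff, double sigma) {
  const int n = xyz.nrow();
  const double cut2 = cutoff * cutoff;
  double rep[3] = {0, 0, 0}, att[3] = {0, 0, 0}, ele[3] = {0, 0, 0};
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double *X = &xyz(0, 0), *Y = X + n, *Z = Y + n;

  for (int i = 0; i < n - 1; ++i) {
    if (!heavy[i]) continue;
    const double xi = X[i], yi = Y[i], zi = Z[i];
    for (int j = i + 1; j < n; ++j) {
      if (!heavy[j]) continue;
      if (resUid[i] == resUid[j]) continue;
      if (chainIdx[i] == chainIdx[j] &&
          (resno[i] - resno[j] == 1 || resno[j] - resno[i] == 1))
        continue;
      const double dx = xi - X[j];
      const double dy = yi - Y[j];
      const double dz = zi - Z[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > cut2) continue;
      const double rsum = vdw[i] + vdw[j];
      const double attLim = rsum + 4.0 * sigma;
      const bool hasQ = charge[i] != 0.0 && charge[j] != 0.0;
      if (d2 > attLim * attLim && !hasQ) continue;
      const double d = std::sqrt(d2);

      int cls;  // 0 intra, 1 vlvh, 2 abag
      if (group[i] == group[j]) {
        cls = 0;
      } else if (group[i] == 3 || group[j] == 3) {
        cls = 2;
      } else {
        cls = 1;
      }

      if (d < rsum) {
        const double x = (rsum - d) / rsum;
        rep[cls] += x * x;
      }
      const double dd = d - rsum;
      if (dd < 4.0 * sigma) att[cls] += -std::exp(-dd * dd * inv2s2);
      if (hasQ) {
        // clamp below 2 A so the Coulomb term cannot overwhelm the
        // bounded repulsion at vanishing separation
        const double d2e = d2 < 4.0 ? 4.0 : d2;
        ele[cls] += 83.0 * charge[i] * charge[j] / d2e;
      }
    }
  }
  NumericVector out = NumericVector::create(
      rep[0], att[0], ele[0], rep[1], att[1], ele[1], rep[2], att[2], ele[2]);
  out.attr("names") = CharacterVector::create(
      "rep_intra", "att_intra", "elec_intra", "rep_vlvh", "att_vlvh",
      "elec_vlvh", "rep_abag", "att_abag", "elec_abag");
  return out;
}

// Minimal van der Waals gap (d - ri - rj) over cross pairs between two atom
// index sets (1-based), non-hydrogen atoms only.  Used by slide-into-contact.
// [[Rcpp::export]]
double minGapCpp(NumericMatrix xyz, NumericVector vdw, LogicalVector heavy,
                 IntegerVector setA, IntegerVector setB) {
  double best = R_PosInf;
  for (int a = 0; a < setA.size(); ++a) {
    const int i = setA[a] - 1;
    if (!heavy[i]) continue;
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int b = 0; b < setB.size(); ++b) {
      const int j = setB[b] - 1;
      if (!heavy[j]) continue;
      const double dx = xi - xyz(j, 0);
      const double dy = yi - xyz(j, 1);
      const double dz = zi - xyz(j, 2);
      const double gap =
          std::sqrt(dx * dx + dy * dy + dz * dz) - vdw[i] - vdw[j];
      if (gap < best) best = gap;
    }
  }
  return best;
}

// Cross-pair residue contact and proximity queries used by the interface
// (10 A) and native-contact (5 A) definitions.  Returns the minimal heavy-atom
// distance for every (uidA, uidB) residue pair listed.
// [[Rcpp::export]]
NumericVector residuePairMinDistCpp(NumericMatrix xyz, LogicalVector heavy,
                                    IntegerVector resUid, IntegerVector uidA,
                                    IntegerVector uidB) {
  const int n = xyz.nrow();
  const int np = uidA.size();
  NumericVector out(np, R_PosInf);
  // index atoms by residue uid
  std::map<int, std::vector<int> > byRes;
  for (int i = 0; i < n; ++i)
    if (heavy[i]) byRes[resUid[i]].push_back(i);
  for (int p = 0; p < np; ++p) {
    std::vector<int> &A = byRes[uidA[p]];
    std::vector<int> &B = byRes[uidB[p]];
    double best = R_PosInf;
    for (size_t a = 0; a < A.size(); ++a) {
      const int i = A[a];
      for (size_t b = 0; b < B.size(); ++b) {
        const int j = B[b];
        const double dx = xyz(i, 0) - xyz(j, 0);
        const double dy = xyz(i, 1) - xyz(j, 1);
        const double dz = xyz(i, 2) - xyz(j, 2);
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// ---- CCD loop closure kernel ----------------------------------------------

static inline void vsub(const double *a, const double *b, double *o) {
  o[0] = a[0] - b[0]; o[1] = a[1] - b[1]; o[2] = a[2] - b[2];
}
static inline void vcross(const double *a, const double *b, double *o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vlen(const double *a) { return std::sqrt(vdot(a, a)); }
static inline void vunit(double *a) {
  double n = vlen(a);
  a[0] /= n; a[1] /= n; a[2] /= n;
}

// signed dihedral a-b-c-d in degrees, same convention as the R dihedral4()
static double dihedralC(const double *a, const double *b, const double *c,
                        const double *d) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], m1[3], b2h[3];
  vsub(b, a, b1); vsub(c, b, b2); vsub(d, c, b3);
  vcross(b1, b2, n1); vcross(b2, b3, n2);
  b2h[0] = b2[0]; b2h[1] = b2[1]; b2h[2] = b2[2];
  vunit(b2h);
  vcross(n1, b2h, m1);
  double ang = -std::atan2(vdot(m1, n2), vdot(n1, n2)) * 180.0 / M_PI;
  if (ang <= -180.0) ang += 360.0;
  return ang;
}

// NeRF placement, same convention as the R placeAtom()
static void placeAtomC(const double *a, const double *b, const double *c,
                       double bond, double angle, double torsion, double *out) {
  double th = angle * M_PI / 180.0, ph = torsion * M_PI / 180.0;
  double bc[3], ab[3], n[3], m[3];
  vsub(c, b, bc); vunit(bc);
  vsub(b, a, ab);
  vcross(ab, bc, n); vunit(n);
  vcross(n, bc, m);
  double d1 = -bond * std::cos(th);
  double d2 = bond * std::sin(th) * std::cos(ph);
  double d3 = bond * std::sin(th) * std::sin(ph);
  for (int k = 0; k < 3; ++k)
    out[k] = c[k] + d1 * bc[k] + d2 * m[k] + d3 * n[k];
}

static void rotateRows(NumericMatrix &xyz, const IntegerVector &idx,
                       const double *p, const double *u, double angleDeg) {
  double th = angleDeg * M_PI / 180.0, ct = std::cos(th), st = std::sin(th);
  for (int k = 0; k < idx.size(); ++k) {
    int i = idx[k] - 1;
    double v[3] = {xyz(i, 0) - p[0], xyz(i, 1) - p[1], xyz(i, 2) - p[2]};
    double cuv[3];
    vcross(u, v, cuv);
    double du = vdot(u, v);
    for (int c = 0; c < 3; ++c)
      xyz(i, c) = p[c] + v[c] * ct + cuv[c] * st + u[c] * du * (1 - ct);
  }
}

// chainbreak deviation: |N(cut+1) - ideal N continued from residue cut|
static double chainbreakC(const NumericMatrix &xyz, const IntegerVector &ct,
                          double bondCN, double angCACN) {
  double N[3] = {xyz(ct[0] - 1, 0), xyz(ct[0] - 1, 1), xyz(ct[0] - 1, 2)};
  double CA[3] = {xyz(ct[1] - 1, 0), xyz(ct[1] - 1, 1), xyz(ct[1] - 1, 2)};
  double C[3] = {xyz(ct[2] - 1, 0), xyz(ct[2] - 1, 1), xyz(ct[2] - 1, 2)};
  double Nn[3] = {xyz(ct[3] - 1, 0), xyz(ct[3] - 1, 1), xyz(ct[3] - 1, 2)};
  double psi = dihedralC(N, CA, C, Nn);
  double ideal[3];
  placeAtomC(N, CA, C, bondCN, angCACN, psi, ideal);
  double d[3];
  vsub(Nn, ideal, d);
  return vlen(d);
}

// Cyclic coordinate descent over precomputed torsion DOFs.  ct holds the
// 1-based atom indices N,CA,C (cut residue) and Nn,CAn,Cn (next residue);
// each DOF has its axis atom pair, moving atom indices and half flag.
// [[Rcpp::export]]
List ccdRunCpp(NumericMatrix xyzIn, IntegerMatrix axIdx, List movingList,
               LogicalVector forward, IntegerVector ct, int maxSweeps,
               double tol, double bondCN, double angCACN, double angCNCA,
               double bondNCA) {
  NumericMatrix xyz = clone(xyzIn);
  int nd = axIdx.nrow();
  double dev = chainbreakC(xyz, ct, bondCN, angCACN);
  int sweeps = 0;
  if (dev > tol) {
    for (int sweep = 0; sweep < maxSweeps; ++sweep) {
      sweeps = sweep + 1;
      for (int d = 0; d < nd; ++d) {
        IntegerVector mov = movingList[d];
        if (mov.size() == 0) continue;
        // virtual overlap atoms from current coordinates
        double N[3] = {xyz(ct[0] - 1, 0), xyz(ct[0] - 1, 1), xyz(ct[0] - 1, 2)};
        double CA[3] = {xyz(ct[1] - 1, 0), xyz(ct[1] - 1, 1), xyz(ct[1] - 1, 2)};
        double C[3] = {xyz(ct[2] - 1, 0), xyz(ct[2] - 1, 1), xyz(ct[2] - 1, 2)};
        double Nn[3] = {xyz(ct[3] - 1, 0), xyz(ct[3] - 1, 1), xyz(ct[3] - 1, 2)};
        double CAn[3] = {xyz(ct[4] - 1, 0), xyz(ct[4] - 1, 1), xyz(ct[4] - 1, 2)};
        double Cn[3] = {xyz(ct[5] - 1, 0), xyz(ct[5] - 1, 1), xyz(ct[5] - 1, 2)};
        double psi = dihedralC(N, CA, C, Nn);
        double ovl1[3], ovl2[3], ovu1[3];
        placeAtomC(N, CA, C, bondCN, angCACN, psi, ovl1);
        placeAtomC(CA, C, ovl1, bondNCA, angCNCA, 180.0, ovl2);
        double phi = dihedralC(Cn, CAn, Nn, C);
        placeAtomC(Cn, CAn, Nn, bondCN, angCNCA, phi, ovu1);

        double M[3][3], F[3][3];
        if (forward[d]) {
          for (int k = 0; k < 3; ++k) {
            M[0][k] = C[k]; M[1][k] = ovl1[k]; M[2][k] = ovl2[k];
            F[0][k] = ovu1[k]; F[1][k] = Nn[k]; F[2][k] = CAn[k];
          }
        } else {
          for (int k = 0; k < 3; ++k) {
            M[0][k] = ovu1[k]; M[1][k] = Nn[k]; M[2][k] = CAn[k];
            F[0][k] = C[k]; F[1][k] = ovl1[k]; F[2][k] = ovl2[k];
          }
        }
        double p[3] = {xyz(axIdx(d, 0) - 1, 0), xyz(axIdx(d, 0) - 1, 1),
                       xyz(axIdx(d, 0) - 1, 2)};
        double u[3] = {xyz(axIdx(d, 1) - 1, 0) - p[0],
                       xyz(axIdx(d, 1) - 1, 1) - p[1],
                       xyz(axIdx(d, 1) - 1, 2) - p[2]};
        vunit(u);
        double aa = 0, bb = 0;
        for (int k = 0; k < 3; ++k) {
          double mp[3] = {M[k][0] - p[0], M[k][1] - p[1], M[k][2] - p[2]};
          double proj = vdot(mp, u);
          double r[3] = {mp[0] - proj * u[0], mp[1] - proj * u[1],
                         mp[2] - proj * u[2]};
          double s = vlen(r);
          if (s < 1e-9) continue;
          double rh[3] = {r[0] / s, r[1] / s, r[2] / s};
          double th[3];
          vcross(u, rh, th);
          double fv[3] = {F[k][0] - p[0] - proj * u[0],
                          F[k][1] - p[1] - proj * u[1],
                          F[k][2] - p[2] - proj * u[2]};
          aa += s * vdot(fv, rh);
          bb += s * vdot(fv, th);
        }
        if (aa == 0 && bb == 0) continue;
        double theta = std::atan2(bb, aa) * 180.0 / M_PI;
        if (std::fabs(theta) < 1e-10) continue;
        rotateRows(xyz, mov, p, u, theta);
      }
      dev = chainbreakC(xyz, ct, bondCN, angCACN);
      if (dev <= tol) break;
    }
  }
  return List::create(_["xyz"] = xyz, _["sweeps"] = sweeps,
                      _["deviation"] = dev, _["converged"] = dev <= tol);
}


// Same accumulation as pairTermsCpp but restricted to pairs touching the
// atom index set `idx` (1-based).  Used for incremental rescoring when only
// those atoms moved rigidly: the difference new-minus-old over this subset
// equals the change in the full sums.
// [[Rcpp::export]]
NumericVector subsetTermsCpp(NumericMatrix xyz, NumericVector vdw,
                             NumericVector charge, IntegerVector group,
                             IntegerVector resUid, IntegerVector resno,
                             IntegerVector chainIdx, LogicalVector heavy,
                             double cutoff, double sigma,
                             IntegerVector idx) {
  const int n = xyz.nrow();
  const double cut2 = cutoff * cutoff;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<char> inSet(n, 0);
  for (int k = 0; k < idx.size(); ++k) inSet[idx[k] - 1] = 1;
  double rep[3] = {0, 0, 0}, att[3] = {0, 0, 0}, ele[3] = {0, 0, 0};
  const double *X = &xyz(0, 0), *Y = X + n, *Z = Y + n;
  for (int k = 0; k < idx.size(); ++k) {
    const int i = idx[k] - 1;
    if (!heavy[i]) continue;
    const double xi = X[i], yi = Y[i], zi = Z[i];
    for (int j = 0; j < n; ++j) {
      if (!heavy[j]) continue;
      if (inSet[j] && j <= i) continue;
      if (resUid[i] == resUid[j]) continue;
      if (chainIdx[i] == chainIdx[j] &&
          (resno[i] - resno[j] == 1 || resno[j] - resno[i] == 1))
        continue;
      const double dx = xi - X[j];
      const double dy = yi - Y[j];
      const double dz = zi - Z[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > cut2) continue;
      const double rsum = vdw[i] + vdw[j];
      const double attLim = rsum + 4.0 * sigma;
      const bool hasQ = charge[i] != 0.0 && charge[j] != 0.0;
      if (d2 > attLim * attLim && !hasQ) continue;
      const double d = std::sqrt(d2);
      int cls;
      if (group[i] == group[j]) cls = 0;
      else if (group[i] == 3 || group[j] == 3) cls = 2;
      else cls = 1;
      if (d < rsum) {
        const double x = (rsum - d) / rsum;
        rep[cls] += x * x;
      }
      const double dd = d - rsum;
      if (dd < 4.0 * sigma) att[cls] += -std::exp(-dd * dd * inv2s2);
      if (hasQ) {
        const double d2e = d2 < 4.0 ? 4.0 : d2;
        ele[cls] += 83.0 * charge[i] * charge[j] / d2e;
      }
    }
  }
  NumericVector out = NumericVector::create(
      rep[0], att[0], ele[0], rep[1], att[1], ele[1], rep[2], att[2], ele[2]);
  out.attr("names") = CharacterVector::create(
      "rep_intra", "att_intra", "elec_intra", "rep_vlvh", "att_vlvh",
      "elec_vlvh", "rep_abag", "att_abag", "elec_abag");
  return out;
}

// Sum of squared chainbreak deviations over cutpoints; each row of `cuts`
// holds the 1-based atom indices N, CA, C (cut residue) and N (next).
// [[Rcpp::export]]
double cbTermCpp(NumericMatrix xyz, IntegerMatrix cuts, double bondCN,
                 double angCACN) {
  double s = 0;
  for (int i = 0; i < cuts.nrow(); ++i) {
    IntegerVector ct = IntegerVector::create(cuts(i, 0), cuts(i, 1),
                                             cuts(i, 2), cuts(i, 3));
    double dev = chainbreakC(xyz, ct, bondCN, angCACN);
    s += dev * dev;
  }
  return s;
}

// Weighted pair-energy total over pairs touching the index set, used by the
// chi-grid scan below.  wv9 matches the 9-term kernel output order.
static double subsetTotalC(const NumericMatrix &xyz, const NumericVector &vdw,
                           const NumericVector &charge,
                           const IntegerVector &group,
                           const IntegerVector &resUid,
                           const IntegerVector &resno,
                           const IntegerVector &chainIdx,
                           const LogicalVector &heavy, double cutoff,
                           double sigma, const std::vector<int> &idx,
                           const std::vector<char> &inSet,
                           const NumericVector &wv9) {
  const int n = xyz.nrow();
  const double cut2 = cutoff * cutoff;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double *X = &xyz(0, 0), *Y = X + n, *Z = Y + n;
  double acc[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  for (size_t k = 0; k < idx.size(); ++k) {
    const int i = idx[k];
    if (!heavy[i]) continue;
    const double xi = X[i], yi = Y[i], zi = Z[i];
    for (int j = 0; j < n; ++j) {
      if (!heavy[j]) continue;
      if (inSet[j] && j <= i) continue;
      if (resUid[i] == resUid[j]) continue;
      if (chainIdx[i] == chainIdx[j] &&
          (resno[i] - resno[j] == 1 || resno[j] - resno[i] == 1))
        continue;
      const double dx = xi - X[j], dy = yi - Y[j], dz = zi - Z[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > cut2) continue;
      const double rsum = vdw[i] + vdw[j];
      const double attLim = rsum + 4.0 * sigma;
      const bool hasQ = charge[i] != 0.0 && charge[j] != 0.0;
      if (d2 > attLim * attLim && !hasQ) continue;
      const double d = std::sqrt(d2);
      int cls;
      if (group[i] == group[j]) cls = 0;
      else if (group[i] == 3 || group[j] == 3) cls = 2;
      else cls = 1;
      if (d < rsum) {
        const double x = (rsum - d) / rsum;
        acc[3 * cls] += x * x;
      }
      const double dd = d - rsum;
      if (dd < 4.0 * sigma) acc[3 * cls + 1] += -std::exp(-dd * dd * inv2s2);
      if (hasQ) {
        const double d2e = d2 < 4.0 ? 4.0 : d2;
        acc[3 * cls + 2] += 83.0 * charge[i] * charge[j] / d2e;
      }
    }
  }
  double tot = 0;
  for (int t = 0; t < 9; ++t) tot += acc[t] * wv9[t];
  return tot;
}

// Greedy grid scan of one chi angle: evaluates the candidate values and
// returns c(bestAngle, bestDelta) where bestDelta is the energy change
// relative to the current angle (0 if no candidate improves).
// [[Rcpp::export]]
NumericVector chiScanCpp(NumericMatrix xyzIn, IntegerVector quad,
                         IntegerVector mov, NumericVector cand,
                         NumericVector vdw, NumericVector charge,
                         IntegerVector group, IntegerVector resUid,
                         IntegerVector resno, IntegerVector chainIdx,
                         LogicalVector heavy, double cutoff, double sigma,
                         NumericVector wv9) {
  NumericMatrix xyz = clone(xyzIn);
  const int n = xyz.nrow();
  std::vector<int> idx0(mov.size());
  std::vector<char> inSet(n, 0);
  for (int k = 0; k < mov.size(); ++k) {
    idx0[k] = mov[k] - 1;
    inSet[mov[k] - 1] = 1;
  }
  double A[3] = {xyz(quad[0] - 1, 0), xyz(quad[0] - 1, 1), xyz(quad[0] - 1, 2)};
  double B[3] = {xyz(quad[1] - 1, 0), xyz(quad[1] - 1, 1), xyz(quad[1] - 1, 2)};
  double C[3] = {xyz(quad[2] - 1, 0), xyz(quad[2] - 1, 1), xyz(quad[2] - 1, 2)};
  double D[3] = {xyz(quad[3] - 1, 0), xyz(quad[3] - 1, 1), xyz(quad[3] - 1, 2)};
  const double curAng = dihedralC(A, B, C, D);
  double u[3];
  vsub(C, B, u); vunit(u);

  // save original moving coordinates
  std::vector<double> orig(3 * idx0.size());
  for (size_t k = 0; k < idx0.size(); ++k)
    for (int c = 0; c < 3; ++c) orig[3 * k + c] = xyz(idx0[k], c);

  const double base = subsetTotalC(xyz, vdw, charge, group, resUid, resno,
                                   chainIdx, heavy, cutoff, sigma, idx0,
                                   inSet, wv9);
  double bestAngle = curAng, bestDelta = 0;
  for (int ci = 0; ci < cand.size(); ++ci) {
    // restore and rotate to candidate
    for (size_t k = 0; k < idx0.size(); ++k)
      for (int c = 0; c < 3; ++c) xyz(idx0[k], c) = orig[3 * k + c];
    IntegerVector movR(mov);
    rotateRows(xyz, movR, B, u, cand[ci] - curAng);
    const double v = subsetTotalC(xyz, vdw, charge, group, resUid, resno,
                                  chainIdx, heavy, cutoff, sigma, idx0,
                                  inSet, wv9) - base;
    if (v < bestDelta - 1e-12) {
      bestDelta = v;
      bestAngle = cand[ci];
    }
  }
  return NumericVector::create(bestAngle, bestDelta);
}
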