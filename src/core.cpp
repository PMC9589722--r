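// Core numerics: structure-based energy/forces, BAOAB Langevin propagation,
// restraints, and per-frame observable kernels. Coordinates are in Angstrom,
// energies in kcal/mol, time in the reduced unit tau (unit bead masses).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG: splitmix64 keyed on (seed, step, dof, draw). Stateless,
// so a run restarted from a serialized state reproduces the full-run stream.
// ---------------------------------------------------------------------------
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t seed, uint64_t step, uint64_t dof, uint64_t draw) {
  uint64_t key = splitmix64(seed ^ 0x8AD318A5C57B3EA1ULL);
  key = splitmix64(key ^ (step * 0xD1342543DE82EF95ULL));
  key = splitmix64(key ^ (dof * 0x2545F4914F6CDD1DULL));
  key = splitmix64(key ^ (draw * 0x9E6C63D0876A9B4DULL));
  // (0,1): never exactly 0
  return (static_cast<double>(key >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

static inline double gauss_cb(uint64_t seed, uint64_t step, uint64_t dof) {
  double u1 = u01(seed, step, dof, 1);
  double u2 = u01(seed, step, dof, 2);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

// ---------------------------------------------------------------------------
// Topology containers (parsed once per call from R lists)
// ---------------------------------------------------------------------------
struct PairList {           // generic (i, j) list with per-pair constants
  std::vector<int> i, j;
  std::vector<double> a, b; // meaning depends on term
};

struct Topo {
  int n;
  // bonded (single-basin, shared between conformers after hinge pruning)
  std::vector<int> b_i, b_j;            std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k;       std::vector<double> a_t0, a_kc;
  std::vector<int> d_i, d_j, d_k, d_l;  std::vector<double> d_p0, d_kc;
  // shared 12-10 contacts (intra-domain protein + protein-ligand native)
  PairList shared;                       // a = r0, b = eps
  // interface contacts per component and basin
  int ncomp;
  std::vector<PairList> comp_closed, comp_open;  // a = r0, b = eps
  // non-native protein-ligand pairs (Gaussian well, strength eps_nnat)
  PairList nnat;                         // no per-pair constants
  // excluded volume pairs: a = sigma, b = eps
  PairList exv;
};

struct Restraint {
  int type;                  // 0 flat_bottom, 1 rmsd, 2 xi_bias, 3 tether, 4 posfix
  std::vector<int> idxA, idxB;
  arma::mat refA, refB;      // reference coordinates (n_sel x 3)
  double k = 0, r0 = 0, center = 0, rmsd_co = 1;
  std::vector<double> t_r0;  // tether targets
  std::vector<double> t_k;   // tether constants
};

static std::vector<int> as_idx0(SEXP s) {
  IntegerVector v(s);
  std::vector<int> out(v.size());
  for (int q = 0; q < v.size(); ++q) out[q] = v[q] - 1;  // R 1-based -> 0-based
  return out;
}

static PairList parse_pairs(List pl) {
  PairList p;
  IntegerMatrix ij = pl["ij"];
  int m = ij.nrow();
  p.i.resize(m); p.j.resize(m);
  for (int q = 0; q < m; ++q) { p.i[q] = ij(q, 0) - 1; p.j[q] = ij(q, 1) - 1; }
  if (pl.containsElementNamed("a")) {
    NumericVector a = pl["a"]; p.a.assign(a.begin(), a.end());
  }
  if (pl.containsElementNamed("b")) {
    NumericVector b = pl["b"]; p.b.assign(b.begin(), b.end());
  }
  return p;
}

static Topo parse_topo(List tl) {
  Topo t;
  t.n = as<int>(tl["n"]);
  List bonds = tl["bonds"];
  IntegerMatrix bij = bonds["ij"];
  NumericVector br0 = bonds["r0"], bk = bonds["k"];
  for (int q = 0; q < bij.nrow(); ++q) {
    t.b_i.push_back(bij(q, 0) - 1); t.b_j.push_back(bij(q, 1) - 1);
    t.b_r0.push_back(br0[q]); t.b_k.push_back(bk[q]);
  }
  List ang = tl["angles"];
  IntegerMatrix aij = ang["ijk"];
  NumericVector at0 = ang["theta0"], ak = ang["k"];
  for (int q = 0; q < aij.nrow(); ++q) {
    t.a_i.push_back(aij(q, 0) - 1); t.a_j.push_back(aij(q, 1) - 1);
    t.a_k.push_back(aij(q, 2) - 1);
    t.a_t0.push_back(at0[q]); t.a_kc.push_back(ak[q]);
  }
  List dih = tl["dihedrals"];
  IntegerMatrix dij = dih["ijkl"];
  NumericVector dp0 = dih["phi0"], dk = dih["k"];
  for (int q = 0; q < dij.nrow(); ++q) {
    t.d_i.push_back(dij(q, 0) - 1); t.d_j.push_back(dij(q, 1) - 1);
    t.d_k.push_back(dij(q, 2) - 1); t.d_l.push_back(dij(q, 3) - 1);
    t.d_p0.push_back(dp0[q]); t.d_kc.push_back(dk[q]);
  }
  t.shared = parse_pairs(tl["shared_contacts"]);
  List cc = tl["comp_closed"], co = tl["comp_open"];
  t.ncomp = cc.size();
  for (int c = 0; c < t.ncomp; ++c) {
    t.comp_closed.push_back(parse_pairs(cc[c]));
    t.comp_open.push_back(parse_pairs(co[c]));
  }
  t.nnat = parse_pairs(tl["nonnative"]);
  t.exv = parse_pairs(tl["exv"]);
  return t;
}

static std::vector<Restraint> parse_restraints(List rl) {
  std::vector<Restraint> out;
  for (int q = 0; q < rl.size(); ++q) {
    List r = rl[q];
    std::string ty = as<std::string>(r["type"]);
    Restraint rr;
    if (ty == "flat_bottom") {
      rr.type = 0;
      rr.idxA = as_idx0(r["idxA"]); rr.idxB = as_idx0(r["idxB"]);
      rr.k = as<double>(r["k"]); rr.r0 = as<double>(r["r0"]);
    } else if (ty == "rmsd") {
      rr.type = 1;
      rr.idxA = as_idx0(r["idx"]);
      rr.refA = as<arma::mat>(r["ref"]);
      rr.k = as<double>(r["k"]);
    } else if (ty == "xi_bias") {
      rr.type = 2;
      rr.idxA = as_idx0(r["idx"]);
      rr.refA = as<arma::mat>(r["ref_closed"]);
      rr.refB = as<arma::mat>(r["ref_open"]);
      rr.k = as<double>(r["k"]); rr.center = as<double>(r["center"]);
      rr.rmsd_co = as<double>(r["rmsd_co"]);
    } else if (ty == "tether") {
      rr.type = 3;
      rr.idxA = as_idx0(r["i"]); rr.idxB = as_idx0(r["j"]);
      NumericVector r0 = r["r0"], kk = r["k"];
      rr.t_r0.assign(r0.begin(), r0.end());
      rr.t_k.assign(kk.begin(), kk.end());
    } else if (ty == "posfix") {
      rr.type = 4;
      rr.idxA = as_idx0(r["idx"]);
      rr.refA = as<arma::mat>(r["ref"]);
      rr.k = as<double>(r["k"]);
    } else {
      stop("unknown restraint type: " + ty);
    }
    out.push_back(rr);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Pair potentials (with energy-shifted truncation)
// ---------------------------------------------------------------------------
static const double CONTACT_RC = 2.5;   // in units of r0
static const double NNAT_RC = 3.5;      // in units of sigma
static const double EXV_RC = 2.5;       // in units of sigma
// shift constants at the truncation radii
static const double CONTACT_SHIFT =
  5.0 / 59604644775.390625 - 6.0 / 9536743.1640625; // 5(1/2.5)^12-6(1/2.5)^10
static const double NNAT_SHIFT = 0.0021874911181828869; // exp(-3.5^2/2)
static const double EXV_SHIFT = 1.6777216e-05;           // (1/2.5)^12

// All pair kernels work on r^2 and return the energy while setting
// fscale = -(1/r) dV/dr, so force_ij = fscale * (x_i - x_j).

static inline double v1210_r2(double r2, double r0, double eps, double &fs) {
  if (r2 >= CONTACT_RC * CONTACT_RC * r0 * r0) { fs = 0; return 0; }
  double q2 = r0 * r0 / r2;
  double q4 = q2 * q2, q10 = q4 * q4 * q2, q12 = q10 * q2;
  fs = eps * 60.0 * (q12 - q10) / r2;
  return eps * (5.0 * q12 - 6.0 * q10 - CONTACT_SHIFT);
}

static inline double vgauss_r2(double r2, double eps, double sigma, double &fs) {
  double s2 = sigma * sigma;
  if (r2 >= NNAT_RC * NNAT_RC * s2) { fs = 0; return 0; }
  double e = std::exp(-0.5 * r2 / s2);
  fs = -eps * e / s2;
  return -eps * (e - NNAT_SHIFT);
}

static inline double vexv_r2(double r2, double eps, double sigma, double &fs) {
  double s2 = sigma * sigma;
  if (r2 >= EXV_RC * EXV_RC * s2) { fs = 0; return 0; }
  double q2 = s2 / r2, q4 = q2 * q2, q12 = q4 * q4 * q4;
  fs = 12.0 * eps * q12 / r2;
  return eps * (q12 - EXV_SHIFT);
}

// best-fit rotation of Y onto X (both n x 3, already centered)
static arma::mat kabsch_rot(const arma::mat &Xc, const arma::mat &Yc) {
  arma::mat C = Yc.t() * Xc;            // 3 x 3
  arma::mat U, V; arma::vec s;
  arma::svd(U, s, V, C);
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  return V * D * U.t();                 // rotation applied to Y rows: Y * R.t()
}

// RMSD of selected beads to a reference, plus gradient d(RMSD)/dx on selection.
// grad is (n_sel x 3); returns RMSD.
static double rmsd_grad(const arma::mat &X, const std::vector<int> &idx,
                        const arma::mat &ref, arma::mat &grad) {
  int m = idx.size();
  arma::mat Xs(m, 3), Ys = ref;
  for (int q = 0; q < m; ++q) Xs.row(q) = X.row(idx[q]);
  arma::rowvec cx = arma::mean(Xs, 0), cy = arma::mean(Ys, 0);
  Xs.each_row() -= cx; Ys.each_row() -= cy;
  arma::mat R = kabsch_rot(Xs, Ys);
  arma::mat Yrot = Ys * R.t();
  arma::mat diff = Xs - Yrot;
  double msd = arma::accu(diff % diff) / m;
  double rmsd = std::sqrt(std::max(msd, 0.0));
  double denom = std::max(rmsd, 1e-10);
  grad = diff / (m * denom);
  return rmsd;
}

// ---------------------------------------------------------------------------
// Full energy + forces
// ---------------------------------------------------------------------------
struct EnergyOut {
  double bond = 0, angle = 0, dihedral = 0, shared = 0, nnat = 0, exv = 0,
         restraint = 0;
  std::vector<double> vmb;      // mixed interface energies
  std::vector<double> v1, v2;   // per-component basin energies
  double total = 0;
};

// accumulate pairwise force given fscale = -(1/r) dV/dr
// (raw column-major access; n = number of rows)
static inline void add_pair_force_fs(arma::mat &F, const double *dx,
                                     int i, int j, double fs) {
  double *f = F.memptr();
  const arma::uword n = F.n_rows;
  f[i] += fs * dx[0];          f[j] -= fs * dx[0];
  f[n + i] += fs * dx[1];      f[n + j] -= fs * dx[1];
  f[2 * n + i] += fs * dx[2];  f[2 * n + j] -= fs * dx[2];
}

static inline double pair_d2(const arma::mat &X, int i, int j, double *dx) {
  const double *x = X.memptr();
  const arma::uword n = X.n_rows;
  dx[0] = x[i] - x[j];
  dx[1] = x[n + i] - x[n + j];
  dx[2] = x[2 * n + i] - x[2 * n + j];
  return dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
}

static double pair_dist(const arma::mat &X, int i, int j) {
  double dx[3];
  return std::sqrt(pair_d2(X, i, j, dx));
}

// legacy form taking dV/dr and r (bonds, tethers)
static inline void add_pair_force(arma::mat &F, const arma::mat &X,
                                  int i, int j, double dvdr, double r) {
  double dx[3];
  pair_d2(X, i, j, dx);
  add_pair_force_fs(F, dx, i, j, -dvdr / std::max(r, 1e-12));
}

// sum a contact list, accumulating into F with weight applied later via scale
static double contact_sum(const arma::mat &X, const PairList &p, arma::mat &F) {
  double V = 0;
  double dx[3], fs;
  for (size_t q = 0; q < p.i.size(); ++q) {
    double r2 = pair_d2(X, p.i[q], p.j[q], dx);
    V += v1210_r2(r2, p.a[q], p.b[q], fs);
    add_pair_force_fs(F, dx, p.i[q], p.j[q], fs);
  }
  return V;
}

// mode: 0 = multi-basin mix, 1 = closed basin only, 2 = open basin only
static EnergyOut energy_forces(const arma::mat &X, const Topo &t,
                               double eps_nnat, double sigma_nnat,
                               const std::vector<double> &deltaV,
                               const std::vector<double> &Delta,
                               const std::vector<Restraint> &res,
                               int mode, arma::mat &F) {
  EnergyOut E;
  F.zeros(t.n, 3);

  // bonds: V = k (r - r0)^2
  {
    double dx[3];
    for (size_t q = 0; q < t.b_i.size(); ++q) {
      double r = std::sqrt(pair_d2(X, t.b_i[q], t.b_j[q], dx));
      double dr = r - t.b_r0[q];
      E.bond += t.b_k[q] * dr * dr;
      add_pair_force_fs(F, dx, t.b_i[q], t.b_j[q],
                        -2.0 * t.b_k[q] * dr / std::max(r, 1e-12));
    }
  }

  // angles: cosine-harmonic V = k (cos theta - cos theta0)^2, which is
  // smooth at theta = pi (straight reference geometries are common here)
  for (size_t q = 0; q < t.a_i.size(); ++q) {
    int i = t.a_i[q], j = t.a_j[q], k = t.a_k[q];
    arma::rowvec rij = X.row(i) - X.row(j);
    arma::rowvec rkj = X.row(k) - X.row(j);
    double nij = arma::norm(rij), nkj = arma::norm(rkj);
    double cosv = arma::dot(rij, rkj) / (nij * nkj);
    cosv = std::min(1.0, std::max(-1.0, cosv));
    double dc = cosv - std::cos(t.a_t0[q]);
    E.angle += t.a_kc[q] * dc * dc;
    double dEdc = 2.0 * t.a_kc[q] * dc;
    arma::rowvec di = rkj / (nij * nkj) - cosv * rij / (nij * nij);
    arma::rowvec dk = rij / (nij * nkj) - cosv * rkj / (nkj * nkj);
    F.row(i) -= dEdc * di;
    F.row(k) -= dEdc * dk;
    F.row(j) += dEdc * (di + dk);
  }

  // dihedrals: V = k (1 - cos(phi - phi0))
  for (size_t q = 0; q < t.d_i.size(); ++q) {
    int i = t.d_i[q], j = t.d_j[q], k = t.d_k[q], l = t.d_l[q];
    arma::rowvec b1 = X.row(j) - X.row(i);
    arma::rowvec b2 = X.row(k) - X.row(j);
    arma::rowvec b3 = X.row(l) - X.row(k);
    arma::rowvec n1 = arma::cross(b1, b2);
    arma::rowvec n2 = arma::cross(b2, b3);
    double nn1 = arma::norm(n1), nn2 = arma::norm(n2), nb2 = arma::norm(b2);
    if (nn1 < 1e-9 || nn2 < 1e-9) continue;   // collinear: term undefined, skip
    double cphi = arma::dot(n1, n2) / (nn1 * nn2);
    cphi = std::min(1.0, std::max(-1.0, cphi));
    double sphi = arma::dot(arma::cross(n1, n2), b2) / (nn1 * nn2 * nb2);
    double phi = std::atan2(sphi, cphi);
    double dphi = phi - t.d_p0[q];
    E.dihedral += t.d_kc[q] * (1.0 - std::cos(dphi));
    double dEdphi = t.d_kc[q] * std::sin(dphi);
    // dphi/dr for the four beads (standard chain-rule identities)
    arma::rowvec t1 = -(nb2 / (nn1 * nn1)) * n1;
    arma::rowvec t4 = (nb2 / (nn2 * nn2)) * n2;
    double s1 = arma::dot(b1, b2) / (nb2 * nb2);
    double s2 = arma::dot(b3, b2) / (nb2 * nb2);
    arma::rowvec t2 = -t1 - s1 * t1 + s2 * t4;
    arma::rowvec t3 = -t4 + s1 * t1 - s2 * t4;
    F.row(i) -= dEdphi * t1; F.row(j) -= dEdphi * t2;
    F.row(k) -= dEdphi * t3; F.row(l) -= dEdphi * t4;
  }

  // shared 12-10 contacts
  E.shared = contact_sum(X, t.shared, F);

  // interface components with double-basin mixing
  E.vmb.assign(t.ncomp, 0.0);
  E.v1.assign(t.ncomp, 0.0);
  E.v2.assign(t.ncomp, 0.0);
  for (int c = 0; c < t.ncomp; ++c) {
    arma::mat F1(t.n, 3, arma::fill::zeros), F2(t.n, 3, arma::fill::zeros);
    double V1 = contact_sum(X, t.comp_closed[c], F1);
    double V2 = contact_sum(X, t.comp_open[c], F2) + deltaV[c];
    E.v1[c] = V1; E.v2[c] = V2;
    double w1, w2, Vmb;
    if (mode == 1) { w1 = 1; w2 = 0; Vmb = V1; }
    else if (mode == 2) { w1 = 0; w2 = 1; Vmb = V2; }
    else {
      double D = Delta[c];
      double diff = V1 - V2;
      double s = std::sqrt(diff * diff + 4.0 * D * D);
      Vmb = 0.5 * (V1 + V2) - 0.5 * s;
      if (s < 1e-12) { w1 = 0.5; w2 = 0.5; }
      else { w1 = 0.5 * (1.0 - diff / s); w2 = 0.5 * (1.0 + diff / s); }
    }
    E.vmb[c] = Vmb;
    F += w1 * F1 + w2 * F2;
  }

  // non-native Gaussian wells
  {
    double dx[3], fs;
    for (size_t q = 0; q < t.nnat.i.size(); ++q) {
      double r2 = pair_d2(X, t.nnat.i[q], t.nnat.j[q], dx);
      E.nnat += vgauss_r2(r2, eps_nnat, sigma_nnat, fs);
      add_pair_force_fs(F, dx, t.nnat.i[q], t.nnat.j[q], fs);
    }
  }

  // excluded volume
  {
    double dx[3], fs;
    for (size_t q = 0; q < t.exv.i.size(); ++q) {
      double r2 = pair_d2(X, t.exv.i[q], t.exv.j[q], dx);
      E.exv += vexv_r2(r2, t.exv.b[q], t.exv.a[q], fs);
      add_pair_force_fs(F, dx, t.exv.i[q], t.exv.j[q], fs);
    }
  }

  // restraints
  for (const Restraint &rr : res) {
    if (rr.type == 0) {                    // flat-bottom on centroid distance
      arma::rowvec ca(3, arma::fill::zeros), cb(3, arma::fill::zeros);
      for (int ix : rr.idxA) ca += X.row(ix);
      for (int ix : rr.idxB) cb += X.row(ix);
      ca /= rr.idxA.size(); cb /= rr.idxB.size();
      arma::rowvec dvec = ca - cb;
      double d = arma::norm(dvec);
      if (d > rr.r0 && d > 1e-12) {
        double ex = d - rr.r0;
        E.restraint += 0.5 * rr.k * ex * ex;
        arma::rowvec g = rr.k * ex * dvec / d;
        for (int ix : rr.idxA) F.row(ix) -= g / rr.idxA.size();
        for (int ix : rr.idxB) F.row(ix) += g / rr.idxB.size();
      }
    } else if (rr.type == 1) {             // (k/2) RMSD^2
      arma::mat g;
      double rv = rmsd_grad(X, rr.idxA, rr.refA, g);
      E.restraint += 0.5 * rr.k * rv * rv;
      for (size_t q = 0; q < rr.idxA.size(); ++q)
        F.row(rr.idxA[q]) -= rr.k * rv * g.row(q);
    } else if (rr.type == 2) {             // umbrella bias on xi
      arma::mat ga, gb;
      double a = rmsd_grad(X, rr.idxA, rr.refA, ga);
      double b = rmsd_grad(X, rr.idxA, rr.refB, gb);
      double xi = (a - b) / rr.rmsd_co;
      double dev = xi - rr.center;
      E.restraint += 0.5 * rr.k * dev * dev;
      double pref = rr.k * dev / rr.rmsd_co;
      for (size_t q = 0; q < rr.idxA.size(); ++q)
        F.row(rr.idxA[q]) -= pref * (ga.row(q) - gb.row(q));
    } else if (rr.type == 3) {             // harmonic distance tethers
      for (size_t q = 0; q < rr.idxA.size(); ++q) {
        double r = pair_dist(X, rr.idxA[q], rr.idxB[q]);
        double dr = r - rr.t_r0[q];
        E.restraint += 0.5 * rr.t_k[q] * dr * dr;
        add_pair_force(F, X, rr.idxA[q], rr.idxB[q], rr.t_k[q] * dr, r);
      }
    } else if (rr.type == 4) {             // positional fix
      for (size_t q = 0; q < rr.idxA.size(); ++q) {
        arma::rowvec dvec = X.row(rr.idxA[q]) - rr.refA.row(q);
        E.restraint += 0.5 * rr.k * arma::dot(dvec, dvec);
        F.row(rr.idxA[q]) -= rr.k * dvec;
      }
    }
  }

  E.total = E.bond + E.angle + E.dihedral + E.shared + E.nnat + E.exv +
            E.restraint;
  for (int c = 0; c < t.ncomp; ++c) E.total += E.vmb[c];
  return E;
}

// [[Rcpp::export]]
List cg_energy_cpp(NumericMatrix coords, List topo, double eps_nnat,
                   double sigma_nnat, NumericVector deltaV,
                   NumericVector Delta, List restraints, int mode) {
  Topo t = parse_topo(topo);
  std::vector<Restraint> res = parse_restraints(restraints);
  arma::mat X = as<arma::mat>(coords);
  if ((int)X.n_rows != t.n) stop("coordinate/topology size mismatch");
  arma::mat F;
  std::vector<double> dV(deltaV.begin(), deltaV.end());
  std::vector<double> DD(Delta.begin(), Delta.end());
  EnergyOut E = energy_forces(X, t, eps_nnat, sigma_nnat, dV, DD, res, mode, F);
  return List::create(
    _["total"] = E.total,
    _["bond"] = E.bond, _["angle"] = E.angle, _["dihedral"] = E.dihedral,
    _["contacts_shared"] = E.shared,
    _["interface_mixed"] = NumericVector(E.vmb.begin(), E.vmb.end()),
    _["interface_closed"] = NumericVector(E.v1.begin(), E.v1.end()),
    _["interface_open"] = NumericVector(E.v2.begin(), E.v2.end()),
    _["nonnative"] = E.nnat, _["exv"] = E.exv, _["restraint"] = E.restraint,
    _["forces"] = wrap(F));
}

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator. With gamma = 0 this reduces to velocity Verlet.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List run_cg_cpp(NumericMatrix coords, NumericMatrix vels, List topo,
                double eps_nnat, double sigma_nnat,
                NumericVector deltaV, NumericVector Delta, List restraints,
                int mode, double kT, double gamma, double dt,
                int n_steps, int stride, double seed_d, double step_offset_d) {
  Topo t = parse_topo(topo);
  std::vector<Restraint> res = parse_restraints(restraints);
  arma::mat X = as<arma::mat>(coords);
  arma::mat V = as<arma::mat>(vels);
  if ((int)X.n_rows != t.n) stop("coordinate/topology size mismatch");
  std::vector<double> dV(deltaV.begin(), deltaV.end());
  std::vector<double> DD(Delta.begin(), Delta.end());
  uint64_t seed = (uint64_t)seed_d;
  uint64_t step_offset = (uint64_t)step_offset_d;

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, (1.0 - c1 * c1) * kT)); // unit mass

  int n_frames = n_steps / std::max(stride, 1) + 1;
  arma::mat frames(n_frames, 3 * t.n);
  arma::vec ekin(n_frames), epot(n_frames);

  arma::mat F;
  EnergyOut E = energy_forces(X, t, eps_nnat, sigma_nnat, dV, DD, res, mode, F);
  if (!F.is_finite()) stop("non-finite force at step 0");

  int fidx = 0;
  auto record = [&](int) {
    for (int ii = 0; ii < t.n; ++ii)
      for (int d = 0; d < 3; ++d) frames(fidx, 3 * ii + d) = X(ii, d);
    ekin(fidx) = 0.5 * arma::accu(V % V);
    epot(fidx) = E.total - E.restraint;  // physical energy (bias excluded)
    ++fidx;
  };
  record(0);

  for (int s = 1; s <= n_steps; ++s) {
    uint64_t gstep = step_offset + (uint64_t)s;
    V += 0.5 * dt * F;                   // B
    X += 0.5 * dt * V;                   // A
    if (gamma > 0) {                     // O
      for (int ii = 0; ii < t.n; ++ii)
        for (int d = 0; d < 3; ++d)
          V(ii, d) = c1 * V(ii, d) + c2 * gauss_cb(seed, gstep, 3 * ii + d);
    }
    X += 0.5 * dt * V;                   // A
    E = energy_forces(X, t, eps_nnat, sigma_nnat, dV, DD, res, mode, F);
    V += 0.5 * dt * F;                   // B
    if (s % std::max(stride, 1) == 0) {
      if (!F.is_finite() || !X.is_finite())
        stop("non-finite state at step " + std::to_string(s));
      record(s);
    }
  }

  return List::create(_["frames"] = wrap(frames),
                      _["ekin"] = wrap(ekin), _["epot"] = wrap(epot),
                      _["coords"] = wrap(X), _["vels"] = wrap(V),
                      _["n_steps"] = n_steps, _["stride"] = stride);
}

// ---------------------------------------------------------------------------
// 1D Langevin dynamics on a polynomial potential (oracle systems)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List run_poly1d_cpp(double x0, double v0, NumericVector coeffs, double kT,
                    double gamma, double dt, int n_steps, int stride,
                    double seed_d, double step_offset_d) {
  uint64_t seed = (uint64_t)seed_d;
  uint64_t off = (uint64_t)step_offset_d;
  int nc = coeffs.size();
  auto force = [&](double x) {
    double f = 0, xp = 1;             // -dV/dx, V = sum coeffs[k] x^k
    for (int k = 1; k < nc; ++k) {
      f -= k * coeffs[k] * xp;
      xp *= x;
    }
    return f;
  };
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(std::max(0.0, (1.0 - c1 * c1) * kT));
  int n_frames = n_steps / std::max(stride, 1) + 1;
  NumericVector xs(n_frames), vs(n_frames);
  double x = x0, v = v0, F = force(x);
  int fi = 0;
  xs[fi] = x; vs[fi] = v; ++fi;
  for (int s = 1; s <= n_steps; ++s) {
    v += 0.5 * dt * F;
    x += 0.5 * dt * v;
    if (gamma > 0) v = c1 * v + c2 * gauss_cb(seed, off + (uint64_t)s, 0);
    x += 0.5 * dt * v;
    F = force(x);
    v += 0.5 * dt * F;
    if (s % std::max(stride, 1) == 0) { xs[fi] = x; vs[fi] = v; ++fi; }
  }
  return List::create(_["x"] = xs, _["v"] = vs,
                      _["x_final"] = x, _["v_final"] = v);
}

// ---------------------------------------------------------------------------
// Frame observable kernels (frames: n_frames x 3N, bead-major x,y,z)
// ---------------------------------------------------------------------------
static arma::mat frame_coords(const arma::mat &frames, int f, int n) {
  arma::mat X(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) X(i, d) = frames(f, 3 * i + d);
  return X;
}

// [[Rcpp::export]]
NumericVector rmsd_frames_cpp(NumericMatrix frames, NumericMatrix ref,
                              IntegerVector idx) {
  arma::mat Fm = as<arma::mat>(frames);
  arma::mat Rf = as<arma::mat>(ref);
  int n = Fm.n_cols / 3;
  std::vector<int> ix(idx.size());
  for (int q = 0; q < idx.size(); ++q) ix[q] = idx[q] - 1;
  NumericVector out(Fm.n_rows);
  arma::mat g;
  for (arma::uword f = 0; f < Fm.n_rows; ++f) {
    arma::mat X = frame_coords(Fm, f, n);
    out[f] = rmsd_grad(X, ix, Rf, g);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector q_frames_cpp(NumericMatrix frames, IntegerMatrix pairs,
                           NumericVector r0, double lam) {
  arma::mat Fm = as<arma::mat>(frames);
  int m = pairs.nrow();
  NumericVector out(Fm.n_rows);
  for (arma::uword f = 0; f < Fm.n_rows; ++f) {
    int formed = 0;
    for (int q = 0; q < m; ++q) {
      int i = pairs(q, 0) - 1, j = pairs(q, 1) - 1;
      double s = 0;
      for (int d = 0; d < 3; ++d) {
        double dx = Fm(f, 3 * i + d) - Fm(f, 3 * j + d);
        s += dx * dx;
      }
      if (std::sqrt(s) < lam * r0[q]) ++formed;
    }
    out[f] = (double)formed / m;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector centroid_dist_frames_cpp(NumericMatrix frames, IntegerVector idxA,
                                       IntegerVector idxB) {
  arma::mat Fm = as<arma::mat>(frames);
  NumericVector out(Fm.n_rows);
  for (arma::uword f = 0; f < Fm.n_rows; ++f) {
    double ca[3] = {0, 0, 0}, cb[3] = {0, 0, 0};
    for (int q = 0; q < idxA.size(); ++q)
      for (int d = 0; d < 3; ++d) ca[d] += Fm(f, 3 * (idxA[q] - 1) + d);
    for (int q = 0; q < idxB.size(); ++q)
      for (int d = 0; d < 3; ++d) cb[d] += Fm(f, 3 * (idxB[q] - 1) + d);
    double s = 0;
    for (int d = 0; d < 3; ++d) {
      double dx = ca[d] / idxA.size() - cb[d] / idxB.size();
      s += dx * dx;
    }
    out[f] = std::sqrt(s);
  }
  return out;
}

// per-contact formed indicator for one frame set: returns n_frames x m 0/1
// [[Rcpp::export]]
IntegerMatrix contacts_formed_cpp(NumericMatrix frames, IntegerMatrix pairs,
                                  NumericVector r0, double lam) {
  arma::mat Fm = as<arma::mat>(frames);
  int m = pairs.nrow();
  IntegerMatrix out(Fm.n_rows, m);
  for (arma::uword f = 0; f < Fm.n_rows; ++f)
    for (int q = 0; q < m; ++q) {
      int i = pairs(q, 0) - 1, j = pairs(q, 1) - 1;
      double s = 0;
      for (int d = 0; d < 3; ++d) {
        double dx = Fm(f, 3 * i + d) - Fm(f, 3 * j + d);
        s += dx * dx;
      }
      out(f, q) = std::sqrt(s) < lam * r0[q] ? 1 : 0;
    }
  return out;
}
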