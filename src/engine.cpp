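// Langevin (BAOAB) integrators with GaMD boosting, in compiled code.
//
// Two engines are exposed:
//   cpp_run_surface : dynamics of a single particle on an analytic 1D/2D
//                     potential surface, optionally with a total-energy
//                     GaMD boost (frozen E, k per call).
//   cpp_run_beads   : dynamics of the bead peptide + fixed receptor (+
//                     mobile environment beads) system with the
//                     essential-peptide energy decomposition and the
//                     dual (peptide / rest) boost.
//
// Boost parameters are frozen within a call; the R layer chunks calls to
// refresh statistics during equilibration. Randomness is a self-contained
// mt19937_64 + polar Box-Muller stream keyed by (seed, stream) so results
// are reproducible and replicas are independent.

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

namespace {

struct RNG {
  std::mt19937_64 gen;
  bool has_spare;
  double spare;
  RNG(int seed, int stream) : has_spare(false), spare(0.0) {
    std::seed_seq ss{seed, stream};
    gen.seed(ss);
  }
  double unif() {
    // 53-bit uniform in [0, 1)
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m;
    has_spare = true;
    return u * m;
  }
};

// ---- analytic surfaces -------------------------------------------------
// kind 1: harmonic, pars = (kappa)            V = kappa/2 * |x|^2
// kind 2: double well (1D), pars = (h, a)     V = h * (x^2 - a^2)^2 / a^4
// kind 3: three-state (2D), pars =
//   (nmin, then per minimum cx, cy, depth, width,
//    then lox, hix, loy, hiy, kwall)
//   V = -sum_i depth_i exp(-|r - c_i|^2 / (2 w_i^2)) + quadratic walls
double surf_energy(int kind, const std::vector<double>& p,
                   const double* x, int d, double* grad) {
  for (int j = 0; j < d; ++j) grad[j] = 0.0;
  if (kind == 1) {
    double kap = p[0], v = 0.0;
    for (int j = 0; j < d; ++j) { v += 0.5 * kap * x[j] * x[j]; grad[j] = kap * x[j]; }
    return v;
  } else if (kind == 2) {
    double h = p[0], a = p[1], a4 = a * a * a * a;
    double q = x[0] * x[0] - a * a;
    grad[0] = 4.0 * h * x[0] * q / a4;
    return h * q * q / a4;
  } else if (kind == 3) {
    int nmin = (int) p[0];
    double v = 0.0;
    for (int i = 0; i < nmin; ++i) {
      double cx = p[1 + 4 * i], cy = p[2 + 4 * i];
      double dep = p[3 + 4 * i], w = p[4 + 4 * i];
      double dx = x[0] - cx, dy = x[1] - cy;
      double e = std::exp(-(dx * dx + dy * dy) / (2.0 * w * w));
      v -= dep * e;
      grad[0] += dep * e * dx / (w * w);
      grad[1] += dep * e * dy / (w * w);
    }
    int off = 1 + 4 * nmin;
    double kw = p[off + 4];
    for (int j = 0; j < 2; ++j) {
      double lo = p[off + 2 * j], hi = p[off + 2 * j + 1];
      if (x[j] < lo) { v += 0.5 * kw * (lo - x[j]) * (lo - x[j]); grad[j] -= kw * (lo - x[j]); }
      if (x[j] > hi) { v += 0.5 * kw * (x[j] - hi) * (x[j] - hi); grad[j] += kw * (x[j] - hi); }
    }
    return v;
  }
  stop("unknown surface kind");
  return NA_REAL;
}

inline double boost_dv(double v, double E, double k, bool on) {
  if (!on || v >= E) return 0.0;
  double d = E - v;
  return 0.5 * k * d * d;
}
inline double boost_scale(double v, double E, double k, bool on) {
  if (!on || v >= E) return 1.0;
  return 1.0 - k * (E - v);
}

} // namespace

// [[Rcpp::export]]
List cpp_run_surface(int kind, NumericVector pars,
                     NumericVector x0, NumericVector v0,
                     int nsteps, double dt, double friction, double kT,
                     double E, double k, bool boost_on,
                     int seed, int stream, int stride,
                     double overflow_guard) {
  int d = x0.size();
  std::vector<double> p(pars.begin(), pars.end());
  double x[2], vel[2], grad[2];
  for (int j = 0; j < d; ++j) { x[j] = x0[j]; vel[j] = v0[j]; }

  RNG rng(seed, stream);
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * kT);

  int nrec = nsteps / stride;
  NumericMatrix X(nrec, d);
  NumericVector Vrec(nrec), DVrec(nrec);
  NumericVector Vall(nsteps); // every step, for statistics collection

  double V = surf_energy(kind, p, x, d, grad);
  double s = boost_scale(V, E, k, boost_on);
  double f[2];
  for (int j = 0; j < d; ++j) f[j] = -grad[j] * s;

  int irec = 0;
  for (int i = 0; i < nsteps; ++i) {
    for (int j = 0; j < d; ++j) vel[j] += 0.5 * dt * f[j];      // B
    for (int j = 0; j < d; ++j) x[j] += 0.5 * dt * vel[j];      // A
    for (int j = 0; j < d; ++j) vel[j] = c1 * vel[j] + c2 * rng.norm(); // O
    for (int j = 0; j < d; ++j) x[j] += 0.5 * dt * vel[j];      // A
    V = surf_energy(kind, p, x, d, grad);
    if (!std::isfinite(V) || std::fabs(V) > overflow_guard)
      stop("integration instability: |V| exceeded guard at step %d", i + 1);
    s = boost_scale(V, E, k, boost_on);
    for (int j = 0; j < d; ++j) { f[j] = -grad[j] * s; vel[j] += 0.5 * dt * f[j]; } // B
    Vall[i] = V;
    if ((i + 1) % stride == 0) {
      for (int j = 0; j < d; ++j) X(irec, j) = x[j];
      Vrec[irec] = V;
      DVrec[irec] = boost_dv(V, E, k, boost_on);
      ++irec;
    }
  }
  NumericVector xf(d), vf(d);
  for (int j = 0; j < d; ++j) { xf[j] = x[j]; vf[j] = vel[j]; }
  return List::create(_["x"] = xf, _["v"] = vf, _["X"] = X,
                      _["V"] = Vrec, _["dV"] = DVrec, _["Vall"] = Vall);
}

// [[Rcpp::export]]
NumericVector cpp_surface_energy(int kind, NumericVector pars, NumericMatrix pts) {
  int d = pts.ncol();
  std::vector<double> p(pars.begin(), pars.end());
  double x[2], grad[2];
  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    for (int j = 0; j < d; ++j) x[j] = pts(i, j);
    out[i] = surf_energy(kind, p, x, d, grad);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_surface_gradient(int kind, NumericVector pars, NumericMatrix pts) {
  int d = pts.ncol();
  std::vector<double> p(pars.begin(), pars.end());
  double x[2], grad[2];
  NumericMatrix out(pts.nrow(), d);
  for (int i = 0; i < pts.nrow(); ++i) {
    for (int j = 0; j < d; ++j) x[j] = pts(i, j);
    surf_energy(kind, p, x, d, grad);
    for (int j = 0; j < d; ++j) out(i, j) = grad[j];
  }
  return out;
}

// ---- bead system -------------------------------------------------------
//
// Energy terms and their classification (t: 0 = peptide L, 1 = receptor P,
// 2 = environment E):
//   bond L-L                      -> V_LL,b   (peptide term)
//   nonbonded L-L                 -> V_LL,nb  (peptide term)
//   nonbonded L-P                 -> V_PL,nb  (peptide term)
//   nonbonded L-E                 -> V_LE,nb  (peptide term)
//   everything else (E-E, P-E, P-P nonbonded, non-peptide bonds,
//   confining wall on every mobile bead)      -> V_rest
// V_L = first four; V_D = V_rest.
//
// Pair potential: finite soft-core repulsion A (1 - (r/rc)^2)^2 for r < rc
// plus, for designated attractive pairs, a Gaussian well
// -eps exp(-(r - r0)^2 / (2 w^2)).

namespace {

struct BeadModel {
  int n;
  IntegerVector type;       // 0 L, 1 P(receptor), 2 E
  IntegerMatrix bonds;      // m x 2, 0-based
  NumericVector bond_k, bond_r0;
  IntegerVector pi_, pj_;   // pair list, 0-based
  NumericVector rep_A, rep_rc, att_eps, att_r0, att_w;
  double wall_R, wall_k;
};

// comps: 0 ll_b, 1 ll_nb, 2 pl_nb, 3 le_nb, 4 rest
void bead_energy(const BeadModel& M, const NumericMatrix& x,
                 double* comps, NumericMatrix* fL, NumericMatrix* fD) {
  for (int c = 0; c < 5; ++c) comps[c] = 0.0;
  if (fL) { std::fill(fL->begin(), fL->end(), 0.0); std::fill(fD->begin(), fD->end(), 0.0); }

  // bonds
  for (int b = 0; b < M.bonds.nrow(); ++b) {
    int i = M.bonds(b, 0), j = M.bonds(b, 1);
    double dx[3], r2 = 0.0;
    for (int c = 0; c < 3; ++c) { dx[c] = x(i, c) - x(j, c); r2 += dx[c] * dx[c]; }
    double r = std::sqrt(r2);
    double dr = r - M.bond_r0[b];
    double v = 0.5 * M.bond_k[b] * dr * dr;
    bool pep = (M.type[i] == 0 && M.type[j] == 0);
    comps[pep ? 0 : 4] += v;
    if (fL && r > 1e-12) {
      double fmag = -M.bond_k[b] * dr / r; // dV/dr * (-1/r) => force coeff on dx
      NumericMatrix& F = pep ? *fL : *fD;
      for (int c = 0; c < 3; ++c) { F(i, c) += fmag * dx[c]; F(j, c) -= fmag * dx[c]; }
    }
  }

  // nonbonded pairs
  for (int q = 0; q < M.pi_.size(); ++q) {
    int i = M.pi_[q], j = M.pj_[q];
    double dx[3], r2 = 0.0;
    for (int c = 0; c < 3; ++c) { dx[c] = x(i, c) - x(j, c); r2 += dx[c] * dx[c]; }
    double r = std::sqrt(r2);
    double v = 0.0, dvdr = 0.0;
    double rc = M.rep_rc[q], A = M.rep_A[q];
    if (r < rc) {
      double u = 1.0 - (r * r) / (rc * rc);
      v += A * u * u;
      dvdr += -4.0 * A * u * r / (rc * rc);
    }
    double eps = M.att_eps[q];
    if (eps > 0.0) {
      double w = M.att_w[q], d0 = r - M.att_r0[q];
      double e = std::exp(-d0 * d0 / (2.0 * w * w));
      v += -eps * e;
      dvdr += eps * e * d0 / (w * w);
    }
    int ti = M.type[i], tj = M.type[j];
    int cls;
    if (ti == 0 && tj == 0) cls = 1;
    else if ((ti == 0 && tj == 1) || (ti == 1 && tj == 0)) cls = 2;
    else if ((ti == 0 && tj == 2) || (ti == 2 && tj == 0)) cls = 3;
    else cls = 4;
    comps[cls] += v;
    if (fL && r > 1e-12) {
      double fmag = -dvdr / r;
      NumericMatrix& F = (cls == 4) ? *fD : *fL;
      for (int c = 0; c < 3; ++c) { F(i, c) += fmag * dx[c]; F(j, c) -= fmag * dx[c]; }
    }
  }

  // confining wall (mobile beads; receptor is fixed, wall there is inert)
  for (int i = 0; i < M.n; ++i) {
    if (M.type[i] == 1) continue;
    double r2 = 0.0;
    for (int c = 0; c < 3; ++c) r2 += x(i, c) * x(i, c);
    double r = std::sqrt(r2);
    if (r > M.wall_R) {
      double d = r - M.wall_R;
      comps[4] += 0.5 * M.wall_k * d * d;
      if (fD && r > 1e-12) {
        double fmag = -M.wall_k * d / r;
        for (int c = 0; c < 3; ++c) (*fD)(i, c) += fmag * x(i, c);
      }
    }
  }
}

BeadModel as_model(List model) {
  BeadModel M;
  M.type = model["type"];
  M.n = M.type.size();
  M.bonds = as<IntegerMatrix>(model["bonds"]);
  M.bond_k = model["bond_k"];
  M.bond_r0 = model["bond_r0"];
  M.pi_ = model["pair_i"];
  M.pj_ = model["pair_j"];
  M.rep_A = model["rep_A"];
  M.rep_rc = model["rep_rc"];
  M.att_eps = model["att_eps"];
  M.att_r0 = model["att_r0"];
  M.att_w = model["att_w"];
  M.wall_R = as<double>(model["wall_R"]);
  M.wall_k = as<double>(model["wall_k"]);
  return M;
}

} // namespace

// [[Rcpp::export]]
List cpp_bead_energy(List model, NumericMatrix x) {
  BeadModel M = as_model(model);
  double comps[5];
  NumericMatrix fL(M.n, 3), fD(M.n, 3);
  bead_energy(M, x, comps, &fL, &fD);
  NumericVector cv(5);
  for (int c = 0; c < 5; ++c) cv[c] = comps[c];
  cv.names() = CharacterVector::create("ll_b", "ll_nb", "pl_nb", "le_nb", "rest");
  return List::create(_["components"] = cv, _["fL"] = fL, _["fD"] = fD);
}

// [[Rcpp::export]]
List cpp_run_beads(List model, NumericMatrix x0, NumericMatrix v0,
                   NumericVector mass,
                   int nsteps, double dt, double friction, double kT,
                   double EL, double kL, bool boostL,
                   double ED, double kD, bool boostD,
                   int seed, int stream, int stride,
                   double overflow_guard) {
  BeadModel M = as_model(model);
  int n = M.n;
  NumericMatrix x(clone(x0)), vel(clone(v0));
  NumericMatrix fL(n, 3), fD(n, 3);
  RNG rng(seed, stream);
  double c1 = std::exp(-friction * dt);

  double comps[5];
  bead_energy(M, x, comps, &fL, &fD);
  double VL = comps[0] + comps[1] + comps[2] + comps[3];
  double VD = comps[4];
  double sL = boost_scale(VL, EL, kL, boostL);
  double sD = boost_scale(VD, ED, kD, boostD);

  int nrec = nsteps / stride;
  NumericMatrix frames(nrec, n * 3);
  NumericMatrix crec(nrec, 5);
  NumericVector VLall(nsteps), VDall(nsteps);
  NumericVector VLrec(nrec), VDrec(nrec), dVLrec(nrec), dVDrec(nrec);

  std::vector<bool> mobile(n);
  std::vector<double> c2(n);
  for (int i = 0; i < n; ++i) {
    mobile[i] = (M.type[i] != 1);
    c2[i] = std::sqrt((1.0 - c1 * c1) * kT / mass[i]);
  }

  int irec = 0;
  for (int s = 0; s < nsteps; ++s) {
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      for (int c = 0; c < 3; ++c) {
        double f = sL * fL(i, c) + sD * fD(i, c);
        vel(i, c) += 0.5 * dt * f / mass[i];             // B
        x(i, c) += 0.5 * dt * vel(i, c);                 // A
      }
    }
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      for (int c = 0; c < 3; ++c) {
        vel(i, c) = c1 * vel(i, c) + c2[i] * rng.norm(); // O
        x(i, c) += 0.5 * dt * vel(i, c);                 // A
      }
    }
    bead_energy(M, x, comps, &fL, &fD);
    VL = comps[0] + comps[1] + comps[2] + comps[3];
    VD = comps[4];
    if (!std::isfinite(VL + VD) || std::fabs(VL + VD) > overflow_guard)
      stop("integration instability: |V| exceeded guard at step %d", s + 1);
    sL = boost_scale(VL, EL, kL, boostL);
    sD = boost_scale(VD, ED, kD, boostD);
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      for (int c = 0; c < 3; ++c) {
        double f = sL * fL(i, c) + sD * fD(i, c);
        vel(i, c) += 0.5 * dt * f / mass[i];             // B
      }
    }
    VLall[s] = VL;
    VDall[s] = VD;
    if ((s + 1) % stride == 0) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c) frames(irec, 3 * i + c) = x(i, c);
      for (int c = 0; c < 5; ++c) crec(irec, c) = comps[c];
      VLrec[irec] = VL;
      VDrec[irec] = VD;
      dVLrec[irec] = boost_dv(VL, EL, kL, boostL);
      dVDrec[irec] = boost_dv(VD, ED, kD, boostD);
      ++irec;
    }
  }
  return List::create(_["x"] = x, _["v"] = vel, _["frames"] = frames,
                      _["components"] = crec,
                      _["VL"] = VLrec, _["VD"] = VDrec,
                      _["dVL"] = dVLrec, _["dVD"] = dVDrec,
                      _["VLall"] = VLall, _["VDall"] = VDall);
}
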