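#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// Internal unit system: kcal/mol, Angstrom, ps, amu, elementary charge.
// 1 amu*A^2/ps^2 ("mdu") = 10 J/mol = 1/418.4 kcal/mol exactly.
static const double COULOMB_K   = 332.0637;             // kcal*A/(mol*e^2)
static const double EV_PER_KCAL = 0.0433641;            // 1 kcal/mol in eV
static const double KB_EV       = 8.6173e-5;            // eV/K
static const double KB_KCAL     = KB_EV / EV_PER_KCAL;  // kcal/(mol*K)
static const double MDU_PER_KCAL = 418.4;
static const double KCAL_PER_MDU = 1.0 / 418.4;
static const double KB_MDU      = KB_KCAL * MDU_PER_KCAL;

// minimum-image displacement in place; h rows are the cell vectors, so
// cart = frac %*% h and frac = cart %*% hinv
static inline void min_image(double d[3], const double* h, const double* hinv,
                             const int* per, bool any_per) {
  if (!any_per) return;
  double s[3];
  for (int i = 0; i < 3; ++i)
    s[i] = d[0] * hinv[0 + i * 3] + d[1] * hinv[1 + i * 3] + d[2] * hinv[2 + i * 3];
  for (int i = 0; i < 3; ++i)
    if (per[i]) s[i] -= std::round(s[i]);
  for (int j = 0; j < 3; ++j)
    d[j] = s[0] * h[0 + j * 3] + s[1] * h[1 + j * 3] + s[2] * h[2 + j * 3];
}

static inline long long pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

struct FF {
  const double* h;
  const double* hinv;
  int per[3];
  bool any_per;
  std::vector<int> sp;  // 0-based species index
  const double* q;
  const double* eps;    // S x S column-major
  const double* sig;
  const int* form;      // 1 = LJ 12-6, 2 = LJ 9-6
  int S;
  double cutoff;        // <= 0 or non-finite -> no cutoff
  bool shift;
  std::unordered_set<long long> excl;
};

// energies returned in ec/elj; fmag is -dU/dr
static inline void nonbonded_pair(double r, double qq, double eps, double sig,
                                  int form, double cutoff, bool shift,
                                  double& ec, double& elj, double& fmag) {
  double ecoul = COULOMB_K * qq / r;
  fmag = COULOMB_K * qq / (r * r);
  double el = 0.0;
  if (eps > 0.0) {
    if (form == 1) {
      double sr6 = std::pow(sig / r, 6), sr12 = sr6 * sr6;
      el = 4.0 * eps * (sr12 - sr6);
      fmag += 4.0 * eps * (12.0 * sr12 - 6.0 * sr6) / r;
    } else {
      double sr3 = (sig / r) * (sig / r) * (sig / r);
      double sr6 = sr3 * sr3, sr9 = sr6 * sr3;
      el = eps * (2.0 * sr9 - 3.0 * sr6);
      fmag += eps * (18.0 * sr9 - 18.0 * sr6) / r;
    }
  }
  if (shift && std::isfinite(cutoff) && cutoff > 0.0) {
    ecoul -= COULOMB_K * qq / cutoff;
    if (eps > 0.0) {
      if (form == 1) {
        double sc6 = std::pow(sig / cutoff, 6);
        el -= 4.0 * eps * (sc6 * sc6 - sc6);
      } else {
        double sc3 = (sig / cutoff) * (sig / cutoff) * (sig / cutoff);
        el -= eps * (2.0 * sc3 * sc3 * sc3 - 3.0 * sc3 * sc3);
      }
    }
  }
  ec = ecoul;
  elj = el;
}

// full energy + force evaluation; forces accumulated into f (n x 3, col-major)
static void eval_all(int n, const double* x, const FF& ff,
                     const IntegerMatrix& bonds, const NumericVector& bond_k,
                     const NumericVector& bond_r0,
                     const IntegerMatrix& angles, const NumericVector& ang_k,
                     const NumericVector& ang_t0,
                     double* f, double& e_coul, double& e_lj,
                     double& e_bond, double& e_angle) {
  e_coul = e_lj = e_bond = e_angle = 0.0;
  std::fill(f, f + 3 * n, 0.0);
  bool use_cut = std::isfinite(ff.cutoff) && ff.cutoff > 0.0;
  double cut2 = use_cut ? ff.cutoff * ff.cutoff : 0.0;

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (ff.excl.count(pair_key(i, j, n))) continue;
      double d[3] = { x[i] - x[j], x[i + n] - x[j + n], x[i + 2 * n] - x[j + 2 * n] };
      min_image(d, ff.h, ff.hinv, ff.per, ff.any_per);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (use_cut && r2 > cut2) continue;
      double r = std::sqrt(r2);
      if (r < 1e-12) stop("overlapping atoms in nonbonded evaluation");
      int si = ff.sp[i], sj = ff.sp[j];
      double eps = ff.eps[si + sj * ff.S];
      double sig = ff.sig[si + sj * ff.S];
      int form = ff.form[si + sj * ff.S];
      double ec, el, fmag;
      nonbonded_pair(r, ff.q[i] * ff.q[j], eps, sig, form, ff.cutoff, ff.shift,
                     ec, el, fmag);
      e_coul += ec;
      e_lj += el;
      double fr = fmag / r;
      for (int k = 0; k < 3; ++k) {
        f[i + k * n] += fr * d[k];
        f[j + k * n] -= fr * d[k];
      }
    }
  }

  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double d[3] = { x[i] - x[j], x[i + n] - x[j + n], x[i + 2 * n] - x[j + 2 * n] };
    min_image(d, ff.h, ff.hinv, ff.per, ff.any_per);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double dr = r - bond_r0[b];
    e_bond += bond_k[b] * dr * dr;
    double fr = -2.0 * bond_k[b] * dr / r;   // -dU/dr along d
    for (int k = 0; k < 3; ++k) {
      f[i + k * n] += fr * d[k];
      f[j + k * n] -= fr * d[k];
    }
  }

  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a, 0) - 1, j = angles(a, 1) - 1, kk = angles(a, 2) - 1;
    double rij[3] = { x[i] - x[j], x[i + n] - x[j + n], x[i + 2 * n] - x[j + 2 * n] };
    double rkj[3] = { x[kk] - x[j], x[kk + n] - x[j + n], x[kk + 2 * n] - x[j + 2 * n] };
    min_image(rij, ff.h, ff.hinv, ff.per, ff.any_per);
    min_image(rkj, ff.h, ff.hinv, ff.per, ff.any_per);
    double nij = std::sqrt(rij[0] * rij[0] + rij[1] * rij[1] + rij[2] * rij[2]);
    double nkj = std::sqrt(rkj[0] * rkj[0] + rkj[1] * rkj[1] + rkj[2] * rkj[2]);
    double c = (rij[0] * rkj[0] + rij[1] * rkj[1] + rij[2] * rkj[2]) / (nij * nkj);
    c = std::max(-1.0, std::min(1.0, c));
    double theta = std::acos(c);
    double dth = theta - ang_t0[a];
    e_angle += ang_k[a] * dth * dth;
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-8) s = 1e-8;
    double dudt = 2.0 * ang_k[a] * dth;
    for (int k = 0; k < 3; ++k) {
      double u = rij[k] / nij, w = rkj[k] / nkj;
      double fi = dudt * (w - c * u) / (nij * s);
      double fk = dudt * (u - c * w) / (nkj * s);
      f[i + k * n] += fi;
      f[kk + k * n] += fk;
      f[j + k * n] -= (fi + fk);
    }
  }
}

static FF make_ff(const NumericMatrix& h, const NumericMatrix& hinv,
                  const LogicalVector& periodic, const IntegerVector& sp,
                  const NumericVector& q, const NumericMatrix& eps,
                  const NumericMatrix& sig, const IntegerMatrix& form,
                  double cutoff, bool shift, const IntegerMatrix& excl,
                  int n) {
  FF ff;
  ff.h = h.begin();
  ff.hinv = hinv.begin();
  ff.any_per = false;
  for (int i = 0; i < 3; ++i) {
    ff.per[i] = periodic[i] ? 1 : 0;
    if (ff.per[i]) ff.any_per = true;
  }
  ff.sp.assign(sp.size(), 0);
  for (int i = 0; i < sp.size(); ++i) ff.sp[i] = sp[i] - 1;
  ff.q = q.begin();
  ff.eps = eps.begin();
  ff.sig = sig.begin();
  ff.form = form.begin();
  ff.S = eps.nrow();
  ff.cutoff = cutoff;
  ff.shift = shift;
  for (int r = 0; r < excl.nrow(); ++r)
    ff.excl.insert(pair_key(excl(r, 0) - 1, excl(r, 1) - 1, n));
  return ff;
}

// [[Rcpp::export]]
List energy_forces_cpp(NumericMatrix pos, NumericMatrix h, NumericMatrix hinv,
                       LogicalVector periodic, IntegerVector sp, NumericVector q,
                       NumericMatrix eps, NumericMatrix sig, IntegerMatrix form,
                       double cutoff, bool shift, IntegerMatrix bonds,
                       NumericVector bond_k, NumericVector bond_r0,
                       IntegerMatrix angles, NumericVector ang_k,
                       NumericVector ang_t0, IntegerMatrix excl) {
  int n = pos.nrow();
  FF ff = make_ff(h, hinv, periodic, sp, q, eps, sig, form, cutoff, shift, excl, n);
  NumericMatrix f(n, 3);
  double ec, el, eb, ea;
  eval_all(n, pos.begin(), ff, bonds, bond_k, bond_r0, angles, ang_k, ang_t0,
           f.begin(), ec, el, eb, ea);
  return List::create(_["coulomb"] = ec, _["lj"] = el, _["bond"] = eb,
                      _["angle"] = ea, _["total"] = ec + el + eb + ea,
                      _["forces"] = f);
}

// Velocity-Verlet with Andersen-style collisional thermostat: each atom
// independently suffers an elastic collision with a Maxwell-distributed
// virtual particle with probability collision_rate*dt per step.
// T_ref(t) = tref0 + tref_rate * t; RNG is R's, so set.seed() governs runs.
// [[Rcpp::export]]
List run_md_cpp(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                NumericMatrix h, NumericMatrix hinv, LogicalVector periodic,
                IntegerVector sp, NumericVector q, NumericMatrix eps,
                NumericMatrix sig, IntegerMatrix form, double cutoff,
                bool shift, IntegerMatrix bonds, NumericVector bond_k,
                NumericVector bond_r0, IntegerMatrix angles,
                NumericVector ang_k, NumericVector ang_t0, IntegerMatrix excl,
                double dt, int n_steps, int sample_every, double coll_rate,
                NumericVector m0, double tref0, double tref_rate, int ndof,
                double blowup) {
  int n = pos0.nrow();
  FF ff = make_ff(h, hinv, periodic, sp, q, eps, sig, form, cutoff, shift, excl, n);
  std::vector<double> x(pos0.begin(), pos0.end());
  std::vector<double> v(vel0.begin(), vel0.end());
  std::vector<double> f(3 * n);
  double ec, el, eb, ea;
  eval_all(n, x.data(), ff, bonds, bond_k, bond_r0, angles, ang_k, ang_t0,
           f.data(), ec, el, eb, ea);
  double epot = ec + el + eb + ea;

  int n_frames = n_steps / sample_every + 1;
  List frames(n_frames), vframes(n_frames);
  NumericVector times(n_frames), trefs(n_frames), tkins(n_frames),
      epots(n_frames), ekins(n_frames);
  int fi = 0;
  double pcoll = coll_rate * dt;

  auto record = [&](int step) {
    NumericMatrix fr(n, 3), vfr(n, 3);
    std::copy(x.begin(), x.end(), fr.begin());
    std::copy(v.begin(), v.end(), vfr.begin());
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * mass[i] *
            (v[i] * v[i] + v[i + n] * v[i + n] + v[i + 2 * n] * v[i + 2 * n]);
    frames[fi] = fr;
    vframes[fi] = vfr;
    times[fi] = step * dt;
    trefs[fi] = tref0 + tref_rate * step * dt;
    tkins[fi] = 2.0 * ke / (ndof * KB_MDU);
    epots[fi] = epot;
    ekins[fi] = ke * KCAL_PER_MDU;
    ++fi;
  };
  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double am = 0.5 * dt * MDU_PER_KCAL / mass[i];
      for (int k = 0; k < 3; ++k) v[i + k * n] += am * f[i + k * n];
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += dt * v[i];
    for (int i = 0; i < 3 * n; ++i)
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > blowup)
        stop("integration blew up at step %d", step);
    eval_all(n, x.data(), ff, bonds, bond_k, bond_r0, angles, ang_k, ang_t0,
             f.data(), ec, el, eb, ea);
    epot = ec + el + eb + ea;
    for (int i = 0; i < n; ++i) {
      double am = 0.5 * dt * MDU_PER_KCAL / mass[i];
      for (int k = 0; k < 3; ++k) v[i + k * n] += am * f[i + k * n];
    }
    if (pcoll > 0.0) {
      double tref = tref0 + tref_rate * step * dt;
      for (int i = 0; i < n; ++i) {
        if (unif_rand() < pcoll) {
          double mm0 = m0[i] > 0.0 ? m0[i] : mass[i];
          double sd = tref > 0.0 ? std::sqrt(KB_MDU * tref / mm0) : 0.0;
          double fac = 2.0 * mm0 / (mm0 + mass[i]);
          for (int k = 0; k < 3; ++k) {
            double v0 = sd > 0.0 ? sd * norm_rand() : 0.0;
            v[i + k * n] += fac * (v0 - v[i + k * n]);
          }
        }
      }
    }
    if (step % sample_every == 0) record(step);
  }

  NumericMatrix posf(n, 3), velf(n, 3);
  std::copy(x.begin(), x.end(), posf.begin());
  std::copy(v.begin(), v.end(), velf.begin());
  return List::create(_["frames"] = frames, _["vel_frames"] = vframes,
                      _["times"] = times,
                      _["t_ref"] = trefs, _["t_kin"] = tkins,
                      _["e_pot"] = epots, _["e_kin"] = ekins,
                      _["positions"] = posf, _["velocities"] = velf);
}
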