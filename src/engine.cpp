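// Trajectory engine for the built-in two-state 1D analytic models.
//
// All quantities in Hartree atomic units (hbar = 1, mass in m_e, length in
// bohr, time in a.u.).  The R layer owns validation and the general
// (N-state / N-DOF) operation API; this file owns the tight per-step loop:
// velocity-Verlet nuclear motion on the active surface, RK4 electronic
// substeps with linear interpolation of (eps, v.d) across the nuclear step,
// the fewest-switches hop test, velocity rescaling, and the three
// decoherence schemes (SHXF auxiliary trajectories, energy-based damping,
// A-FSSH moments + stochastic collapse).

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;
typedef std::complex<double> cplx;

// ---------------------------------------------------------------------------
// counter-based RNG: one independent splitmix64 stream per trajectory
// ---------------------------------------------------------------------------

struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  double unif() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z = z ^ (z >> 31);
    return (z >> 11) * 0x1.0p-53; // in [0, 1)
  }
};

static uint64_t stream_seed(double base_seed, double traj_id) {
  // mix base seed and trajectory index into one 64-bit stream key
  uint64_t b = (uint64_t)(int64_t)base_seed;
  uint64_t t = (uint64_t)(int64_t)traj_id;
  uint64_t z = b * 0x9E3779B97F4A7C15ULL + t * 0xD1342543DE82EF95ULL + 0x632BE59BD9B4E019ULL;
  z = (z ^ (z >> 29)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 32));
  return z;
}

// ---------------------------------------------------------------------------
// built-in diabatic models (symmetric 2x2, one nuclear DOF)
// ---------------------------------------------------------------------------
// id 1: single avoided crossing   (A, B, C, D)
// id 2: dual avoided crossing     (A, B, C, D, E0)
// id 3: extended coupling with reflection (A, B, C)
// id 4: sharp sloped crossing     (A, B, C, D)

static void model_eval(int id, const double* p, double x,
                       double& h11, double& h22, double& h12,
                       double& g11, double& g22, double& g12) {
  switch (id) {
  case 1: {
    double A = p[0], B = p[1], C = p[2], D = p[3];
    if (x >= 0) { h11 =  A * (1.0 - std::exp(-B * x)); g11 =  A * B * std::exp(-B * x); }
    else        { h11 = -A * (1.0 - std::exp( B * x)); g11 =  A * B * std::exp( B * x); }
    h22 = -h11; g22 = -g11;
    h12 = C * std::exp(-D * x * x); g12 = -2.0 * D * x * h12;
    break;
  }
  case 2: {
    double A = p[0], B = p[1], C = p[2], D = p[3], E0 = p[4];
    h11 = 0.0; g11 = 0.0;
    h22 = -A * std::exp(-B * x * x) + E0;
    g22 = 2.0 * A * B * x * std::exp(-B * x * x);
    h12 = C * std::exp(-D * x * x); g12 = -2.0 * D * x * h12;
    break;
  }
  case 3: {
    double A = p[0], B = p[1], C = p[2];
    h11 = A; h22 = -A; g11 = 0.0; g22 = 0.0;
    if (x < 0) { h12 = B * std::exp( C * x);         g12 = B * C * std::exp( C * x); }
    else       { h12 = B * (2.0 - std::exp(-C * x)); g12 = B * C * std::exp(-C * x); }
    break;
  }
  case 4: {
    double A = p[0], B = p[1], C = p[2], D = p[3];
    double th = std::tanh(B * x);
    h11 =  A * th; g11 =  A * B * (1.0 - th * th);
    h22 = -h11;    g22 = -g11;
    h12 = C * std::exp(-D * x * x); g12 = -2.0 * D * x * h12;
    break;
  }
  default:
    stop("unknown built-in model id");
  }
}

// [[Rcpp::export(name = ".model_eval_cpp")]]
List model_eval_cpp(int id, NumericVector params, double x) {
  double h11, h22, h12, g11, g22, g12;
  model_eval(id, params.begin(), x, h11, h22, h12, g11, g22, g12);
  NumericMatrix H(2, 2), G(2, 2);
  H(0, 0) = h11; H(1, 1) = h22; H(0, 1) = H(1, 0) = h12;
  G(0, 0) = g11; G(1, 1) = g22; G(0, 1) = G(1, 0) = g12;
  return List::create(_["H"] = H, _["dH"] = G);
}

// vectorized evaluation for grid-based (wavepacket) work
// [[Rcpp::export(name = ".model_eval_grid_cpp")]]
List model_eval_grid_cpp(int id, NumericVector params, NumericVector x) {
  int n = x.size();
  NumericVector v11(n), v22(n), v12(n);
  double h11, h22, h12, g11, g22, g12;
  for (int i = 0; i < n; ++i) {
    model_eval(id, params.begin(), x[i], h11, h22, h12, g11, g22, g12);
    v11[i] = h11; v22[i] = h22; v12[i] = h12;
  }
  return List::create(_["V11"] = v11, _["V22"] = v22, _["V12"] = v12);
}

// ---------------------------------------------------------------------------
// adiabatic point: closed-form symmetric 2x2 diagonalization
// ---------------------------------------------------------------------------

struct Adiab {
  double e0, e1;      // adiabatic energies, ascending
  double u[2][2];     // eigvec columns: [.][0] lower, [.][1] upper
  double ga0, ga1;    // adiabatic gradients (Hellmann-Feynman)
  double d01;         // NACV <u0|d/dx u1>
};

static const double DEGEN_TOL = 1e-13;

static Adiab adiabatize2(int id, const double* p, double x,
                         const Adiab* prev, bool want_grad) {
  double h11, h22, h12, g11, g22, g12;
  model_eval(id, p, x, h11, h22, h12, g11, g22, g12);
  double mm = 0.5 * (h11 + h22), dd = 0.5 * (h11 - h22);
  double r = std::sqrt(dd * dd + h12 * h12);
  if (r < DEGEN_TOL)
    stop("conical-intersection point: degenerate adiabatic energies (NACV undefined)");
  Adiab a;
  a.e0 = mm - r; a.e1 = mm + r;
  double al = std::atan2(h12, dd);
  double c = std::cos(0.5 * al), s = std::sin(0.5 * al);
  // upper eigvec (c, s); lower (-s, c)
  a.u[0][0] = -s; a.u[1][0] = c;
  a.u[0][1] =  c; a.u[1][1] = s;
  if (prev) { // sign continuity with previous step
    for (int j = 0; j < 2; ++j) {
      double ov = a.u[0][j] * prev->u[0][j] + a.u[1][j] * prev->u[1][j];
      if (ov < 0) { a.u[0][j] = -a.u[0][j]; a.u[1][j] = -a.u[1][j]; }
    }
  } else {    // fallback phase convention: first non-negligible component > 0
    for (int j = 0; j < 2; ++j) {
      double lead = (std::fabs(a.u[0][j]) > 1e-12) ? a.u[0][j] : a.u[1][j];
      if (lead < 0) { a.u[0][j] = -a.u[0][j]; a.u[1][j] = -a.u[1][j]; }
    }
  }
  if (want_grad) {
    // G = U^T dH U
    double c0[2] = { a.u[0][0], a.u[1][0] }, c1[2] = { a.u[0][1], a.u[1][1] };
    double dc0[2] = { g11 * c0[0] + g12 * c0[1], g12 * c0[0] + g22 * c0[1] };
    double dc1[2] = { g11 * c1[0] + g12 * c1[1], g12 * c1[0] + g22 * c1[1] };
    a.ga0 = c0[0] * dc0[0] + c0[1] * dc0[1];
    a.ga1 = c1[0] * dc1[0] + c1[1] * dc1[1];
    double G01 = c0[0] * dc1[0] + c0[1] * dc1[1];
    a.d01 = G01 / (a.e1 - a.e0);
  } else {
    a.ga0 = a.ga1 = a.d01 = 0.0;
  }
  return a;
}

// adiabatic energies only, no phase bookkeeping (for auxiliary trajectories)
static void adiab_energies(int id, const double* p, double x, double& e0, double& e1) {
  double h11, h22, h12, g11, g22, g12;
  model_eval(id, p, x, h11, h22, h12, g11, g22, g12);
  double mm = 0.5 * (h11 + h22), dd = 0.5 * (h11 - h22);
  double r = std::sqrt(dd * dd + h12 * h12);
  e0 = mm - r; e1 = mm + r;
}

// [[Rcpp::export(name = ".adiabatic_point_cpp")]]
List adiabatic_point_cpp(int id, NumericVector params, double x) {
  Adiab a = adiabatize2(id, params.begin(), x, NULL, true);
  NumericMatrix U(2, 2);
  U(0, 0) = a.u[0][0]; U(1, 0) = a.u[1][0];
  U(0, 1) = a.u[0][1]; U(1, 1) = a.u[1][1];
  return List::create(_["energies"] = NumericVector::create(a.e0, a.e1),
                      _["gradients"] = NumericVector::create(a.ga0, a.ga1),
                      _["d01"] = a.d01, _["eigvecs"] = U);
}

// ---------------------------------------------------------------------------
// electronic RK4 over substeps (shared by engine and R-level electronic_step)
// ---------------------------------------------------------------------------

struct ElecSched {
  double e0a, e1a, e0b, e1b; // energies at step start (a) and end (b)
  double vda, vdb;           // v * d01 at start and end
};

struct XiTerm {
  bool on;
  double lam0, lam1;         // (Q/M) . f_n, frozen across the step
};

static void elec_deriv(const cplx& C0, const cplx& C1, double tau,
                       const ElecSched& s, const XiTerm& xi,
                       cplx& d0, cplx& d1) {
  double e0 = s.e0a + tau * (s.e0b - s.e0a);
  double e1 = s.e1a + tau * (s.e1b - s.e1a);
  double vd = s.vda + tau * (s.vdb - s.vda);
  const cplx I(0.0, 1.0);
  d0 = -I * e0 * C0 - vd * C1;
  d1 = -I * e1 * C1 + vd * C0;
  if (xi.on) {
    double p0 = std::norm(C0), p1 = std::norm(C1), ps = p0 + p1;
    if (ps > 0) {
      double lbar = (p0 * xi.lam0 + p1 * xi.lam1) / ps;
      d0 += (xi.lam0 - lbar) * C0;
      d1 += (xi.lam1 - lbar) * C1;
    }
  }
}

static void elec_rk4(cplx& C0, cplx& C1, double dt, int nsub,
                     const ElecSched& s, const XiTerm& xi) {
  double h = dt / nsub;
  for (int j = 0; j < nsub; ++j) {
    double t0 = (double)j / nsub, tm = (j + 0.5) / nsub, t1 = (double)(j + 1) / nsub;
    cplx k10, k11, k20, k21, k30, k31, k40, k41, a0, a1;
    elec_deriv(C0, C1, t0, s, xi, k10, k11);
    a0 = C0 + 0.5 * h * k10; a1 = C1 + 0.5 * h * k11;
    elec_deriv(a0, a1, tm, s, xi, k20, k21);
    a0 = C0 + 0.5 * h * k20; a1 = C1 + 0.5 * h * k21;
    elec_deriv(a0, a1, tm, s, xi, k30, k31);
    a0 = C0 + h * k30; a1 = C1 + h * k31;
    elec_deriv(a0, a1, t1, s, xi, k40, k41);
    C0 += (h / 6.0) * (k10 + 2.0 * k20 + 2.0 * k30 + k40);
    C1 += (h / 6.0) * (k11 + 2.0 * k21 + 2.0 * k31 + k41);
  }
}

// [[Rcpp::export(name = ".electronic_step_cpp")]]
ComplexVector electronic_step_cpp(ComplexVector C, NumericVector eps_start,
                                  NumericVector eps_end, double vd_start,
                                  double vd_end, double dt, int nsub,
                                  double xi_lam0, double xi_lam1, bool xi_on) {
  cplx C0(C[0].r, C[0].i), C1(C[1].r, C[1].i);
  ElecSched s = { eps_start[0], eps_start[1], eps_end[0], eps_end[1], vd_start, vd_end };
  XiTerm xi = { xi_on, xi_lam0, xi_lam1 };
  elec_rk4(C0, C1, dt, nsub, s, xi);
  ComplexVector out(2);
  out[0].r = C0.real(); out[0].i = C0.imag();
  out[1].r = C1.real(); out[1].i = C1.imag();
  return out;
}

// ---------------------------------------------------------------------------
// single-trajectory propagator
// ---------------------------------------------------------------------------

// scheme: 0 none, 1 shxf, 2 edc, 3 afssh
// rescale: 0 iso, 1 nacv, 2 nacv+iso;  frustrated: 0 keep, 1 reverse
// hop-log branch codes: 0 iso, 1 nacv, 2 iso-after-frustrated-nacv,
//                       -1 frustrated(energy), -2 frustrated(zero nacv)

// [[Rcpp::export(name = ".propagate_cpp")]]
List propagate_cpp(int model_id, NumericVector params, double mass,
                   double x0, double v0, int active0, ComplexVector C0in,
                   double dt, int nsteps, int nsub, int record_every,
                   int scheme, double sigma, double spawn_thr, double alpha,
                   int rescale, int frustrated_policy,
                   double base_seed, double traj_id,
                   double exit_x, bool collect_full) {
  const double* p = params.begin();
  SplitMix64 rng(stream_seed(base_seed, traj_id));

  double x = x0, v = v0, t = 0.0;
  int a = active0; // 0-based
  cplx C[2] = { cplx(C0in[0].r, C0in[0].i), cplx(C0in[1].r, C0in[1].i) };
  Adiab ad = adiabatize2(model_id, p, x, NULL, true);

  // SHXF auxiliary state (single nonactive state in a 2-state system).
  // The auxiliary keeps its own direction of travel (aux_dir); only the
  // speed is refreshed from energy conservation on its surface, and it
  // reflects at its own classical turning points.
  bool aux_alive = false, aux_frozen = false, aux_respawned = false;
  double aux_x = 0.0, aux_v = 0.0, aux_E = 0.0, aux_dir = 1.0,
         f_acc[2] = { 0.0, 0.0 };
  double Q = 0.0;
  int n_frozen = 0;

  // A-FSSH moments for the nonactive state
  double dR = 0.0, dP = 0.0, dF_prev = 0.0;

  // diagnostics
  double max_norm_dev = 0.0, max_seg_drift = 0.0, max_hop_jump = 0.0;
  int n_draws = 0, n_frustrated = 0, n_accepted = 0, n_lowpop = 0, n_collapse = 0, n_reset = 0;

  double ea = (a == 0) ? ad.e0 : ad.e1;
  double E_seg = 0.5 * mass * v * v + ea;

  int nsnap = nsteps / record_every + 1;
  NumericVector rt(nsnap), rx(nsnap), rv(nsnap), rp0(nsnap), rp1(nsnap),
                re0(nsnap), re1(nsnap), rE(nsnap);
  IntegerVector ract(nsnap);
  NumericVector rc0r, rc0i, rc1r, rc1i, rQ, rzeta, rdbg1, rdbg2;
  if (collect_full) {
    rc0r = NumericVector(nsnap); rc0i = NumericVector(nsnap);
    rc1r = NumericVector(nsnap); rc1i = NumericVector(nsnap);
    rQ = NumericVector(nsnap); rzeta = NumericVector(nsnap);
    rdbg1 = NumericVector(nsnap); rdbg2 = NumericVector(nsnap);
  }
  double dbg1 = 0.0, dbg2 = 0.0; // scheme internals: shxf (aux_x, lam diff),
                                 // edc (tau, -), afssh (dR, collapse rate)
  std::vector<double> draws; // every uniform consumed, in order
  std::vector<int> hop_step, hop_from, hop_to, hop_acc, hop_branch;
  std::vector<double> hop_t, hop_r, hop_zeta;

  int isnap = 0;
  double last_zeta = 0.0;
  bool exited = false;

  for (int i = 0; i <= nsteps; ++i) {
    if (i % record_every == 0 && isnap < nsnap) {
      rt[isnap] = t; rx[isnap] = x; rv[isnap] = v; ract[isnap] = a + 1;
      rp0[isnap] = std::norm(C[0]); rp1[isnap] = std::norm(C[1]);
      re0[isnap] = ad.e0; re1[isnap] = ad.e1;
      double eac = (a == 0) ? ad.e0 : ad.e1;
      rE[isnap] = 0.5 * mass * v * v + eac;
      if (collect_full) {
        rc0r[isnap] = C[0].real(); rc0i[isnap] = C[0].imag();
        rc1r[isnap] = C[1].real(); rc1i[isnap] = C[1].imag();
        rQ[isnap] = Q; rzeta[isnap] = last_zeta;
        rdbg1[isnap] = dbg1; rdbg2[isnap] = dbg2;
      }
      ++isnap;
    }
    if (i == nsteps) break;

    if (exited) { // frozen free flight: extrapolate position only
      x += v * dt; t += dt;
      continue;
    }

    // --- 1. velocity Verlet on the active surface
    double ga_old = (a == 0) ? ad.ga0 : ad.ga1;
    double acc_old = -ga_old / mass;
    double x_new = x + v * dt + 0.5 * acc_old * dt * dt;
    Adiab ad_new = adiabatize2(model_id, p, x_new, &ad, true);
    double ga_new = (a == 0) ? ad_new.ga0 : ad_new.ga1;
    double v_new = v + 0.5 * (acc_old - ga_new / mass) * dt;
    double dv_verlet = v_new - v;

    // --- 2. electronic RK4 substeps (SHXF xi enters the RHS)
    ElecSched sched = { ad.e0, ad.e1, ad_new.e0, ad_new.e1,
                        v * ad.d01, v_new * ad_new.d01 };
    XiTerm xi = { scheme == 1 && aux_alive,
                  (Q / mass) * f_acc[0], (Q / mass) * f_acc[1] };
    elec_rk4(C[0], C[1], dt, nsub, sched, xi);
    {
      double dev = std::fabs(std::norm(C[0]) + std::norm(C[1]) - 1.0);
      if (dev > max_norm_dev) max_norm_dev = dev;
    }

    // --- 3. fewest-switches hop test (step-end quantities)
    int k = 1 - a;
    double rho_aa = std::norm(C[a]);
    double zeta;
    if (rho_aa > 1e-12) {
      double d_ak = (a == 0) ? ad_new.d01 : -ad_new.d01;
      double re = (std::conj(C[a]) * C[k]).real();
      zeta = 2.0 * dt * v_new * d_ak * re / rho_aa;
      if (zeta < 0) zeta = 0;
      if (zeta > 1) zeta = 1;
    } else {
      zeta = 0; ++n_lowpop;
    }
    last_zeta = zeta;
    double r_hop = rng.unif(); ++n_draws;
    if (collect_full) draws.push_back(r_hop);

    int old_a = a;
    if (r_hop <= zeta && zeta > 0) {
      double en = (k == 0) ? ad_new.e0 : ad_new.e1;
      double eaa = (a == 0) ? ad_new.e0 : ad_new.e1;
      double deps = en - eaa;
      double E_pre = 0.5 * mass * v_new * v_new + eaa;
      bool accepted = false;
      int branch = -1;
      double v_try = v_new;

      bool try_nacv = (rescale == 1 || rescale == 2);
      bool nacv_failed = false;
      if (try_nacv) {
        double d_an = (a == 0) ? ad_new.d01 : -ad_new.d01;
        if (std::fabs(d_an) < 1e-30) { nacv_failed = true; branch = -2; }
        else {
          double aq = d_an * d_an / (2.0 * mass);
          double bq = v_new * d_an;
          double disc = bq * bq - 4.0 * aq * deps;
          if (disc < 0) { nacv_failed = true; branch = -1; }
          else {
            double sq = std::sqrt(disc);
            double g1 = (-bq + sq) / (2.0 * aq), g2 = (-bq - sq) / (2.0 * aq);
            double gam = (std::fabs(g1) <= std::fabs(g2)) ? g1 : g2;
            v_try = v_new + gam * d_an / mass;
            accepted = true; branch = 1;
          }
        }
      }
      if ((rescale == 0) || (rescale == 2 && nacv_failed)) {
        double KE = 0.5 * mass * v_new * v_new;
        if (KE >= deps && (KE > 0 || deps >= 0)) {
          double kap = (KE > 0) ? std::sqrt(1.0 - deps / KE) : 1.0;
          v_try = kap * v_new;
          accepted = true;
          branch = (rescale == 2) ? 2 : 0;
        } else {
          accepted = false; branch = -1;
        }
      }

      if (accepted) {
        v_new = v_try;
        a = k;
        double E_post = 0.5 * mass * v_new * v_new + en;
        double jump = std::fabs(E_post - E_pre);
        if (jump > max_hop_jump) max_hop_jump = jump;
        E_seg = E_post;
        ++n_accepted;
        if (scheme == 3) { dR = dP = dF_prev = 0.0; }
        if (scheme == 1 && aux_alive) {
          // role swap: real trajectory takes over the new active state;
          // respawn the auxiliary for the previously active state here
          aux_x = x_new;
          double KEp = 0.5 * mass * v_new * v_new;
          double e_newa = (a == 0) ? ad_new.e0 : ad_new.e1;
          double e_olda = (old_a == 0) ? ad_new.e0 : ad_new.e1;
          double KE_aux = KEp + e_newa - e_olda;
          if (KE_aux >= 0) {
            aux_dir = (v_new >= 0) ? 1.0 : -1.0;
            aux_v = aux_dir * std::sqrt(2.0 * KE_aux / mass);
            aux_frozen = false;
          } else { aux_v = 0.0; aux_frozen = true; ++n_frozen; }
          aux_E = 0.5 * mass * aux_v * aux_v + e_olda;
          aux_respawned = true;
        }
      } else {
        ++n_frustrated;
        if (frustrated_policy == 1) v_new = -v_new;
      }
      hop_step.push_back(i + 1); hop_t.push_back(t + dt);
      hop_from.push_back(old_a + 1); hop_to.push_back(k + 1);
      hop_acc.push_back(accepted ? 1 : 0); hop_branch.push_back(branch);
      hop_r.push_back(r_hop); hop_zeta.push_back(zeta);
    }

    // --- 4. per-step decoherence application (EDC damping / A-FSSH),
    //        using the post-hop active state and velocity
    if (scheme == 2) { // energy-based decoherence
      double T = 0.5 * mass * v_new * v_new;
      int n = 1 - a;
      double en = (n == 0) ? ad_new.e0 : ad_new.e1;
      double eaa = (a == 0) ? ad_new.e0 : ad_new.e1;
      double gap = std::fabs(en - eaa);
      if (gap > 1e-12 && T > 0) {
        double tau = (1.0 / gap) * (1.0 + alpha / T);
        dbg1 = tau;
        C[n] *= std::exp(-dt / tau);
        double off = std::norm(C[n]);
        double target = 1.0 - off;
        if (target > 0) {
          double can = std::norm(C[a]);
          if (can > 1e-300) C[a] *= std::sqrt(target / can);
          else C[a] = cplx(std::sqrt(target), 0.0);
        }
      }
    } else if (scheme == 3) { // A-FSSH moments, collapse, reset
      int n = 1 - a;
      double gan = (n == 0) ? ad_new.ga0 : ad_new.ga1;
      double gaa = (a == 0) ? ad_new.ga0 : ad_new.ga1;
      double dF = -(gan - gaa); // force difference F_n - F_a
      dR += dP / mass * dt + 0.5 * dF_prev / mass * dt * dt;
      dP += 0.5 * (dF_prev + dF) * dt;
      dF_prev = dF;
      double en = (n == 0) ? ad_new.e0 : ad_new.e1;
      double eaa = (a == 0) ? ad_new.e0 : ad_new.e1;
      double rate_c = 0.5 * dF * dR - 2.0 * std::fabs((en - eaa) * ad_new.d01 * dR);
      double rate_r = -0.5 * dF * dR;
      dbg1 = dR; dbg2 = rate_c;
      bool collapsed = false;
      if (rate_c > 0) {
        double u = rng.unif(); ++n_draws;
        if (collect_full) draws.push_back(u);
        if (u < dt * rate_c) {
          C[n] = cplx(0.0, 0.0);
          double s2 = std::norm(C[a]);
          if (s2 > 1e-300) C[a] *= std::sqrt(1.0 / s2);
          else C[a] = cplx(1.0, 0.0);
          dR = dP = dF_prev = 0.0;
          collapsed = true; ++n_collapse;
        }
      }
      if (!collapsed && rate_r > 0) {
        double u = rng.unif(); ++n_draws;
        if (collect_full) draws.push_back(u);
        if (u < dt * rate_r) { dR = dP = dF_prev = 0.0; ++n_reset; }
      }
    }

    // --- 5. SHXF auxiliary-trajectory bookkeeping
    if (scheme == 1) {
      int n = 1 - a;
      double pn = std::norm(C[n]);
      // hysteresis: spawn where transfer is genuine, kill where population
      // is negligible (otherwise late-time coherence pins at the threshold)
      double kill_thr = std::min(1e-4, spawn_thr);
      double e_n_here = (n == 0) ? ad_new.e0 : ad_new.e1;
      double e_a_here = (a == 0) ? ad_new.e0 : ad_new.e1;
      if (!aux_alive) {
        if (pn > spawn_thr) { // spawn at the current position
          aux_alive = true; aux_x = x_new;
          f_acc[0] = f_acc[1] = 0.0;
          double KE_aux = 0.5 * mass * v_new * v_new + e_a_here - e_n_here;
          if (KE_aux >= 0) {
            aux_dir = (v_new >= 0) ? 1.0 : -1.0;
            aux_v = aux_dir * std::sqrt(2.0 * KE_aux / mass);
            aux_frozen = false;
          } else { aux_v = 0.0; aux_frozen = true; ++n_frozen; }
          aux_E = 0.5 * mass * aux_v * aux_v + e_n_here;
        }
      } else if (pn < kill_thr) { // population gone: kill the auxiliary
        aux_alive = false; aux_frozen = false;
        f_acc[0] = f_acc[1] = 0.0; Q = 0.0;
      } else if (aux_respawned) { // respawned at a hop this very step
        aux_respawned = false;
      } else { // advance the auxiliary on surface n by energy conservation
        double aux_v_old = aux_v;
        aux_x += aux_v * dt;
        double ea0, ea1;
        adiab_energies(model_id, p, aux_x, ea0, ea1);
        double e_n_aux = (n == 0) ? ea0 : ea1;
        double KE_aux = aux_E - e_n_aux;
        if (KE_aux >= 0) {
          aux_v = aux_dir * std::sqrt(2.0 * KE_aux / mass);
          if (aux_frozen) aux_frozen = false;
        } else if (!aux_frozen) {
          // classical turning point on the auxiliary surface: reflect
          aux_dir = -aux_dir;
          aux_v = 0.0;
        } else {
          aux_v = 0.0; // spawn-forbidden aux stays at rest
        }
        f_acc[n] += mass * (aux_v - aux_v_old);
        // active-state accumulated force from the real momentum change
        // (velocity-Verlet increment only; hop rescaling jumps excluded)
        f_acc[old_a] += mass * dv_verlet;
      }
      if (aux_alive) {
        double pa = std::norm(C[a]);
        double psum = pa + std::norm(C[n]);
        double wn = (psum > 0) ? std::norm(C[n]) / psum : 0.0;
        Q = wn * (x_new - aux_x) / (2.0 * sigma * sigma);
        dbg1 = aux_x;
        dbg2 = (Q / mass) * (f_acc[1 - a] - f_acc[a]);
      } else { Q = 0.0; dbg1 = 0.0; dbg2 = 0.0; }
    }

    // --- 6. advance clock, energy audit
    x = x_new; v = v_new; ad = ad_new; t += dt;
    double eac = (a == 0) ? ad.e0 : ad.e1;
    double E = 0.5 * mass * v * v + eac;
    double drift = std::fabs(E - E_seg);
    if (drift > max_seg_drift) max_seg_drift = drift;

    if (R_finite(exit_x) && std::fabs(x) > exit_x && x * v > 0) exited = true;
  }

  List rec = List::create(
    _["t"] = rt, _["x"] = rx, _["v"] = rv, _["active"] = ract,
    _["pop"] = cbind(rp0, rp1), _["energies"] = cbind(re0, re1),
    _["etot"] = rE);
  List hops = List::create(
    _["step"] = wrap(hop_step), _["t"] = wrap(hop_t),
    _["from"] = wrap(hop_from), _["to"] = wrap(hop_to),
    _["accepted"] = wrap(hop_acc), _["branch"] = wrap(hop_branch),
    _["r"] = wrap(hop_r), _["zeta"] = wrap(hop_zeta));
  List diag = List::create(
    _["max_norm_dev"] = max_norm_dev, _["max_seg_drift"] = max_seg_drift,
    _["max_hop_jump"] = max_hop_jump, _["n_draws"] = n_draws,
    _["n_accepted"] = n_accepted, _["n_frustrated"] = n_frustrated,
    _["n_frozen_aux"] = n_frozen, _["n_lowpop"] = n_lowpop,
    _["n_collapse"] = n_collapse, _["n_reset"] = n_reset,
    _["exited"] = exited);
  ComplexVector Cfin(2);
  Cfin[0].r = C[0].real(); Cfin[0].i = C[0].imag();
  Cfin[1].r = C[1].real(); Cfin[1].i = C[1].imag();
  List fin = List::create(_["t"] = t, _["x"] = x, _["v"] = v,
                          _["active"] = a + 1, _["C"] = Cfin);
  List out = List::create(_["record"] = rec, _["hops"] = hops,
                          _["diagnostics"] = diag, _["final"] = fin);
  if (collect_full) {
    out["C_record"] = List::create(_["re0"] = rc0r, _["im0"] = rc0i,
                                   _["re1"] = rc1r, _["im1"] = rc1i);
    out["Q_record"] = rQ;
    out["zeta_record"] = rzeta;
    out["debug1"] = rdbg1;
    out["debug2"] = rdbg2;
    out["draws"] = wrap(draws);
  }
  return out;
}
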