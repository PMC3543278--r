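// Core integrators for the two-scale cortical model:
//  - finite-N Euler-Maruyama simulation of units of globally coupled
//    excitatory/inhibitory theta neurons with exponential chemical PSCs and
//    diffusive (gap-junction) coupling among interneurons;
//  - deterministic Fokker-Planck mean-field of the same network, discretized
//    by a Fourier pseudo-spectral differentiation matrix in phase and advanced
//    by an adaptive Dormand-Prince 5(4) scheme in time.
// Both share the same input-assembly and modulation-schedule code so that the
// finite-N and infinite-N paths see identical couplings.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based noise: one logical stream per neuron, indexed by (seed,
// neuron, step).  Reproducibility is independent of evaluation order and of
// how a run is split into chunks.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double counter_normal(uint64_t seed, uint64_t neuron,
                                    uint64_t step) {
  uint64_t h = splitmix64(seed ^ splitmix64(neuron ^ splitmix64(step)));
  uint64_t h2 = splitmix64(h);
  // 53-bit uniforms in (0, 1]
  double u1 = ((h >> 11) + 1.0) * 1.1102230246251565e-16;
  double u2 = (h2 >> 11) * 1.1102230246251565e-16;
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
}

// ---------------------------------------------------------------------------
// Modulation schedule: a shared on/off-with-exponential-tail time course for
// the cholinergic factors and a rectangular window for the top-down Glu drive.

struct Schedule {
  double ach_level, ach_t0, ach_t1, ach_tau;
  double ge_level, ge_t0, ge_t1, ge_tau;
  double glu_inc, glu_t0, glu_t1;
  std::vector<int> glu_units; // 0-based
};

static inline double course(double t, double t0, double t1, double tau) {
  if (t < t0) return 0.0;
  if (t <= t1) return 1.0;
  if (tau <= 0.0) return 0.0;
  if (!std::isfinite(tau)) return 1.0;
  return std::exp(-(t - t1) / tau);
}

static Schedule as_schedule(const List& s) {
  Schedule sc;
  sc.ach_level = as<double>(s["ach_level"]);
  sc.ach_t0 = as<double>(s["ach_t0"]);
  sc.ach_t1 = as<double>(s["ach_t1"]);
  sc.ach_tau = as<double>(s["ach_tau"]);
  sc.ge_level = as<double>(s["ge_level"]);
  sc.ge_t0 = as<double>(s["ge_t0"]);
  sc.ge_t1 = as<double>(s["ge_t1"]);
  sc.ge_tau = as<double>(s["ge_tau"]);
  sc.glu_inc = as<double>(s["glu_inc"]);
  sc.glu_t0 = as<double>(s["glu_t0"]);
  sc.glu_t1 = as<double>(s["glu_t1"]);
  IntegerVector gu = s["glu_units"];
  sc.glu_units = std::vector<int>(gu.begin(), gu.end());
  return sc;
}

static inline double g_ach_at(const Schedule& s, double t) {
  return s.ach_level * course(t, s.ach_t0, s.ach_t1, s.ach_tau);
}
static inline double g_e_at(const Schedule& s, double t) {
  return s.ge_level * course(t, s.ge_t0, s.ge_t1, s.ge_tau);
}

static void glu_at(const Schedule& s, double t, arma::vec& glu) {
  glu.zeros();
  if (s.glu_inc != 0.0 && t >= s.glu_t0 && t < s.glu_t1)
    for (size_t i = 0; i < s.glu_units.size(); ++i)
      glu(s.glu_units[i]) += s.glu_inc;
}

// ---------------------------------------------------------------------------
// Unit parameters shared by both integrators.

struct Pars {
  double r_e, r_i, g_ee, g_ei, g_ie, g_ii, g_gap, kappa_e, kappa_i, D;
};

static Pars as_pars(const List& p) {
  Pars q;
  q.r_e = as<double>(p["r_e"]);
  q.r_i = as<double>(p["r_i"]);
  q.g_ee = as<double>(p["g_ee"]);
  q.g_ei = as<double>(p["g_ei"]);
  q.g_ie = as<double>(p["g_ie"]);
  q.g_ii = as<double>(p["g_ii"]);
  q.g_gap = as<double>(p["g_gap"]);
  q.kappa_e = as<double>(p["kappa_e"]);
  q.kappa_i = as<double>(p["kappa_i"]);
  q.D = as<double>(p["D"]);
  return q;
}

// Assemble per-unit inputs to the excitatory and inhibitory ensembles from
// the synaptic currents, with the cholinergic factors scaling every
// IN->PYR strength by (1 - g_ach) and every PYR->PYR strength by (1 - g_e).
static void assemble_inputs(const Pars& p, const arma::mat& wee,
                            const arma::mat& wie, const arma::mat& wei,
                            const arma::vec& IE, const arma::vec& II,
                            double gach, double ge, arma::vec& uE,
                            arma::vec& uI) {
  const double fE = 1.0 - ge, fI = 1.0 - gach;
  uE = fE * (p.g_ee * IE + wee * IE) - fI * (p.g_ie * II + wei * II);
  uI = p.g_ei * IE + wie * IE - p.g_ii * II;
}

// ---------------------------------------------------------------------------
// Finite-N stochastic simulation (Euler-Maruyama).
//
// theta_e: N_E x M, theta_i: N_I x M, phases in (-pi, pi]; syn: length 2M
// (E currents then I currents).  Returns spikes, final state and (optionally)
// a strided phase trace.  `step0` is the global step counter used to index
// the counter-based noise so that chunked runs continue the same streams.

// [[Rcpp::export]]
List cpp_simulate_network(arma::mat theta_e, arma::mat theta_i, arma::vec syn,
                          double t0, double n_steps_d, double dt, List params,
                          List weights, List schedule, double seed_d,
                          double step0_d, int record_stride) {
  const Pars p = as_pars(params);
  const Schedule sc = as_schedule(schedule);
  const arma::mat wee = as<arma::mat>(weights["wee"]);
  const arma::mat wie = as<arma::mat>(weights["wie"]);
  const arma::mat wei = as<arma::mat>(weights["wei"]);
  const int M = theta_e.n_cols;
  const int NE = theta_e.n_rows, NI = theta_i.n_rows;
  const uint64_t seed = (uint64_t)seed_d;
  const uint64_t step0 = (uint64_t)step0_d;
  const long n_steps = (long)n_steps_d;
  const double pi = 3.141592653589793;

  arma::vec IE = syn.subvec(0, M - 1), II = syn.subvec(M, 2 * M - 1);
  arma::vec uE(M), uI(M), glu(M);
  const double decE = std::exp(-dt / p.kappa_e);
  const double decI = std::exp(-dt / p.kappa_i);
  const double sq = std::sqrt(p.D * dt);

  std::vector<double> sp_t, sp_id, sp_unit;
  std::vector<int> sp_ens; // 0 = E, 1 = I
  std::vector<double> rec_t;
  std::vector<arma::mat> rec_e, rec_i;

  for (long s = 0; s < n_steps; ++s) {
    double t = t0 + s * dt;
    if (record_stride > 0 && (s % record_stride) == 0) {
      rec_t.push_back(t);
      rec_e.push_back(theta_e);
      rec_i.push_back(theta_i);
    }
    double gach = g_ach_at(sc, t), ge = g_e_at(sc, t);
    glu_at(sc, t, glu);
    assemble_inputs(p, wee, wie, wei, IE, II, gach, ge, uE, uI);

    arma::vec cntE(M, arma::fill::zeros), cntI(M, arma::fill::zeros);
    const uint64_t stp = step0 + (uint64_t)s;
    for (int k = 0; k < M; ++k) {
      const double drvE = p.r_e + glu(k) + uE(k);
      for (int i = 0; i < NE; ++i) {
        double th = theta_e(i, k);
        double opc = 1.0 + std::cos(th);
        double z = (p.D > 0.0)
                       ? counter_normal(seed, (uint64_t)(k * NE + i), stp)
                       : 0.0;
        double thn = th + dt * ((1.0 - std::cos(th)) + opc * drvE) +
                     opc * sq * z;
        if (!std::isfinite(thn))
          stop("non-finite phase (E neuron %d, unit %d, t = %g)", i + 1, k + 1,
               t);
        if (thn > pi) {
          double frac = (pi - th) / (thn - th);
          sp_t.push_back(t + frac * dt);
          sp_ens.push_back(0);
          sp_id.push_back(i + 1);
          sp_unit.push_back(k + 1);
          cntE(k) += 1.0;
          thn -= 2.0 * pi;
        } else if (thn <= -pi) {
          thn += 2.0 * pi;
        }
        theta_e(i, k) = thn;
      }
      const double drvI = p.r_i + uI(k);
      double S = 0.0, C = 0.0;
      if (p.g_gap != 0.0) {
        for (int i = 0; i < NI; ++i) {
          S += std::sin(theta_i(i, k));
          C += std::cos(theta_i(i, k));
        }
      }
      const uint64_t offI = (uint64_t)(M * NE);
      for (int i = 0; i < NI; ++i) {
        double th = theta_i(i, k);
        double opc = 1.0 + std::cos(th);
        double gap = (p.g_gap != 0.0)
                         ? p.g_gap / NI *
                               (S * std::cos(th) - C * std::sin(th))
                         : 0.0;
        double z = (p.D > 0.0)
                       ? counter_normal(seed, offI + (uint64_t)(k * NI + i),
                                        stp)
                       : 0.0;
        double thn = th + dt * ((1.0 - std::cos(th)) + opc * drvI + gap) +
                     opc * sq * z;
        if (!std::isfinite(thn))
          stop("non-finite phase (I neuron %d, unit %d, t = %g)", i + 1, k + 1,
               t);
        if (thn > pi) {
          double frac = (pi - th) / (thn - th);
          sp_t.push_back(t + frac * dt);
          sp_ens.push_back(1);
          sp_id.push_back(i + 1);
          sp_unit.push_back(k + 1);
          cntI(k) += 1.0;
          thn -= 2.0 * pi;
        } else if (thn <= -pi) {
          thn += 2.0 * pi;
        }
        theta_i(i, k) = thn;
      }
    }
    // exponential PSC bookkeeping: decay then jump (one state variable per
    // ensemble; exactly equivalent to summing per-spike exponential kernels)
    IE = IE * decE + cntE / (NE * p.kappa_e);
    II = II * decI + cntI / (NI * p.kappa_i);
  }

  arma::vec syn_out(2 * M);
  syn_out.subvec(0, M - 1) = IE;
  syn_out.subvec(M, 2 * M - 1) = II;

  List rec = R_NilValue;
  if (record_stride > 0) {
    int nr = rec_t.size();
    arma::cube ce(NE, M, nr), ci(NI, M, nr);
    for (int j = 0; j < nr; ++j) {
      ce.slice(j) = rec_e[j];
      ci.slice(j) = rec_i[j];
    }
    rec = List::create(_["times"] = NumericVector(rec_t.begin(), rec_t.end()),
                       _["theta_e"] = ce, _["theta_i"] = ci);
  }

  return List::create(
      _["spike_time"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["spike_ens"] = IntegerVector(sp_ens.begin(), sp_ens.end()),
      _["spike_id"] = NumericVector(sp_id.begin(), sp_id.end()),
      _["spike_unit"] = NumericVector(sp_unit.begin(), sp_unit.end()),
      _["theta_e"] = theta_e, _["theta_i"] = theta_i, _["syn"] = syn_out,
      _["t_end"] = t0 + n_steps * dt, _["step_end"] = (double)(step0 + n_steps),
      _["trace"] = rec);
}

// ---------------------------------------------------------------------------
// Fokker-Planck mean field.
//
// State: densities N (K x 2M; columns 1..M excitatory, M+1..2M inhibitory)
// on the uniform grid theta_j = -pi + j * 2*pi/K, plus 2M synaptic currents.
// The instantaneous population rate is the probability flux at the spike
// phase theta = pi; there B = 1 + cos(theta) vanishes, so the flux reduces to
// 2 * n(pi) (grid point 0 by periodicity).

struct FPsys {
  int K, M;
  arma::cx_vec ik;    // i * wavenumber, Nyquist zeroed (spectral derivative)
  arma::vec costh, sinth, om_cos, op_cos; // cos, sin, 1-cos, 1+cos
  double h;
  Pars p;
  arma::mat wee, wie, wei;
  Schedule sc;
  // preallocated workspaces (RHS is called 7x per step)
  mutable arma::cx_mat wF;
  mutable arma::mat wAN, wBN, wV, wD;
  mutable arma::vec wuE, wuI, wglu;
};

// spectral first derivative of each column via FFT (equivalent to the
// classical cot-formula differentiation matrix for even K), writing into a
// preallocated output
static void spec_deriv_into(const FPsys& S, const arma::mat& X,
                            arma::mat& out) {
  S.wF = arma::fft(X);
  S.wF.each_col() %= S.ik;
  out = arma::real(arma::ifft(S.wF));
}

static void fp_init_geometry(FPsys& S, int K) {
  S.K = K;
  S.h = 2.0 * 3.141592653589793 / K;
  arma::vec th(K);
  for (int j = 0; j < K; ++j) th(j) = -3.141592653589793 + j * S.h;
  S.costh = arma::cos(th);
  S.sinth = arma::sin(th);
  S.om_cos = 1.0 - S.costh;
  S.op_cos = 1.0 + S.costh;
  S.ik.set_size(K);
  for (int j = 0; j < K; ++j) {
    int k = (j <= K / 2) ? j : j - K;
    if (j == K / 2) k = 0; // zero the Nyquist mode in the odd derivative
    S.ik(j) = arma::cx_double(0.0, (double)k);
  }
}

static void fp_rhs(const FPsys& S, double t, const arma::mat& N,
                   const arma::vec& IE, const arma::vec& II, arma::mat& dN,
                   arma::vec& dIE, arma::vec& dII) {
  const int M = S.M;
  double gach = g_ach_at(S.sc, t), ge = g_e_at(S.sc, t);
  glu_at(S.sc, t, S.wglu);
  assemble_inputs(S.p, S.wee, S.wie, S.wei, IE, II, gach, ge, S.wuE, S.wuI);

  for (int k = 0; k < M; ++k) {
    S.wAN.col(k) =
        (S.om_cos + S.op_cos * (S.p.r_e + S.wglu(k) + S.wuE(k))) % N.col(k);
    if (S.p.g_gap != 0.0) {
      double sbar = S.h * arma::dot(S.sinth, N.col(M + k));
      double cbar = S.h * arma::dot(S.costh, N.col(M + k));
      S.wAN.col(M + k) = (S.om_cos + S.op_cos * (S.p.r_i + S.wuI(k)) +
                          S.p.g_gap * (sbar * S.costh - cbar * S.sinth)) %
                         N.col(M + k);
    } else {
      S.wAN.col(M + k) =
          (S.om_cos + S.op_cos * (S.p.r_i + S.wuI(k))) % N.col(M + k);
    }
  }
  S.wBN = N.each_col() % S.op_cos;
  spec_deriv_into(S, S.wBN, S.wV);
  S.wV.each_col() %= S.op_cos;
  spec_deriv_into(S, S.wV, S.wD);
  spec_deriv_into(S, S.wAN, dN);
  dN *= -1.0;
  dN += 0.5 * S.p.D * S.wD;

  for (int k = 0; k < M; ++k) {
    dIE(k) = (-IE(k) + 2.0 * N(0, k)) / S.p.kappa_e;
    dII(k) = (-II(k) + 2.0 * N(0, M + k)) / S.p.kappa_i;
  }
}

static void fp_alloc_workspaces(FPsys& S) {
  S.wF.set_size(S.K, 2 * S.M);
  S.wAN.set_size(S.K, 2 * S.M);
  S.wBN.set_size(S.K, 2 * S.M);
  S.wV.set_size(S.K, 2 * S.M);
  S.wD.set_size(S.K, 2 * S.M);
  S.wuE.set_size(S.M);
  S.wuI.set_size(S.M);
  S.wglu.set_size(S.M);
}

// ---------------------------------------------------------------------------
// Spectral-Galerkin evolution of the densities.
//
// The drift A(theta) = (1 - cos) + (1 + cos) d [+ gap terms] contains only
// the harmonics {1, cos, sin}, and the noise factor B = 1 + cos only {1,
// cos}; in Fourier space every term of the Fokker-Planck operator is
// therefore a banded (bandwidth <= 2) map on the mode coefficients.  Each
// density is evolved as its complex coefficients c_k, k = 0..L-1 (L = K/2,
// Hermitian symmetry implied); products are exact (no aliasing), and the
// k = 0 equation vanishes identically, so mass is conserved to rounding
// error.  Time stepping: adaptive Dormand-Prince 5(4).

struct FPGal {
  int L, M, K;
  arma::cx_vec ik;          // i * k, k = 0..L-1
  arma::vec sgn;            // flux weights at theta = pi: 1, 2(-1)^k
  Pars p;
  arma::mat wee, wie, wei;
  Schedule sc;
  // workspaces
  mutable arma::cx_mat DN, UP, Sh, Dh, AN, U1, V, DNV, UPV, W;
  mutable arma::cx_rowvec a0r, acr, asr;
  mutable arma::vec uE, uI, glu;
};

static void gal_alloc(FPGal& S) {
  const int L = S.L, C2 = 2 * S.M;
  S.ik.set_size(L);
  S.sgn.set_size(L);
  for (int k = 0; k < L; ++k) {
    S.ik(k) = arma::cx_double(0.0, (double)k);
    S.sgn(k) = (k == 0) ? 1.0 : ((k % 2) ? -2.0 : 2.0);
  }
  S.DN.set_size(L, C2); S.UP.set_size(L, C2); S.Sh.set_size(L, C2);
  S.Dh.set_size(L, C2);
  S.AN.set_size(L, C2); S.U1.set_size(L, C2); S.V.set_size(L, C2);
  S.DNV.set_size(L, C2); S.UPV.set_size(L, C2); S.W.set_size(L, C2);
  S.a0r.set_size(C2); S.acr.set_size(C2); S.asr.set_size(C2);
  S.uE.set_size(S.M); S.uI.set_size(S.M); S.glu.set_size(S.M);
}

// population rate (probability flux at theta = pi) per column
static inline arma::rowvec gal_flux(const FPGal& S, const arma::cx_mat& C) {
  return 2.0 * (S.sgn.t() * arma::real(C));
}

static inline void gal_shifts(const FPGal& S, const arma::cx_mat& C,
                              arma::cx_mat& DN, arma::cx_mat& UP) {
  const int L = S.L;
  DN.rows(1, L - 1) = C.rows(0, L - 2);
  DN.row(0) = arma::conj(C.row(1));
  UP.rows(0, L - 2) = C.rows(1, L - 1);
  UP.row(L - 1).zeros();
}

static void gal_rhs(const FPGal& S, double t, const arma::cx_mat& C,
                    const arma::vec& IE, const arma::vec& II, arma::cx_mat& dC,
                    arma::vec& dIE, arma::vec& dII) {
  const int M = S.M;
  double gach = g_ach_at(S.sc, t), ge = g_e_at(S.sc, t);
  glu_at(S.sc, t, S.glu);
  assemble_inputs(S.p, S.wee, S.wie, S.wei, IE, II, gach, ge, S.uE, S.uI);

  // per-column drift harmonics: A = a0 + ac cos + as sin
  for (int k = 0; k < M; ++k) {
    double dE = S.p.r_e + S.glu(k) + S.uE(k);
    S.a0r(k) = 1.0 + dE;
    S.acr(k) = dE - 1.0;
    S.asr(k) = 0.0;
    double dI = S.p.r_i + S.uI(k);
    double ac = dI - 1.0, as = 0.0;
    if (S.p.g_gap != 0.0) {
      // <cos> = 2*pi*Re c1, <sin> = -2*pi*Im c1 of the inhibitory density
      arma::cx_double c1 = C(1, M + k);
      double cbar = 2.0 * 3.141592653589793 * c1.real();
      double sbar = -2.0 * 3.141592653589793 * c1.imag();
      ac += S.p.g_gap * sbar;
      as += -S.p.g_gap * cbar;
    }
    S.a0r(M + k) = 1.0 + dI;
    S.acr(M + k) = ac;
    S.asr(M + k) = as;
  }

  gal_shifts(S, C, S.DN, S.UP);
  S.Sh = 0.5 * (S.DN + S.UP);
  // (A n)_k = a0 c_k + ac (c_{k-1}+c_{k+1})/2 - (i/2) as (c_{k-1}-c_{k+1})
  S.Dh = S.DN - S.UP;
  S.AN = C.each_row() % S.a0r + S.Sh.each_row() % S.acr +
         arma::cx_double(0.0, -0.5) * (S.Dh.each_row() % S.asr);
  // diffusion: (D/2) d/dth [ B d/dth (B n) ]
  S.U1 = C + S.Sh;
  S.V = S.U1.each_col() % S.ik;
  gal_shifts(S, S.V, S.DNV, S.UPV);
  S.W = S.V + 0.5 * (S.DNV + S.UPV);
  dC = -(S.AN.each_col() % S.ik) + (0.5 * S.p.D) * (S.W.each_col() % S.ik);

  arma::rowvec J = gal_flux(S, C);
  for (int k = 0; k < M; ++k) {
    dIE(k) = (-IE(k) + J(k)) / S.p.kappa_e;
    dII(k) = (-II(k) + J(M + k)) / S.p.kappa_i;
  }
}

// grid densities (K points, theta_0 = -pi) -> coefficients of e^{i k theta},
// c_0..c_{L-1}, and back.  The grid origin at -pi contributes a (-1)^k
// phase relative to the index-space DFT.
static arma::cx_mat gal_analyze(const arma::mat& N, int L) {
  arma::cx_mat F = arma::fft(N) / (double)N.n_rows;
  arma::cx_mat C = F.rows(0, L - 1);
  for (int k = 1; k < L; k += 2) C.row(k) *= -1.0;
  return C;
}

static arma::mat gal_synthesize(const arma::cx_mat& C, int K) {
  const int L = C.n_rows;
  arma::cx_mat F(K, C.n_cols, arma::fill::zeros);
  F.rows(0, L - 1) = C;
  for (int k = 1; k < L; k += 2) F.row(k) *= -1.0;
  for (int k = 1; k < L; ++k) F.row(K - k) = arma::conj(F.row(k));
  return arma::real(arma::ifft(F)) * (double)K;
}

// [[Rcpp::export]]
List cpp_integrate_fp(arma::mat N0, arma::vec I0, double t0, double t_end,
                      double stride, List params, List weights, List schedule,
                      double rtol, double atol, double dt_init,
                      double dt_max, int dens_every, double neg_abort,
                      double mass_abort) {
  FPGal S;
  S.M = N0.n_cols / 2;
  S.K = N0.n_rows;
  S.L = S.K / 2;
  gal_alloc(S);
  S.p = as_pars(params);
  S.wee = as<arma::mat>(weights["wee"]);
  S.wie = as<arma::mat>(weights["wie"]);
  S.wei = as<arma::mat>(weights["wei"]);
  S.sc = as_schedule(schedule);

  const int M = S.M, K = S.K, L = S.L;
  arma::cx_mat C = gal_analyze(N0, L);
  arma::vec IE = I0.subvec(0, M - 1), II = I0.subvec(M, 2 * M - 1);

  // Butcher tableau (Dormand-Prince)
  const double a21 = 1.0 / 5, a31 = 3.0 / 40, a32 = 9.0 / 40, a41 = 44.0 / 45,
               a42 = -56.0 / 15, a43 = 32.0 / 9, a51 = 19372.0 / 6561,
               a52 = -25360.0 / 2187, a53 = 64448.0 / 6561, a54 = -212.0 / 729,
               a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
               a64 = 49.0 / 176, a65 = -5103.0 / 18656, b1 = 35.0 / 384,
               b3 = 500.0 / 1113, b4 = 125.0 / 192, b5 = -2187.0 / 6784,
               b6 = 11.0 / 84, e1 = 35.0 / 384 - 5179.0 / 57600,
               e3 = 500.0 / 1113 - 7571.0 / 16695, e4 = 125.0 / 192 - 393.0 / 640,
               e5 = -2187.0 / 6784 + 92097.0 / 339200, e6 = 11.0 / 84 - 187.0 / 2100,
               e7 = -1.0 / 40;

  std::vector<double> out_t;
  std::vector<arma::vec> out_fE, out_fI, out_IE, out_II;
  std::vector<arma::mat> out_dens;
  std::vector<double> out_dens_t;

  double mass_drift = 0.0, min_dens = N0.min();

  auto record = [&](double t) {
    out_t.push_back(t);
    arma::rowvec J = gal_flux(S, C);
    arma::vec fE(M), fI(M);
    for (int k = 0; k < M; ++k) {
      fE(k) = J(k);
      fI(k) = J(M + k);
    }
    out_fE.push_back(fE);
    out_fI.push_back(fI);
    out_IE.push_back(IE);
    out_II.push_back(II);
    // diagnostics on the reconstructed densities
    arma::mat N = gal_synthesize(C, K);
    double md = N.min();
    if (md < min_dens) min_dens = md;
    if (md < -neg_abort)
      stop("density fell below -%g at t = %g (grid under-resolved?)",
           neg_abort, t);
    for (int c = 0; c < 2 * M; ++c) {
      double dmass = std::abs(2.0 * 3.141592653589793 * C(0, c).real() - 1.0);
      if (dmass > mass_drift) mass_drift = dmass;
      if (dmass > mass_abort)
        stop("density normalization drifted by %g (> %g) at t = %g", dmass,
             mass_abort, t);
    }
    if (dens_every > 0 && ((int)out_t.size() - 1) % dens_every == 0) {
      out_dens.push_back(N);
      out_dens_t.push_back(t);
    }
  };

  double t = t0;
  double dt = dt_init;
  long n_acc = 0, n_rej = 0;
  record(t);
  double t_next = std::min(t0 + stride, t_end);

  arma::cx_mat k1(L, 2 * M), k2(L, 2 * M), k3(L, 2 * M), k4(L, 2 * M),
      k5(L, 2 * M), k6(L, 2 * M), k7(L, 2 * M), Ctmp(L, 2 * M),
      C5(L, 2 * M), Cerr(L, 2 * M);
  arma::vec k1E(M), k2E(M), k3E(M), k4E(M), k5E(M), k6E(M), k7E(M),
      k1I(M), k2I(M), k3I(M), k4I(M), k5I(M), k6I(M), k7I(M), Etmp(M), Itmp(M),
      E5(M), I5(M), Eerr(M), Ierr(M);

  const double eps_t = 1e-12 * std::max(1.0, std::abs(t_end));
  while (t < t_end - eps_t) {
    if (dt > dt_max) dt = dt_max;
    bool hit = false;
    double dt_try = dt;
    if (t + dt_try >= t_next - eps_t) {
      dt_try = t_next - t;
      hit = true;
    }

    gal_rhs(S, t, C, IE, II, k1, k1E, k1I);
    Ctmp = C + dt_try * a21 * k1;
    Etmp = IE + dt_try * a21 * k1E;
    Itmp = II + dt_try * a21 * k1I;
    gal_rhs(S, t + dt_try / 5.0, Ctmp, Etmp, Itmp, k2, k2E, k2I);
    Ctmp = C + dt_try * (a31 * k1 + a32 * k2);
    Etmp = IE + dt_try * (a31 * k1E + a32 * k2E);
    Itmp = II + dt_try * (a31 * k1I + a32 * k2I);
    gal_rhs(S, t + 0.3 * dt_try, Ctmp, Etmp, Itmp, k3, k3E, k3I);
    Ctmp = C + dt_try * (a41 * k1 + a42 * k2 + a43 * k3);
    Etmp = IE + dt_try * (a41 * k1E + a42 * k2E + a43 * k3E);
    Itmp = II + dt_try * (a41 * k1I + a42 * k2I + a43 * k3I);
    gal_rhs(S, t + 0.8 * dt_try, Ctmp, Etmp, Itmp, k4, k4E, k4I);
    Ctmp = C + dt_try * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4);
    Etmp = IE + dt_try * (a51 * k1E + a52 * k2E + a53 * k3E + a54 * k4E);
    Itmp = II + dt_try * (a51 * k1I + a52 * k2I + a53 * k3I + a54 * k4I);
    gal_rhs(S, t + 8.0 / 9.0 * dt_try, Ctmp, Etmp, Itmp, k5, k5E, k5I);
    Ctmp = C + dt_try * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5);
    Etmp = IE + dt_try * (a61 * k1E + a62 * k2E + a63 * k3E + a64 * k4E +
                          a65 * k5E);
    Itmp = II + dt_try * (a61 * k1I + a62 * k2I + a63 * k3I + a64 * k4I +
                          a65 * k5I);
    gal_rhs(S, t + dt_try, Ctmp, Etmp, Itmp, k6, k6E, k6I);
    C5 = C + dt_try * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    E5 = IE + dt_try * (b1 * k1E + b3 * k3E + b4 * k4E + b5 * k5E + b6 * k6E);
    I5 = II + dt_try * (b1 * k1I + b3 * k3I + b4 * k4I + b5 * k5I + b6 * k6I);
    gal_rhs(S, t + dt_try, C5, E5, I5, k7, k7E, k7I);
    Cerr = dt_try * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);
    Eerr = dt_try * (e1 * k1E + e3 * k3E + e4 * k4E + e5 * k5E + e6 * k6E +
                     e7 * k7E);
    Ierr = dt_try * (e1 * k1I + e3 * k3I + e4 * k4I + e5 * k5I + e6 * k6I +
                     e7 * k7I);

    double sc_err = 0.0;
    {
      // scale relative to a density-amplitude floor: coefficient magnitudes
      // are bounded by the density scale 1/(2 pi)
      double m1 = (arma::abs(Cerr) /
                   (atol + rtol * (arma::abs(C5) + 0.05))).max();
      double m2 = arma::abs(Eerr / (atol + rtol * (arma::abs(E5) + 0.05))).max();
      double m3 = arma::abs(Ierr / (atol + rtol * (arma::abs(I5) + 0.05))).max();
      sc_err = std::max(m1, std::max(m2, m3));
    }
    if (!std::isfinite(sc_err))
      stop("non-finite state during integration at t = %g", t);

    if (sc_err <= 1.0) {
      t += dt_try;
      C = C5;
      IE = E5;
      II = I5;
      ++n_acc;
      if (hit) {
        record(t);
        t_next += stride;
        if (t_next > t_end + eps_t) t_next = t_end;
      }
      double fac = 0.9 * std::pow(std::max(sc_err, 1e-10), -0.2);
      dt = dt_try * std::min(5.0, std::max(0.2, fac));
    } else {
      ++n_rej;
      double fac = 0.9 * std::pow(sc_err, -0.2);
      dt = dt_try * std::max(0.1, fac);
      if (dt < 1e-10)
        stop("step size underflow at t = %g (stiffness/CFL violation)", t);
    }
  }

  int T = out_t.size();
  arma::mat fE(T, M), fI(T, M), oIE(T, M), oII(T, M);
  for (int i = 0; i < T; ++i) {
    fE.row(i) = out_fE[i].t();
    fI.row(i) = out_fI[i].t();
    oIE.row(i) = out_IE[i].t();
    oII.row(i) = out_II[i].t();
  }
  List dens = R_NilValue;
  if (dens_every > 0) {
    int nd = out_dens.size();
    arma::cube cd(K, 2 * M, nd);
    for (int i = 0; i < nd; ++i) cd.slice(i) = out_dens[i];
    dens = List::create(
        _["times"] = NumericVector(out_dens_t.begin(), out_dens_t.end()),
        _["densities"] = cd);
  }
  arma::vec I_final(2 * M);
  I_final.subvec(0, M - 1) = IE;
  I_final.subvec(M, 2 * M - 1) = II;
  return List::create(
      _["times"] = NumericVector(out_t.begin(), out_t.end()),
      _["flux_e"] = fE, _["flux_i"] = fI, _["syn_e"] = oIE, _["syn_i"] = oII,
      _["N_final"] = gal_synthesize(C, K), _["I_final"] = I_final,
      _["t_final"] = t,
      _["mass_drift"] = mass_drift, _["min_density"] = min_dens,
      _["n_accepted"] = (double)n_acc, _["n_rejected"] = (double)n_rej,
      _["dens"] = dens);
}

// Pointwise probability flux J(theta) = A n - (D/2) B d(B n)/dtheta for one
// unit, using the same discretization as the integrator.

// [[Rcpp::export]]
arma::mat cpp_fp_flux_profile(arma::mat N, arma::vec Icur, double t,
                              List params, List weights, List schedule) {
  FPsys S;
  S.M = N.n_cols / 2;
  fp_init_geometry(S, N.n_rows);
  fp_alloc_workspaces(S);
  S.p = as_pars(params);
  S.wee = as<arma::mat>(weights["wee"]);
  S.wie = as<arma::mat>(weights["wie"]);
  S.wei = as<arma::mat>(weights["wei"]);
  S.sc = as_schedule(schedule);
  const int M = S.M;
  arma::vec IE = Icur.subvec(0, M - 1), II = Icur.subvec(M, 2 * M - 1);
  arma::vec uE(M), uI(M), glu(M);
  double gach = g_ach_at(S.sc, t), ge = g_e_at(S.sc, t);
  glu_at(S.sc, t, glu);
  assemble_inputs(S.p, S.wee, S.wie, S.wei, IE, II, gach, ge, uE, uI);
  arma::mat J(S.K, 2 * M);
  arma::mat dBN(S.K, 2 * M);
  spec_deriv_into(S, N.each_col() % S.op_cos, dBN);
  for (int k = 0; k < M; ++k) {
    arma::vec Ae = S.om_cos + S.op_cos * (S.p.r_e + glu(k) + uE(k));
    J.col(k) = Ae % N.col(k) - 0.5 * S.p.D * (S.op_cos % dBN.col(k));
    arma::vec Ai = S.om_cos + S.op_cos * (S.p.r_i + uI(k));
    if (S.p.g_gap != 0.0) {
      double sbar = S.h * arma::dot(S.sinth, N.col(M + k));
      double cbar = S.h * arma::dot(S.costh, N.col(M + k));
      Ai += S.p.g_gap * (sbar * S.costh - cbar * S.sinth);
    }
    J.col(M + k) = Ai % N.col(M + k) - 0.5 * S.p.D * (S.op_cos % dBN.col(M + k));
  }
  return J;
}
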