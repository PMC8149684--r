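// Fixed-step RK4 integration of the left-heart + systemic + pulmonary
// lumped-parameter circuit.  The right-hand side here mirrors, term by
// term, the R implementation in assemble_rhs(); the R/deSolve route is the
// cross-check, this is the production path.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// parameter vector layout (must match .model_par_vector in R)
enum {
  iR_ao, iC_ao, iR_SV, iC_SAC, iR_SA, iR_ub, iR_pda,
  iL_PV, iR_PV, iR_PVC, iC_PVC, iL_PC, iR_PC, iR_PA, iC_PA,
  iQ_MPV, iP_CV0,
  iT, it_ee, iV0_LV, iV0_LA, ila_shift,
  // elastance LV: Emin, N, m1, m2, tau1, tau2 (absolute s)
  iLV_Emin, iLV_N, iLV_m1, iLV_m2, iLV_t1, iLV_t2,
  iLA_Emin, iLA_N, iLA_m1, iLA_m2, iLA_t1, iLA_t2,
  // valves: inertance (L) and bernoulli (B) coefficients, mmHg units
  iL_AV, iB_AV, ihas_AR, iL_AR, iB_AR,
  iL_MV, iB_MV, ihas_MR, iL_MR, iB_MR,
  NPAR
};

static const int NS = 12;  // state dimension
// state: 0 V_LV, 1 V_LA, 2 P_Cao, 3 P_CSAC, 4 P_CPA, 5 P_CPVC,
//        6 Q_AV, 7 Q_AR, 8 Q_MV, 9 Q_MR, 10 Q_PV, 11 Q_PC

static const double TAU_CLOSE = 1e-3;  // s, closed-valve flow bleed-off

// positive modulo without libm fmod (keeps the binary portable across
// glibc symbol versions)
static inline double mod_pos(double a, double m) {
  double r = a - std::floor(a / m) * m;
  if (r >= m) r -= m;
  if (r < 0.0) r += m;
  return r;
}

static inline double hill(double t, double Emin, double N, double m1,
                          double m2, double t1, double t2) {
  if (t <= 0.0) return Emin;
  double a = std::pow(t / t1, m1);
  return N * (a / (1.0 + a)) / (1.0 + std::pow(t / t2, m2)) + Emin;
}

static inline double valve_dq(double Q, double dp, double L, double B) {
  if (Q > 0.0 || dp > 0.0) return (dp - B * Q * std::fabs(Q)) / L;
  return -Q / TAU_CLOSE;
}

struct Aux {
  double P_LV, P_LA, P_b, Q_src, Q_ub, Q_sa, Q_out;
};

static void rhs(double t, const double* x, const double* p, double* dx,
                Aux* aux) {
  const double T = p[iT];
  const double tt = mod_pos(t, T);

  const double E_LV = hill(tt, p[iLV_Emin], p[iLV_N], p[iLV_m1], p[iLV_m2],
                           p[iLV_t1], p[iLV_t2]);
  const double tla = mod_pos(tt - p[ila_shift], T);
  const double E_LA = hill(tla, p[iLA_Emin], p[iLA_N], p[iLA_m1], p[iLA_m2],
                           p[iLA_t1], p[iLA_t2]);

  const double P_LV = E_LV * (x[0] - p[iV0_LV]);
  const double P_LA = E_LA * (x[1] - p[iV0_LA]);

  const double Q_src = (tt <= p[it_ee])
      ? p[iQ_MPV] * std::sin(M_PI * tt / p[it_ee]) : 0.0;

  // viscoelastic capacitor nodes (series R with C)
  const double P_pa  = x[4] + p[iR_PA]  * (Q_src - x[11]);
  const double P_pvc = x[5] + p[iR_PVC] * (x[11] - x[10]);

  // systemic bifurcation node (algebraic); the arterial compliance node
  // sits between R_pda and R_SA (windkessel: compliance proximal to the
  // arteriolar resistance)
  const double Rds = p[iR_SA] + p[iR_SV];
  const double P_b = (x[2] / p[iR_ao] + p[iP_CV0] / p[iR_ub] + x[3] / p[iR_pda]) /
                     (1.0 / p[iR_ao] + 1.0 / p[iR_ub] + 1.0 / p[iR_pda]);
  const double Q_out = (x[2] - P_b) / p[iR_ao];
  const double Q_ub  = (P_b - p[iP_CV0]) / p[iR_ub];
  const double Q_sa  = (P_b - x[3]) / p[iR_pda];   // into the C_SAC node
  const double Q_sv  = (x[3] - p[iP_CV0]) / Rds;   // out through R_SA+R_SV

  const double Q_AV = x[6], Q_AR = x[7], Q_MV = x[8], Q_MR = x[9];

  dx[0] = Q_MV - Q_MR - Q_AV + Q_AR;          // V_LV
  dx[1] = x[10] - Q_MV + Q_MR;                // V_LA
  dx[2] = (Q_AV - Q_AR - Q_out) / p[iC_ao];   // P_Cao
  dx[3] = (Q_sa - Q_sv) / p[iC_SAC];          // P_CSAC
  dx[4] = (Q_src - x[11]) / p[iC_PA];         // P_CPA
  dx[5] = (x[11] - x[10]) / p[iC_PVC];        // P_CPVC
  dx[6] = valve_dq(Q_AV, P_LV - x[2], p[iL_AV], p[iB_AV]);
  dx[7] = (p[ihas_AR] > 0.5)
      ? valve_dq(Q_AR, x[2] - P_LV, p[iL_AR], p[iB_AR]) : 0.0;
  dx[8] = valve_dq(Q_MV, P_LA - P_LV, p[iL_MV], p[iB_MV]);
  dx[9] = (p[ihas_MR] > 0.5)
      ? valve_dq(Q_MR, P_LV - P_LA, p[iL_MR], p[iB_MR]) : 0.0;
  dx[10] = (P_pvc - p[iR_PV] * x[10] - P_LA) / p[iL_PV];  // Q_PV
  dx[11] = (P_pa - p[iR_PC] * x[11] - P_pvc) / p[iL_PC];  // Q_PC

  if (aux) {
    aux->P_LV = P_LV; aux->P_LA = P_LA; aux->P_b = P_b;
    aux->Q_src = Q_src; aux->Q_ub = Q_ub; aux->Q_sa = Q_sa;
    aux->Q_out = Q_out;
  }
}

static inline void rk4_step(double t, double dt, double* x, const double* p) {
  double k1[NS], k2[NS], k3[NS], k4[NS], xt[NS];
  rhs(t, x, p, k1, nullptr);
  for (int i = 0; i < NS; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
  rhs(t + 0.5 * dt, xt, p, k2, nullptr);
  for (int i = 0; i < NS; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
  rhs(t + 0.5 * dt, xt, p, k3, nullptr);
  for (int i = 0; i < NS; ++i) xt[i] = x[i] + dt * k3[i];
  rhs(t + dt, xt, p, k4, nullptr);
  for (int i = 0; i < NS; ++i)
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export(name = ".lpm_rhs_cpp")]]
NumericVector lpm_rhs_cpp(NumericVector par, NumericVector state, double t) {
  if (par.size() != NPAR) stop("parameter vector has wrong length");
  if (state.size() != NS) stop("state vector has wrong length");
  NumericVector dx(NS);
  rhs(t, REAL(state), REAL(par), REAL(dx), nullptr);
  return dx;
}

// [[Rcpp::export(name = ".lpm_integrate_cpp")]]
List lpm_integrate_cpp(NumericVector par, NumericVector state0, double dt,
                       double steady_tol, int max_cycles, int n_out) {
  if (par.size() != NPAR) stop("parameter vector has wrong length");
  const double* p = REAL(par);
  const double T = p[iT];

  int n_steps = (int)std::lround(T / dt / n_out) * n_out;
  if (n_steps < n_out) n_steps = n_out;
  const double h = T / n_steps;
  const int stride = n_steps / n_out;

  double x[NS];
  for (int i = 0; i < NS; ++i) x[i] = state0[i];

  // cycle until periodic
  double prev[NS], rel = R_PosInf;
  int cyc = 0;
  bool converged = false;
  for (cyc = 0; cyc < max_cycles; ++cyc) {
    for (int i = 0; i < NS; ++i) prev[i] = x[i];
    for (int s = 0; s < n_steps; ++s) rk4_step(s * h, h, x, p);
    rel = 0.0;
    for (int i = 0; i < NS; ++i) {
      double sc = std::fmax(std::fabs(x[i]), 1.0);
      rel = std::fmax(rel, std::fabs(x[i] - prev[i]) / sc);
    }
    if (!std::isfinite(rel)) stop("non-finite state during integration");
    if (rel < steady_tol) { converged = true; ++cyc; break; }
  }

  // one recording cycle
  NumericVector tout(n_out + 1);
  NumericMatrix Y(n_out + 1, 13);
  colnames(Y) = CharacterVector::create(
      "P_LV", "P_LA", "P_ao", "P_sa", "V_LV", "V_LA",
      "Q_AV", "Q_AR", "Q_MV", "Q_MR", "Q_PV", "Q_ub", "Q_sa");
  double vol_av = 0, vol_ar = 0, vol_mv = 0, vol_mr = 0,
         vol_src = 0, vol_ub = 0, vol_out = 0;
  double edv = x[0], esv = x[0], min_vmv0 = R_PosInf;
  double state_start[NS];
  for (int i = 0; i < NS; ++i) state_start[i] = x[i];

  Aux aux;
  double dxdum[NS];
  int row = 0;
  for (int s = 0; s <= n_steps; ++s) {
    double t = s * h;
    rhs(t, x, p, dxdum, &aux);
    if (s % stride == 0) {
      tout[row] = t;
      Y(row, 0) = aux.P_LV; Y(row, 1) = aux.P_LA;
      Y(row, 2) = x[2]; Y(row, 3) = x[3];
      Y(row, 4) = x[0]; Y(row, 5) = x[1];
      Y(row, 6) = std::fmax(x[6], 0.0); Y(row, 7) = std::fmax(x[7], 0.0);
      Y(row, 8) = std::fmax(x[8], 0.0); Y(row, 9) = std::fmax(x[9], 0.0);
      Y(row, 10) = x[10]; Y(row, 11) = aux.Q_ub; Y(row, 12) = aux.Q_sa;
      ++row;
    }
    edv = std::fmax(edv, x[0]); esv = std::fmin(esv, x[0]);
    min_vmv0 = std::fmin(min_vmv0, std::fmin(x[0] - p[iV0_LV],
                                             x[1] - p[iV0_LA]));
    if (s < n_steps) {
      // trapezoid accumulation across the step (gated flows clamped at 0)
      double q0[7] = {std::fmax(x[6], 0.0), std::fmax(x[7], 0.0),
                      std::fmax(x[8], 0.0), std::fmax(x[9], 0.0),
                      aux.Q_src, aux.Q_ub, aux.Q_out};
      rk4_step(t, h, x, p);
      rhs(t + h, x, p, dxdum, &aux);
      double q1[7] = {std::fmax(x[6], 0.0), std::fmax(x[7], 0.0),
                      std::fmax(x[8], 0.0), std::fmax(x[9], 0.0),
                      aux.Q_src, aux.Q_ub, aux.Q_out};
      vol_av  += 0.5 * h * (q0[0] + q1[0]);
      vol_ar  += 0.5 * h * (q0[1] + q1[1]);
      vol_mv  += 0.5 * h * (q0[2] + q1[2]);
      vol_mr  += 0.5 * h * (q0[3] + q1[3]);
      vol_src += 0.5 * h * (q0[4] + q1[4]);
      vol_ub  += 0.5 * h * (q0[5] + q1[5]);
      vol_out += 0.5 * h * (q0[6] + q1[6]);
    }
  }

  NumericVector sstart(NS), send(NS);
  for (int i = 0; i < NS; ++i) { sstart[i] = state_start[i]; send[i] = x[i]; }

  return List::create(
      _["t"] = tout, _["Y"] = Y,
      _["converged"] = converged, _["n_cycles"] = cyc,
      _["rel_change"] = rel,
      _["volumes"] = NumericVector::create(
          _["AV"] = vol_av, _["AR"] = vol_ar, _["MV"] = vol_mv,
          _["MR"] = vol_mr, _["source"] = vol_src, _["upper_body"] = vol_ub,
          _["systemic_out"] = vol_out),
      _["EDV"] = edv, _["ESV"] = esv,
      _["min_V_minus_V0"] = min_vmv0,
      _["state_start"] = sstart, _["state_end"] = send);
}
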