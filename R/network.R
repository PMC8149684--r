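#' Rectified-sine pulmonary inflow source
#'
#' The right heart is abstracted as a prescribed pulmonary-valve flow:
#' `Q(t) = Q_MPV * sin(pi t / t_ee)` for `t <= t_ee` and `0` for
#' `t_ee < t <= T`, with `t` taken modulo `T`.  One cycle delivers
#' `2 Q_MPV t_ee / pi` millilitres.
#'
#' @param t time, s (vectorized; taken mod `T`).
#' @param Q_MPV source amplitude (mean pulmonary-valve flow parameter), mL/s.
#' @param t_ee end-ejection time, s.
#' @param T cardiac period, s.
#' @return Flow in mL/s.
#' @export
pulmonary_source <- function(t, Q_MPV, t_ee, T) {
  if (t_ee <= 0 || t_ee > T) abort_domain("need 0 < t_ee <= T")
  tt <- t %% T
  ifelse(tt <= t_ee, Q_MPV * sin(pi * tt / t_ee), 0)
}

# State layout shared by the R and C++ right-hand sides.
STATE_NAMES <- c("V_LV", "V_LA", "P_Cao", "P_CSAC", "P_CPA", "P_CPVC",
                 "Q_AV", "Q_AR", "Q_MV", "Q_MR", "Q_PV", "Q_PC")

#' Assemble the patient-specific circuit model
#'
#' Combines circuit parameters, the patient's valve branches and the
#' patient's timing into one model object used by [assemble_rhs()] and
#' [simulate_to_steady()].  The network topology (each element used once,
#' in its anatomical position) is:
#'
#' ```
#' Q_source(t) -> [R_PA // C_PA] -> R_PC+L_PC -> [R_PVC // C_PVC]
#'   -> R_PV+L_PV -> LA -> mitral branches -> LV -> aortic branches
#'   -> C_ao -> R_ao -> { R_ub -> venous ; R_pda -> C_SAC -> R_SA
#'   -> R_SV -> venous },   venous node clamped at P_CV0
#' ```
#'
#' `[R // C]` denotes a compliance with its series (viscoelastic)
#' resistance.  Use [netlist()] for an audit dump.
#'
#' @param params a [circulation_params()] set.
#' @param valves output of [build_patient_valves()].
#' @param rec the [patient_record()] (supplies `T` and `t_ee = T_EJ`).
#' @return An `lpm_model` object.
#' @export
lpm_model <- function(params, valves, rec) {
  stopifnot(inherits(params, "circulation_params"),
            inherits(rec, "patient_record"),
            inherits(valves$AV, "valve_branch"),
            inherits(valves$MV, "valve_branch"))
  structure(list(params = params, valves = valves,
                 T = rec$T, t_ee = rec$T_EJ, rec = rec),
            class = "lpm_model")
}

# flat numeric parameter vector in the order the C++ integrator expects
.model_par_vector <- function(model) {
  p <- model$params
  el <- function(e, T) {
    c(e$E_min, (e$E_max - e$E_min) / 2, e$m1, e$m2,
      e$tau1_frac * T, e$tau2_frac * T)
  }
  v <- model$valves
  c(p$R_ao, p$C_ao, p$R_SV, p$C_SAC, p$R_SA, p$R_ub, p$R_pda,
    p$L_PV, p$R_PV, p$R_PVC, p$C_PVC, p$L_PC, p$R_PC, p$R_PA, p$C_PA,
    p$Q_MPV, p$P_CV0,
    model$T, model$t_ee, p$V0_LV, p$V0_LA, p$la_phase_frac * model$T,
    el(p$elastance_LV, model$T), el(p$elastance_LA, model$T),
    v$AV$inertance_coeff, v$AV$bernoulli_coeff,
    as.numeric(!is.null(v$AR)),
    if (is.null(v$AR)) c(1, 0) else c(v$AR$inertance_coeff, v$AR$bernoulli_coeff),
    v$MV$inertance_coeff, v$MV$bernoulli_coeff,
    as.numeric(!is.null(v$MR)),
    if (is.null(v$MR)) c(1, 0) else c(v$MR$inertance_coeff, v$MR$bernoulli_coeff))
}

TAU_VALVE_CLOSE <- 1e-3  # s; closed-branch flow bleed-off time constant

.valve_dq <- function(Q, dp, L, B) {
  if (Q > 0 || dp > 0) (dp - B * Q * abs(Q)) / L else -Q / TAU_VALVE_CLOSE
}

#' Circuit right-hand side (R reference implementation)
#'
#' Time derivative of the 12-dimensional circuit state; deSolve-compatible
#' signature, usable directly with [deSolve::ode()].  Chamber volumes
#' change with net in/outflow, capacitor pressures with net current over
#' compliance, and inductor flows follow the branch pressure balances with
#' the valve branches diode-gated (a closed branch relaxes its flow to zero
#' with a 1 ms time constant, keeping the right-hand side Lipschitz).  The
#' production integrator re-implements exactly this function in C++; the
#' two are cross-checked in the test suite.
#'
#' @param t time, s.
#' @param state named numeric state vector (see `cardiolpm:::STATE_NAMES`).
#' @param model an [lpm_model()].
#' @return `list(derivatives, auxiliaries)` in deSolve convention.
#' @export
assemble_rhs <- function(t, state, model) {
  p <- model$params
  T <- model$T
  x <- unname(state)

  tt <- t %% T
  E_LV <- elastance_value(tt, p$elastance_LV, T)
  tla <- (tt - p$la_phase_frac * T) %% T
  E_LA <- elastance_value(tla, p$elastance_LA, T)
  P_LV <- E_LV * (x[1] - p$V0_LV)
  P_LA <- E_LA * (x[2] - p$V0_LA)

  Q_src <- pulmonary_source(tt, p$Q_MPV, model$t_ee, T)

  P_pa <- x[5] + p$R_PA * (Q_src - x[12])
  P_pvc <- x[6] + p$R_PVC * (x[12] - x[11])

  Rds <- p$R_SA + p$R_SV
  P_b <- (x[3] / p$R_ao + p$P_CV0 / p$R_ub + x[4] / p$R_pda) /
    (1 / p$R_ao + 1 / p$R_ub + 1 / p$R_pda)
  Q_out <- (x[3] - P_b) / p$R_ao
  Q_ub <- (P_b - p$P_CV0) / p$R_ub
  Q_sa <- (P_b - x[4]) / p$R_pda
  Q_sv <- (x[4] - p$P_CV0) / Rds

  v <- model$valves
  dQ_AV <- .valve_dq(x[7], P_LV - x[3], v$AV$inertance_coeff, v$AV$bernoulli_coeff)
  dQ_AR <- if (is.null(v$AR)) 0 else
    .valve_dq(x[8], x[3] - P_LV, v$AR$inertance_coeff, v$AR$bernoulli_coeff)
  dQ_MV <- .valve_dq(x[9], P_LA - P_LV, v$MV$inertance_coeff, v$MV$bernoulli_coeff)
  dQ_MR <- if (is.null(v$MR)) 0 else
    .valve_dq(x[10], P_LV - P_LA, v$MR$inertance_coeff, v$MR$bernoulli_coeff)

  d <- c(
    x[9] - x[10] - x[7] + x[8],          # V_LV
    x[11] - x[9] + x[10],                # V_LA
    (x[7] - x[8] - Q_out) / p$C_ao,      # P_Cao
    (Q_sa - Q_sv) / p$C_SAC,             # P_CSAC
    (Q_src - x[12]) / p$C_PA,            # P_CPA
    (x[12] - x[11]) / p$C_PVC,           # P_CPVC
    dQ_AV, dQ_AR, dQ_MV, dQ_MR,
    (P_pvc - p$R_PV * x[11] - P_LA) / p$L_PV,   # Q_PV
    (P_pa - p$R_PC * x[12] - P_pvc) / p$L_PC    # Q_PC
  )
  if (any(!is.finite(d)))
    abort_domain(paste0("non-finite derivative at t=", signif(t, 6),
                        "; state: ", paste(signif(x, 4), collapse = " ")))
  list(d, P_LV = P_LV, P_LA = P_LA, P_b = P_b,
       Q_src = Q_src, Q_ub = Q_ub, Q_sa = Q_sa, Q_out = Q_out)
}

.initial_state <- function(model) {
  # zeroed capacitor pressures and inductor flows; chambers just above
  # their unloaded volumes (the circuit fills from the source)
  p <- model$params
  stats::setNames(
    c(p$V0_LV + 5, p$V0_LA + 5, rep(0, 4), rep(0, 6)), STATE_NAMES)
}

#' Integrate the circuit to periodic steady state
#'
#' Runs fixed-step RK4 (step `settings$dt`, the model's 0.1 ms reference
#' step) from zeroed capacitor pressures and inductor flows, cycle by
#' cycle, until the relative L-infinity change of the cycle-start state
#' drops below `settings$steady_tol` or `settings$max_cycles` is reached.
#' Non-convergence is a flagged result, not an error.  One further cycle is
#' then recorded as a [waveform_set] on a uniform grid.
#'
#' @param model an [lpm_model()]; alternatively pass `params`, `valves`,
#'   `rec` to [lpm_model()] yourself.
#' @param settings a [solver_settings()].
#' @param state0 optional initial state (named as `cardiolpm:::STATE_NAMES`).
#' @return A `waveform_set`: a data.frame of one steady cycle with columns
#'   `t, P_LV, P_LA, P_ao, P_sa, V_LV, V_LA, Q_AV, Q_AR, Q_MV, Q_MR, Q_PV,
#'   Q_ub, Q_sa`, plus attributes `converged`, `n_cycles`, `rel_change`,
#'   `cycle_volumes` (per-cycle flow integrals, mL), `EDV`, `ESV`, `T`,
#'   `t_ee`, `state_start`, `state_end`.
#' @export
simulate_to_steady <- function(model, settings = solver_settings(),
                               state0 = NULL) {
  stopifnot(inherits(model, "lpm_model"), inherits(settings, "solver_settings"))
  par <- .model_par_vector(model)
  s0 <- if (is.null(state0)) .initial_state(model) else state0[STATE_NAMES]
  res <- .lpm_integrate_cpp(par, as.numeric(s0), settings$dt,
                            settings$steady_tol, settings$max_cycles,
                            settings$n_out)
  wf <- as.data.frame(res$Y)
  wf <- cbind(t = res$t, wf)
  structure(wf,
            class = c("waveform_set", "data.frame"),
            converged = res$converged,
            n_cycles = res$n_cycles,
            rel_change = res$rel_change,
            cycle_volumes = res$volumes,
            EDV = res$EDV, ESV = res$ESV,
            min_V_minus_V0 = res$min_V_minus_V0,
            T = model$T, t_ee = model$t_ee,
            state_start = stats::setNames(res$state_start, STATE_NAMES),
            state_end = stats::setNames(res$state_end, STATE_NAMES))
}

#' @export
print.waveform_set <- function(x, ...) {
  cv <- attr(x, "cycle_volumes")
  cat(sprintf("<waveform_set> %d samples over one cycle (T = %.3f s)\n",
              nrow(x), attr(x, "T")))
  cat(sprintf("  steady: converged=%s after %d cycles (rel change %.2e)\n",
              attr(x, "converged"), attr(x, "n_cycles"), attr(x, "rel_change")))
  cat(sprintf("  cycle volumes [mL]: AV %.1f, MV %.1f, source %.1f\n",
              cv[["AV"]], cv[["MV"]], cv[["source"]]))
  cat(sprintf("  EDV %.1f mL, ESV %.1f mL; P_ao %.0f/%.0f mmHg\n",
              attr(x, "EDV"), attr(x, "ESV"), max(x$P_ao), min(x$P_ao)))
  invisible(x)
}

#' Write / read one steady cycle as CSV
#'
#' Column names are exactly the waveform fields; the header row is the
#' contract for downstream tools.
#'
#' @param waves a `waveform_set` (or any data.frame with its columns).
#' @param path file path.
#' @return `write_waveforms()` returns `path` invisibly; `read_waveforms()`
#'   a data.frame.
#' @export
write_waveforms <- function(waves, path) {
  utils::write.csv(as.data.frame(waves), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path) {
  utils::read.csv(path)
}

#' Human-readable netlist of the assembled circuit
#'
#' @param model an [lpm_model()].
#' @return Character vector (one element per circuit branch), invisibly
#'   printed.
#' @export
netlist <- function(model) {
  p <- model$params
  v <- model$valves
  lines <- c(
    sprintf("SOURCE   Q_src(t) = %.4g * sin(pi t / %.4g), t <= t_ee (rectified sine)", p$Q_MPV, model$t_ee),
    sprintf("NODE     P_CPA:  C_PA=%.4g with series R_PA=%.4g (viscoelastic)", p$C_PA, p$R_PA),
    sprintf("BRANCH   P_CPA -> P_CPVC: R_PC=%.4g + L_PC=%.4g", p$R_PC, p$L_PC),
    sprintf("NODE     P_CPVC: C_PVC=%.4g with series R_PVC=%.4g", p$C_PVC, p$R_PVC),
    sprintf("BRANCH   P_CPVC -> LA: R_PV=%.4g + L_PV=%.4g", p$R_PV, p$L_PV),
    sprintf("CHAMBER  LA: double-Hill elastance, V0=%.4g, phase shift %.3g T", p$V0_LA, p$la_phase_frac),
    sprintf("VALVE    MV (LA -> LV): L=%.4g, B=%.4g, diode", v$MV$inertance_coeff, v$MV$bernoulli_coeff),
    if (!is.null(v$MR)) sprintf("VALVE    MR (LV -> LA): L=%.4g, B=%.4g, diode", v$MR$inertance_coeff, v$MR$bernoulli_coeff),
    sprintf("CHAMBER  LV: double-Hill elastance, V0=%.4g", p$V0_LV),
    sprintf("VALVE    AV (LV -> aorta): L=%.4g, B=%.4g, diode", v$AV$inertance_coeff, v$AV$bernoulli_coeff),
    if (!is.null(v$AR)) sprintf("VALVE    AR (aorta -> LV): L=%.4g, B=%.4g, diode", v$AR$inertance_coeff, v$AR$bernoulli_coeff),
    sprintf("NODE     P_Cao: C_ao=%.4g", p$C_ao),
    sprintf("BRANCH   P_Cao -> P_b: R_ao=%.4g", p$R_ao),
    sprintf("BRANCH   P_b -> venous: R_ub=%.4g (upper body)", p$R_ub),
    sprintf("BRANCH   P_b -> P_CSAC: R_pda=%.4g", p$R_pda),
    sprintf("NODE     P_CSAC: C_SAC=%.4g (windkessel node, proximal to R_SA)", p$C_SAC),
    sprintf("BRANCH   P_CSAC -> venous: R_SA=%.4g + R_SV=%.4g", p$R_SA, p$R_SV),
    sprintf("SINK     venous node clamped at P_CV0=%.4g mmHg", p$P_CV0))
  invisible(lines)
}
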