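#' Double-Hill elastance parameter set
#'
#' Parameters of the double-Hill time-varying elastance used for both heart
#' chambers.  The activation times are fractions of the cardiac period
#' (`tau1 = tau1_frac * T`, `tau2 = tau2_frac * T`), so one parameter set
#' serves any heart rate.  The normalization `N = (E_max - E_min)/2` is
#' always derived, never stored.
#'
#' @param E_max,E_min maximum and minimum elastance, mmHg/mL.
#' @param m1,m2 ascending and descending Hill gradients (dimensionless).
#' @param tau1_frac,tau2_frac ascending/descending time translations as
#'   fractions of `T`.
#' @return An `elastance_params` object.
#' @export
elastance_params <- function(E_max, E_min, m1, m2, tau1_frac, tau2_frac) {
  if (!(E_max > E_min && E_min > 0))
    abort_validation("need E_max > E_min > 0")
  if (m1 <= 0 || m2 <= 0) abort_validation("m1, m2 must be > 0")
  if (!(tau1_frac > 0 && tau1_frac < tau2_frac && tau2_frac < 1))
    abort_validation("need 0 < tau1_frac < tau2_frac < 1")
  structure(list(E_max = E_max, E_min = E_min, m1 = m1, m2 = m2,
                 tau1_frac = tau1_frac, tau2_frac = tau2_frac),
            class = "elastance_params")
}

#' @rdname elastance_params
#' @export
lv_elastance_defaults <- function() {
  elastance_params(E_max = 2.1, E_min = 0.06, m1 = 1.32, m2 = 27.4,
                   tau1_frac = 0.269, tau2_frac = 0.452)
}

#' @rdname elastance_params
#' @export
la_elastance_defaults <- function() {
  elastance_params(E_max = 0.17, E_min = 0.06, m1 = 1.32, m2 = 13.1,
                   tau1_frac = 0.110, tau2_frac = 0.18)
}

#' Circulation circuit parameters
#'
#' All lumped resistances, compliances, inertances and boundary values of
#' the left-heart + systemic + pulmonary circuit, with defaults at the
#' model's reference values.  `R_SA`, `C_SAC`, `C_ao` and `Q_MPV` are the
#' four patient-specific free parameters adjusted by the estimation stage;
#' their defaults are the optimizer's initial values.  `R_ub` defaults to
#' the value that routes 15% of systemic flow through the upper body in the
#' healthy baseline (see [tune_upper_body()]).
#'
#' Units: resistances mmHg.s/mL, compliances mL/mmHg, inertances
#' mmHg.s2/mL, pressures mmHg, `rho_blood` g/mL, `M_MV` g/cm2, `Q_MPV`
#' mL/s, unloaded volumes mL, `la_phase_frac` fraction of `T`.
#'
#' @param ... named overrides of any default.
#' @return A `circulation_params` object (named list).
#' @export
circulation_params <- function(...) {
  p <- list(
    # systemic
    R_ao = 0.05, C_ao = 0.5, R_SV = 0.05, C_SAC = 2, R_SA = 0.8,
    R_ub = 5.48, R_pda = 0.05,
    # pulmonary
    L_PV = 0.0005, R_PV = 0.002, R_PVC = 0.001, C_PVC = 40,
    L_PC = 0.0003, R_PC = 0.21, R_PA = 0.01, C_PA = 4,
    # source / sink
    Q_MPV = 120, P_CV0 = 4,
    # blood / mitral inertance
    rho_blood = RHO_BLOOD, M_MV = 0.53,
    # chambers
    V0_LV = 10, V0_LA = 5,
    la_phase_frac = 0.85,
    elastance_LV = lv_elastance_defaults(),
    elastance_LA = la_elastance_defaults()
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    abort_validation(paste0("unknown parameter(s): ",
                            paste(unknown, collapse = ", ")))
  p[names(over)] <- over
  scal <- setdiff(names(p), c("elastance_LV", "elastance_LA"))
  for (f in scal) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      abort_validation(paste0("parameter ", f, " must be a finite scalar"))
  }
  pos <- c("R_ao", "C_ao", "R_SV", "C_SAC", "R_SA", "R_ub", "R_pda",
           "L_PV", "R_PV", "R_PVC", "C_PVC", "L_PC", "R_PC", "R_PA",
           "C_PA", "Q_MPV", "rho_blood", "M_MV")
  for (f in pos)
    if (p[[f]] <= 0) abort_validation(paste0("parameter ", f, " must be > 0"))
  stopifnot(inherits(p$elastance_LV, "elastance_params"),
            inherits(p$elastance_LA, "elastance_params"))
  structure(p, class = "circulation_params")
}

#' @export
print.circulation_params <- function(x, ...) {
  cat("<circulation_params>\n")
  cat(sprintf("  systemic: R_ao %.3g C_ao %.3g R_SA %.3g C_SAC %.3g R_SV %.3g R_ub %.3g R_pda %.3g\n",
              x$R_ao, x$C_ao, x$R_SA, x$C_SAC, x$R_SV, x$R_ub, x$R_pda))
  cat(sprintf("  pulmonary: R_PA %.3g C_PA %.3g R_PC %.3g L_PC %.3g R_PVC %.3g C_PVC %.3g R_PV %.3g L_PV %.3g\n",
              x$R_PA, x$C_PA, x$R_PC, x$L_PC, x$R_PVC, x$C_PVC, x$R_PV, x$L_PV))
  cat(sprintf("  source Q_MPV %.1f mL/s, venous sink P_CV0 %.1f mmHg\n",
              x$Q_MPV, x$P_CV0))
  invisible(x)
}

#' Solver settings for the circuit integration
#'
#' @param dt fixed integration step, s (default 1e-4, i.e. 0.1 ms).
#' @param steady_tol relative L-infinity change of the cycle-start state
#'   between consecutive cycles below which the solution is declared
#'   periodic (default 1e-6).
#' @param max_cycles cap on the number of cycles integrated (default 200;
#'   cold starts from zeroed initial conditions need ~150 cycles to meet
#'   the 1e-6 periodicity criterion, with some headroom).
#' @param n_out samples per cycle in the returned waveforms (default 500).
#' @return A `solver_settings` object.
#' @export
solver_settings <- function(dt = 1e-4, steady_tol = 1e-6, max_cycles = 200,
                            n_out = 500) {
  stopifnot(dt > 0, steady_tol > 0, max_cycles >= 1, n_out >= 100)
  structure(list(dt = dt, steady_tol = steady_tol,
                 max_cycles = as.integer(max_cycles),
                 n_out = as.integer(n_out)),
            class = "solver_settings")
}
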