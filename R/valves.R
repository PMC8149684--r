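#' Valvular energy loss coefficient
#'
#' Effective area accounting for downstream pressure recovery,
#' `E_L_Co = EOA * A / (A - EOA)`, where `A` is the downstream cross
#' section (ascending aorta for the aortic valve, LVOT for aortic
#' regurgitation).  Diverges as `EOA -> A`.
#'
#' @param eoa effective orifice area, cm2.
#' @param A downstream reference cross-sectional area, cm2.
#' @return Energy loss coefficient, cm2.
#' @examples
#' energy_loss_coefficient(1, 5)   # 1.25
#' @export
energy_loss_coefficient <- function(eoa, A) {
  if (any(eoa <= 0)) abort_domain("eoa must be > 0")
  if (any(eoa >= A))
    abort_domain("eoa must be < reference area A (singular denominator)")
  eoa * A / (A - eoa)
}

#' Valve branch elements
#'
#' A valve branch carries the two coefficients of the net-pressure-gradient
#' formulation: an inertial coefficient multiplying `dQ/dt` and a Bernoulli
#' (convective) coefficient multiplying `Q^2`.  For the aortic-side branches
#' (AV, AR) the inertial coefficient is `2*pi*rho / sqrt(E_L_Co)` and the
#' convective one `rho / (2 E_L_Co^2)`; for the mitral-side branches (MV,
#' MR) they are `M_MV / EOA` and `rho / (2 EOA^2)`.  Both are evaluated in
#' CGS and stored converted to mmHg-based units (1 mmHg = 1333.22 dyn/cm2):
#' `inertance_coeff` in mmHg.s2/mL, `bernoulli_coeff` in mmHg.s2/mL2.
#' Every branch is diode-gated: it conducts only in its forward orientation.
#'
#' @param kind one of `"AV"`, `"AR"`, `"MV"`, `"MR"`.
#' @param eoa effective orifice area, cm2.
#' @param reference_area downstream area, cm2 (`A_AO` for AV, `A_LVOT` for
#'   AR; unused for MV/MR).
#' @param rho blood density, g/mL.
#' @param M_MV mitral inertance constant, g/cm2.
#' @return A `valve_branch` object.
#' @export
valve_branch <- function(kind = c("AV", "AR", "MV", "MR"), eoa,
                         reference_area = NULL, rho = RHO_BLOOD,
                         M_MV = 0.53) {
  kind <- match.arg(kind)
  if (eoa <= 0) abort_domain("eoa must be > 0")
  if (kind %in% c("AV", "AR")) {
    if (is.null(reference_area))
      abort_domain(paste0(kind, " branch needs a reference area"))
    el_co <- energy_loss_coefficient(eoa, reference_area)
    inertance <- 2 * pi * rho / sqrt(el_co) / DYN_CM2_PER_MMHG
    bernoulli <- rho / (2 * el_co^2) / DYN_CM2_PER_MMHG
  } else {
    el_co <- NA_real_
    inertance <- M_MV / eoa / DYN_CM2_PER_MMHG
    bernoulli <- rho / (2 * eoa^2) / DYN_CM2_PER_MMHG
  }
  structure(list(kind = kind, eoa = eoa,
                 reference_area = reference_area %||% NA_real_,
                 el_co = el_co,
                 inertance_coeff = inertance, bernoulli_coeff = bernoulli,
                 gated = TRUE),
            class = "valve_branch")
}

#' Instantaneous net pressure gradient across a valve branch
#'
#' `PG = inertance_coeff * dQ/dt + bernoulli_coeff * Q |Q|` in mmHg.  The
#' convective term is signed so that the gradient always opposes the flow.
#'
#' @param branch a [valve_branch()].
#' @param Q transvalvular flow, mL/s.
#' @param dQdt flow acceleration, mL/s2.
#' @return Net pressure gradient, mmHg.
#' @export
net_pressure_gradient <- function(branch, Q, dQdt) {
  stopifnot(inherits(branch, "valve_branch"))
  if (!is.finite(branch$inertance_coeff) || !is.finite(branch$bernoulli_coeff))
    abort_domain("valve branch coefficients are not initialized")
  branch$inertance_coeff * dQdt + branch$bernoulli_coeff * Q * abs(Q)
}

#' Build the valve branches for one patient
#'
#' The forward aortic and mitral branches are always present.  Reverse
#' (regurgitant) branches are included only when the corresponding
#' regurgitant orifice area is recorded; otherwise the reverse branch is
#' simply absent from the circuit.
#'
#' @param rec a [patient_record()].
#' @param rho blood density, g/mL.
#' @param M_MV mitral inertance constant, g/cm2.
#' @return Named list of [valve_branch()] objects (`AV`, `MV`, and
#'   optionally `AR`, `MR`).
#' @export
build_patient_valves <- function(rec, rho = RHO_BLOOD, M_MV = 0.53) {
  stopifnot(inherits(rec, "patient_record"))
  valves <- list(
    AV = valve_branch("AV", rec$EOA_AV, rec$A_AO, rho = rho),
    MV = valve_branch("MV", rec$EOA_MV, rho = rho, M_MV = M_MV)
  )
  if (!is.null(rec$EOA_AR)) {
    if (rec$EOA_AR >= rec$A_LVOT)
      abort_validation("EOA_AR must be < A_LVOT")
    valves$AR <- valve_branch("AR", rec$EOA_AR, rec$A_LVOT, rho = rho)
  }
  if (!is.null(rec$EOA_MR))
    valves$MR <- valve_branch("MR", rec$EOA_MR, rho = rho, M_MV = M_MV)
  valves
}
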