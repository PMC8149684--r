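#' Double-Hill time-varying elastance
#'
#' Elastance couples chamber pressure and volume, `P(t) = E(t) (V(t) - V0)`.
#' Its time course over one beat is the product of an ascending Hill term
#' (contraction) and a descending Hill term (relaxation):
#'
#' `E(t) = N * [(t/tau1)^m1 / (1 + (t/tau1)^m1)] * [1 / (1 + (t/tau2)^m2)] + E_min`
#'
#' with `N = (E_max - E_min)/2` and `tau_i = tau_i_frac * T`.  Time is taken
#' modulo `T`, so multi-cycle integrations need no wrapping by callers.
#' `E(0) = E_min` exactly, and because both bracketed factors lie in
#' \[0, 1\],
#' `E_min <= E(t) <= (E_max + E_min)/2` everywhere.
#'
#' @param t time since onset of isovolumic contraction, s (vectorized).
#' @param p an [elastance_params()] set.
#' @param T cardiac period, s.
#' @return Elastance in mmHg/mL.
#' @examples
#' elastance_value(0.25, lv_elastance_defaults(), T = 1)
#' @export
elastance_value <- function(t, p, T) {
  if (any(t < 0)) abort_domain("t must be >= 0")
  stopifnot(inherits(p, "elastance_params"), T > 0)
  tt <- t %% T
  tau1 <- p$tau1_frac * T
  tau2 <- p$tau2_frac * T
  N <- (p$E_max - p$E_min) / 2
  a <- (tt / tau1)^p$m1
  N * (a / (1 + a)) / (1 + (tt / tau2)^p$m2) + p$E_min
}

#' Chamber pressure from volume via elastance
#'
#' @param V instantaneous chamber volume, mL.
#' @param V0 unloaded volume, mL.
#' @inheritParams elastance_value
#' @return Pressure in mmHg.
#' @export
chamber_pressure <- function(V, V0, t, p, T) {
  if (any(V <= V0)) abort_domain("degenerate volume: V must exceed V0")
  elastance_value(t, p, T) * (V - V0)
}

#' Anchor the simulated loop to the measured end-diastolic volume
#'
#' The pressure side of the circuit fixes `V - V0`, not `V` itself, so the
#' unloaded volume is shifted by the end-diastolic mismatch,
#' `V0' = V0 + (EDV_measured - EDV_simulated)`; one re-simulation then
#' reproduces the measured EDV (the ESV shift follows).
#'
#' @param simulated_EDV,measured_EDV end-diastolic volumes, mL.
#' @param V0 current unloaded volume, mL.
#' @return The shifted unloaded volume `V0'`, mL.
#' @export
adjust_unloaded_volume <- function(simulated_EDV, measured_EDV, V0) {
  if (simulated_EDV <= 0 || measured_EDV <= 0)
    abort_domain("volumes must be > 0")
  V0 + (measured_EDV - simulated_EDV)
}
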