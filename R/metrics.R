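#' Ejection fraction
#'
#' `EF = (EDV - ESV)/EDV`; values below 0.41 are conventionally classified
#' as reduced contractility.
#'
#' @param EDV,ESV end-diastolic and end-systolic volumes, mL.
#' @return Fraction in (0, 1].
#' @export
ejection_fraction <- function(EDV, ESV) {
  if (any(ESV < 0) || any(EDV <= ESV))
    abort_domain("need EDV > ESV >= 0")
  (EDV - ESV) / EDV
}

#' @rdname ejection_fraction
#' @param ef an ejection fraction.
#' @export
ef_reduced <- function(ef) ef < 0.41

#' Left-ventricular workload (stroke work) from a P-V loop
#'
#' The loop area in the pressure-volume plane, computed by the shoelace
#' formula and converted to joules (1 mmHg.mL = 1.33322e-4 J).  Traversal
#' direction does not change the magnitude.
#'
#' @param P pressures, mmHg.
#' @param V volumes, mL; same length as `P` (the loop is closed
#'   implicitly between the last and first point).
#' @return Stroke work, J.
#' @examples
#' # rectangle loop: 100 mmHg x 70 mL = 7000 mmHg.mL = 0.9333 J
#' lv_workload(c(10, 110, 110, 10), c(50, 50, 120, 120))
#' @export
lv_workload <- function(P, V) {
  if (length(P) != length(V) || length(P) < 3)
    abort_domain("P and V must be equal-length vectors of length >= 3")
  Pn <- c(P, P[1]); Vn <- c(V, V[1])
  n <- length(P)
  area <- abs(sum(Vn[1:n] * Pn[2:(n + 1)] - Vn[2:(n + 1)] * Pn[1:n]) / 2)
  area * J_PER_MMHG_ML
}

#' Systemic arterial compliance (SAC)
#'
#' Stroke-volume-to-pulse-pressure estimator `SAC = SV / (SBP - DBP)`,
#' mL/mmHg.  Indexing to body surface area (mL/m2/mmHg) is left to the
#' caller.  Values at or below 1 mL/mmHg are flagged as low.
#'
#' @param forward_sv forward stroke volume, mL.
#' @param SBP,DBP systolic/diastolic pressures, mmHg.
#' @return Compliance, mL/mmHg.
#' @export
systemic_arterial_compliance <- function(forward_sv, SBP, DBP) {
  if (any(SBP <= DBP)) abort_domain("zero or negative pulse pressure")
  forward_sv / (SBP - DBP)
}

#' @rdname systemic_arterial_compliance
#' @param sac a compliance, mL/mmHg.
#' @export
sac_low <- function(sac) sac <= 1

#' E/A ratio of the transmitral velocity
#'
#' Transmitral velocity is `Q_MV / EOA_MV`.  During diastole it is
#' biphasic: an early filling peak (E) followed by the atrial-contraction
#' peak (A).  Peaks are local maxima separated by at least `min_sep * T`;
#' the earlier peak is E.  A fused or missing A wave yields a single-peak
#' result with `ratio = NA` and `defined = FALSE`.
#'
#' @param waves a [simulate_to_steady()] waveform set (needs `t`, `Q_MV`
#'   and attribute `t_ee` marking end of systole), or any data.frame with
#'   those columns plus explicit `t_ee`, `T` arguments.
#' @param eoa_mv mitral effective orifice area, cm2.
#' @param t_ee,T systole end and cycle period, s (defaulted from
#'   attributes when `waves` is a `waveform_set`).
#' @param min_sep minimal peak separation as a fraction of `T`.
#' @return List with `E_peak`, `A_peak` (cm/s), `t_E`, `t_A` (s), `ratio`,
#'   `defined`, `normal` (ratio within the 0.8-2 band).
#' @export
ea_ratio <- function(waves, eoa_mv, t_ee = attr(waves, "t_ee"),
                     T = attr(waves, "T"), min_sep = 0.05) {
  stopifnot(!is.null(t_ee), !is.null(T))
  v <- waves$Q_MV / eoa_mv
  t <- waves$t
  dia <- t > t_ee
  vd <- v[dia]; td <- t[dia]
  n <- length(vd)
  if (n < 3) abort_domain("no diastolic samples")
  is_peak <- which(vd[2:(n - 1)] > vd[1:(n - 2)] &
                   vd[2:(n - 1)] >= vd[3:n] &
                   vd[2:(n - 1)] > 1e-9) + 1L
  if (length(is_peak) == 0)
    return(list(E_peak = NA_real_, A_peak = NA_real_, t_E = NA_real_,
                t_A = NA_real_, ratio = NA_real_, defined = FALSE,
                normal = NA))
  # order peaks in time, merge peaks closer than min_sep*T (keep higher)
  pk_t <- td[is_peak]; pk_v <- vd[is_peak]
  keep <- order(pk_v, decreasing = TRUE)
  sel <- integer(0)
  for (i in keep) {
    if (all(abs(pk_t[i] - pk_t[sel]) >= min_sep * T)) sel <- c(sel, i)
    if (length(sel) == 2) break
  }
  sel <- sel[order(pk_t[sel])]
  if (length(sel) < 2)
    return(list(E_peak = pk_v[sel[1]], A_peak = NA_real_, t_E = pk_t[sel[1]],
                t_A = NA_real_, ratio = NA_real_, defined = FALSE,
                normal = NA))
  E <- pk_v[sel[1]]; A <- pk_v[sel[2]]
  list(E_peak = E, A_peak = A, t_E = pk_t[sel[1]], t_A = pk_t[sel[2]],
       ratio = E / A, defined = TRUE,
       normal = E / A >= 0.8 && E / A <= 2)
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' `TAWSS = (1/T) integral over the cycle of |tau| dt` by trapezoidal
#' quadrature.  The series must lie within `[0, T]`.  The normal left
#' ventricle operates between roughly 0.2 and 1.2 Pa.
#'
#' @param t sample times, s (strictly increasing).
#' @param tau wall shear stress samples, Pa (magnitudes are taken).
#' @param T cycle period, s.
#' @return TAWSS, Pa.
#' @export
tawss <- function(t, tau, T) {
  if (any(t < 0) || any(t > T + 1e-12)) abort_domain("t must lie in [0, T]")
  if (any(diff(t) <= 0)) abort_domain("t must be strictly increasing")
  trapz(t, abs(tau)) / T
}

#' @rdname tawss
#' @param x a TAWSS value, Pa.
#' @export
tawss_normal <- function(x) x >= 0.2 & x <= 1.2

#' Vortex sphericity index
#'
#' Length-to-width ratio `SI = D2/D1` of the intraventricular vortex
#' measured in the apical long-axis plane; `SI > 2` is considered normal.
#'
#' @param D2_length vortex length, cm.
#' @param D1_width vortex width, cm.
#' @return List with `si` and `normal`.
#' @export
sphericity_index <- function(D2_length, D1_width) {
  if (any(D2_length <= 0) || any(D1_width <= 0))
    abort_domain("vortex dimensions must be > 0")
  si <- D2_length / D1_width
  list(si = si, normal = si > 2)
}

#' Cycle pressure summaries and transvalvular gradients
#'
#' Extrema of the chamber and aortic pressures over one steady cycle, plus
#' the phase-restricted transvalvular gradients: the transmitral gradient
#' is the diastolic maximum of `P_LA - P_LV`, the aortic gradient the
#' systolic maximum of `P_LV - P_ao` (both non-negative by construction).
#' The mean aortic-valve gradient is the ejection-phase time average of the
#' instantaneous gradient; above 40 mmHg it flags severe aortic stenosis.
#' The Doppler-style transmitral estimate `4 v^2` (v = peak E velocity in
#' m/s) is reported alongside when `eoa_mv` is given.
#'
#' @param waves a [simulate_to_steady()] waveform set.
#' @param t_ee,T systole end and cycle period, s (defaulted from
#'   attributes).
#' @param eoa_mv optional mitral orifice area, cm2, for the Doppler-style
#'   gradient estimate.
#' @return Named list of summaries (mmHg).
#' @export
pressure_summaries <- function(waves, t_ee = attr(waves, "t_ee"),
                               T = attr(waves, "T"), eoa_mv = NULL) {
  if (nrow(waves) == 0) abort_domain("empty waveform")
  stopifnot(!is.null(t_ee))
  sys <- waves$t <= t_ee
  dia <- !sys
  out <- list(
    max_P_LA = max(waves$P_LA),
    max_P_LV = max(waves$P_LV),
    max_P_ao = max(waves$P_ao),
    min_P_ao = min(waves$P_ao),
    max_transmitral_PG = max(0, (waves$P_LA - waves$P_LV)[dia]),
    max_AV_PG = max(0, (waves$P_LV - waves$P_ao)[sys]),
    mean_AV_PG = {
      pg <- pmax(waves$P_LV - waves$P_ao, 0)[sys]
      ts <- waves$t[sys]
      if (length(ts) > 1) trapz(ts, pg) / (max(ts) - min(ts)) else pg
    }
  )
  out$severe_as <- out$mean_AV_PG > 40
  if (!is.null(eoa_mv)) {
    vE <- max(waves$Q_MV[dia] / eoa_mv) / 100   # cm/s -> m/s
    out$doppler_transmitral_PG <- 4 * vE^2
  }
  out
}

#' All standard metrics for a fitted patient
#'
#' Convenience wrapper assembling the global metrics from a steady
#' waveform set: EF, stroke work, SAC, E/A ratio and pressure summaries.
#'
#' @param waves a [simulate_to_steady()] result.
#' @param rec the corresponding [patient_record()].
#' @return Named list (flat, JSON-serializable apart from the nested E/A
#'   entry).
#' @export
hemodynamic_metrics <- function(waves, rec) {
  edv <- attr(waves, "EDV"); esv <- attr(waves, "ESV")
  cv <- attr(waves, "cycle_volumes")
  ea <- ea_ratio(waves, rec$EOA_MV)
  ps <- pressure_summaries(waves, eoa_mv = rec$EOA_MV)
  c(list(
    EDV = edv, ESV = esv,
    EF = ejection_fraction(edv, esv),
    EF_reduced = ef_reduced(ejection_fraction(edv, esv)),
    lv_workload_J = lv_workload(waves$P_LV, waves$V_LV),
    forward_sv = cv[["AV"]],
    SAC = systemic_arterial_compliance(cv[["AV"]], max(waves$P_ao),
                                       min(waves$P_ao)),
    E_peak = ea$E_peak, A_peak = ea$A_peak, EA_ratio = ea$ratio,
    EA_defined = ea$defined
  ), ps)
}
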