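#' Configuration for the synthetic-patient generator
#'
#' Sampling ranges are physiological by construction: heart rate 50-90
#' beats/min, ejection fraction of the cycle 0.28-0.38, target forward
#' stroke volume 40-100 mL, aortic-valve effective orifice 0.6-2.5 cm2,
#' mitral orifice 2.5-5 cm2.  The free circuit parameters are sampled
#' log-uniformly within +/-50% of their reference initial values
#' (R_SA 0.8, C_SAC 2, C_ao 0.5) and `Q_MPV` is set analytically to
#' deliver the sampled stroke volume.  Regurgitant orifices are absent
#' with probability `1 - include_regurgitation` and otherwise drawn from
#' 0.05-0.4 cm2, exercising the reverse-branch inclusion logic.
#'
#' @param seed integer RNG seed.
#' @param n number of patients.
#' @param noise list of measurement-noise magnitudes: `sv_frac`
#'   (multiplicative sd on stroke volume and VTIs), `bp_mmHg` (additive sd
#'   on SBP/DBP), `vol_frac` (multiplicative sd on EDV/ESV).  All default
#'   to 0 (noise-free).
#' @param include_regurgitation per-valve probability of a regurgitant
#'   branch (default 0.15).
#' @param ranges optional overrides of the sampling ranges (named list of
#'   length-2 numeric vectors).
#' @return A `synth_config` object.
#' @export
synth_config <- function(seed = 1L, n = 20L,
                         noise = list(sv_frac = 0, bp_mmHg = 0, vol_frac = 0),
                         include_regurgitation = 0.15,
                         ranges = list()) {
  base <- list(
    HR = c(50, 90), tej_frac = c(0.28, 0.38), SV = c(40, 100),
    EOA_AV = c(0.6, 2.5), EOA_MV = c(2.5, 5),
    D_LVOT = c(1.8, 2.4), D_AO = c(2.7, 3.6),
    V0_LV = c(5, 25), EOA_regurg = c(0.05, 0.4)
  )
  base[names(ranges)] <- ranges
  noise_full <- list(sv_frac = 0, bp_mmHg = 0, vol_frac = 0)
  noise_full[names(noise)] <- noise
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 noise = noise_full,
                 include_regurgitation = include_regurgitation,
                 ranges = base),
            class = "synth_config")
}

.runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

# one ground-truth draw (no simulation yet)
.sample_truth <- function(cfg) {
  r <- cfg$ranges
  HR <- stats::runif(1, r$HR[1], r$HR[2])
  T <- 60 / HR
  T_EJ <- stats::runif(1, r$tej_frac[1], r$tej_frac[2]) * T
  SV <- stats::runif(1, r$SV[1], r$SV[2])
  eoa_ar <- if (stats::runif(1) < cfg$include_regurgitation)
    stats::runif(1, r$EOA_regurg[1], r$EOA_regurg[2]) else NULL
  eoa_mr <- if (stats::runif(1) < cfg$include_regurgitation)
    stats::runif(1, r$EOA_regurg[1], r$EOA_regurg[2]) else NULL
  list(
    T = T, T_EJ = T_EJ, SV_target = SV,
    D_LVOT = stats::runif(1, r$D_LVOT[1], r$D_LVOT[2]),
    D_AO = stats::runif(1, r$D_AO[1], r$D_AO[2]),
    EOA_AV = stats::runif(1, r$EOA_AV[1], r$EOA_AV[2]),
    EOA_MV = stats::runif(1, r$EOA_MV[1], r$EOA_MV[2]),
    EOA_AR = eoa_ar, EOA_MR = eoa_mr,
    Q_MPV = pi * SV / (2 * T_EJ),
    R_SA = .runif_log(1, 0.8 / 1.5, 0.8 * 1.5),
    C_SAC = .runif_log(1, 2 / 1.5, 2 * 1.5),
    C_ao = .runif_log(1, 0.5 / 1.5, 0.5 * 1.5),
    V0_LV = stats::runif(1, r$V0_LV[1], r$V0_LV[2])
  )
}

.noisy <- function(x, frac = 0, add = 0) {
  x * (1 + stats::rnorm(length(x), 0, frac)) + stats::rnorm(length(x), 0, add)
}

#' Generate a synthetic cohort with known ground truth
#'
#' For each patient a ground-truth circuit is sampled, forward-simulated to
#' periodic steady state, and read back out the way a sonographer would
#' measure it: the forward LVOT stroke volume from the simulated forward
#' aortic-valve volume, SBP/DBP from the simulated aortic pressure
#' extrema, EDV/ESV from the simulated loop, VTIs consistent with the
#' continuity equations, and the sampled orifice areas as the "measured"
#' ones.  Optional measurement noise is then applied.  Draws whose steady
#' solve does not converge or whose record fails validation are resampled
#' (bounded retries).
#'
#' @param cfg a [synth_config()].
#' @param R_ub upper-body resistance; `NULL` tunes it once via
#'   [tune_upper_body()].
#' @param settings a [solver_settings()].
#' @param max_retries resampling budget per patient.
#' @return List of `n` elements, each `list(record, truth)` where `truth`
#'   carries the generating parameters plus the noise-free simulated
#'   SBP/DBP/SV.
#' @export
generate_cohort <- function(cfg, R_ub = NULL, settings = solver_settings(),
                            max_retries = 10) {
  stopifnot(inherits(cfg, "synth_config"))
  base <- circulation_params()
  base$R_ub <- R_ub %||% tune_upper_body(base, settings = settings)
  with_preserved_seed(cfg$seed, {
    lapply(seq_len(cfg$n), function(i) {
      for (try in seq_len(max_retries)) {
        tr <- .sample_truth(cfg)
        out <- tryCatch(.realize_patient(tr, cfg, base, settings, i),
                        error = function(e) NULL)
        if (!is.null(out)) return(out)
      }
      stop("failed to generate a valid synthetic patient after ",
           max_retries, " retries")
    })
  })
}

.realize_patient <- function(tr, cfg, base, settings, i) {
  params <- base
  params$Q_MPV <- tr$Q_MPV
  params$R_SA <- tr$R_SA; params$C_SAC <- tr$C_SAC; params$C_ao <- tr$C_ao
  params$V0_LV <- tr$V0_LV

  A_LVOT <- pi * tr$D_LVOT^2 / 4
  A_AO <- pi * tr$D_AO^2 / 4
  if (tr$EOA_AV >= A_AO) return(NULL)

  pre <- list(
    id = sprintf("synth-%03d", i),
    T = tr$T, T_EJ = tr$T_EJ,
    forward_lvot_sv = tr$SV_target,  # provisional, replaced below
    D_LVOT = tr$D_LVOT, VTI_LVOT = tr$SV_target / A_LVOT,
    D_AO = tr$D_AO, VTI_AO = tr$SV_target / tr$EOA_AV,
    EOA_AV = tr$EOA_AV, EOA_MV = tr$EOA_MV,
    EDV = 120, ESV = 50, SBP = 120, DBP = 80  # placeholders for validation
  )
  if (!is.null(tr$EOA_AR)) pre$EOA_AR <- tr$EOA_AR
  if (!is.null(tr$EOA_MR)) pre$EOA_MR <- tr$EOA_MR
  rec0 <- patient_record(pre)

  valves <- build_patient_valves(rec0, rho = params$rho_blood,
                                 M_MV = params$M_MV)
  wf <- simulate_to_steady(lpm_model(params, valves, rec0), settings)
  if (!attr(wf, "converged")) return(NULL)
  cv <- attr(wf, "cycle_volumes")
  sv <- cv[["AV"]]
  sbp <- max(wf$P_ao); dbp <- min(wf$P_ao)
  edv <- attr(wf, "EDV"); esv <- attr(wf, "ESV")
  if (sbp > 260 || dbp < 15 || sbp - dbp < 15) return(NULL)

  nz <- cfg$noise
  sv_m <- .noisy(sv, frac = nz$sv_frac)
  rec <- pre
  rec$forward_lvot_sv <- sv_m
  rec$VTI_LVOT <- sv_m / A_LVOT
  rec$VTI_AO <- sv_m / tr$EOA_AV
  rec$SBP <- .noisy(sbp, add = nz$bp_mmHg)
  rec$DBP <- .noisy(dbp, add = nz$bp_mmHg)
  if (rec$SBP <= rec$DBP) return(NULL)
  rec$EDV <- .noisy(edv, frac = nz$vol_frac)
  rec$ESV <- .noisy(esv, frac = nz$vol_frac)
  if (rec$EDV <= rec$ESV) return(NULL)
  record <- patient_record(rec)

  truth <- tr
  truth$sim <- list(forward_sv = sv, SBP = sbp, DBP = dbp,
                    EDV = edv, ESV = esv)
  truth$R_ub <- params$R_ub
  list(record = record, truth = truth)
}

#' Parameter-recovery report for a fitted cohort
#'
#' Per-patient relative errors of the recovered free parameters against the
#' generating truth, with medians and worst cases.  Pulse-pressure
#' reproduction error is `|(SBP_fit - DBP_fit) - (SBP_target - DBP_target)|`
#' in mmHg; compliance error is on the total `C_ao + C_SAC` (the split is
#' only weakly identified by two pressure targets).
#'
#' @param cohort output of [generate_cohort()].
#' @param fits list of [fit_patient()] results, matched by position.
#' @return A data.frame with one row per patient and an attribute
#'   `summary` (named medians and maxima).
#' @export
recovery_report <- function(cohort, fits) {
  if (length(cohort) != length(fits))
    abort_domain("cohort and fits must have the same length")
  rows <- Map(function(cp, ft) {
    tr <- cp$truth; p <- ft$params
    pp_target <- cp$record$SBP - cp$record$DBP
    pp_fit <- (cp$record$SBP + ft$sbp_error) - (cp$record$DBP + ft$dbp_error)
    data.frame(
      id = cp$record$id,
      qmpv_rel_err = abs(p$Q_MPV - tr$Q_MPV) / tr$Q_MPV,
      rsa_rel_err = abs(p$R_SA - tr$R_SA) / tr$R_SA,
      ctot_rel_err = abs((p$C_ao + p$C_SAC) - (tr$C_ao + tr$C_SAC)) /
        (tr$C_ao + tr$C_SAC),
      pp_err_mmHg = abs(pp_fit - pp_target),
      sv_rel_err = abs(ft$sv_error) / cp$record$forward_lvot_sv,
      converged = ft$converged
    )
  }, cohort, fits)
  out <- do.call(rbind, rows)
  num <- c("qmpv_rel_err", "rsa_rel_err", "ctot_rel_err", "pp_err_mmHg",
           "sv_rel_err")
  attr(out, "summary") <- c(
    stats::setNames(vapply(num, function(f) stats::median(out[[f]]), 0),
                    paste0("median_", num)),
    stats::setNames(vapply(num, function(f) max(out[[f]]), 0),
                    paste0("max_", num)))
  out
}

#' Sensitivity of the model outputs to its inputs
#'
#' Perturbs the forward LVOT stroke volume target by `+/-delta` (re-running
#' the stage-1 fit so the model tracks the perturbed measurement) and each
#' pulmonary circuit constant by the same relative amount (no refit;
#' these are fixed model constants), reporting the induced relative
#' changes in peak LV pressure and maximal LV volume.
#'
#' @param rec a [patient_record()].
#' @param params fitted [circulation_params()] for this patient (after the
#'   two-stage fit).
#' @param settings a [solver_settings()].
#' @param delta relative perturbation (default 0.2).
#' @param pulmonary_constants which constants to perturb.
#' @return data.frame with columns `input`, `direction`,
#'   `peak_plv_change`, `max_vlv_change` (relative changes).
#' @export
sensitivity_report <- function(rec, params, settings = solver_settings(),
                               delta = 0.2,
                               pulmonary_constants = c("R_PV", "R_PC", "R_PA",
                                                       "L_PV", "L_PC",
                                                       "C_PA", "C_PVC")) {
  solve_with <- function(p, r = rec) {
    wf <- simulate_to_steady(lpm_model(p, build_patient_valves(
      r, rho = p$rho_blood, M_MV = p$M_MV), r), settings)
    c(peak_plv = max(wf$P_LV), max_vlv = max(wf$V_LV))
  }
  base <- solve_with(params)
  rows <- list()
  for (dir in c(1, -1)) {
    r2 <- rec
    r2$forward_lvot_sv <- rec$forward_lvot_sv * (1 + dir * delta)
    r2$VTI_LVOT <- rec$VTI_LVOT * (1 + dir * delta)
    r2$VTI_AO <- rec$VTI_AO * (1 + dir * delta)
    p2 <- fit_qmpv(r2, params, settings)
    out <- solve_with(p2, r2)
    rows[[length(rows) + 1]] <- data.frame(
      input = "forward_lvot_sv", direction = dir,
      peak_plv_change = (out[["peak_plv"]] - base[["peak_plv"]]) / base[["peak_plv"]],
      max_vlv_change = (out[["max_vlv"]] - base[["max_vlv"]]) / base[["max_vlv"]])
    for (cn in pulmonary_constants) {
      p3 <- params
      p3[[cn]] <- params[[cn]] * (1 + dir * delta)
      out <- solve_with(p3)
      rows[[length(rows) + 1]] <- data.frame(
        input = cn, direction = dir,
        peak_plv_change = (out[["peak_plv"]] - base[["peak_plv"]]) / base[["peak_plv"]],
        max_vlv_change = (out[["max_vlv"]] - base[["max_vlv"]]) / base[["max_vlv"]])
    }
  }
  do.call(rbind, rows)
}
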