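#' Doppler-echocardiography geometry helpers
#'
#' Scalar formulas linking the routinely measured Doppler quantities to the
#' areas and volumes the circuit model needs: the forward LVOT stroke volume
#' from the outflow-tract diameter and velocity-time integral, the ascending
#' aorta cross-section from its diameter, the aortic-valve effective orifice
#' area by continuity, and the elliptical mitral orifice area from its two
#' apical-view diameters.
#'
#' @param D_LVOT,D_AO diameters, cm.
#' @param VTI_LVOT,VTI_AO velocity-time integrals, cm.
#' @param forward_sv forward LVOT stroke volume, mL.
#' @param d1,d2 mitral orifice diameters in the apical two- and four-chamber
#'   views, cm.
#' @return Areas in cm2; `forward_lvot_sv()` returns mL.
#' @examples
#' forward_lvot_sv(D_LVOT = 2, VTI_LVOT = 20)   # 20*pi mL
#' ascending_aorta_area(D_AO = 3)
#' eoa_av_continuity(62.832, VTI_AO = 50)
#' mitral_area_from_diameters(3, 4)
#' @name doppler_geometry
NULL

#' @rdname doppler_geometry
#' @export
forward_lvot_sv <- function(D_LVOT, VTI_LVOT) {
  if (any(D_LVOT <= 0)) abort_domain("D_LVOT must be > 0")
  if (any(VTI_LVOT < 0)) abort_domain("VTI_LVOT must be >= 0")
  pi * D_LVOT^2 / 4 * VTI_LVOT
}

#' @rdname doppler_geometry
#' @export
ascending_aorta_area <- function(D_AO) {
  if (any(D_AO <= 0)) abort_domain("D_AO must be > 0")
  pi * D_AO^2 / 4
}

#' @rdname doppler_geometry
#' @export
eoa_av_continuity <- function(forward_sv, VTI_AO) {
  if (any(forward_sv <= 0)) abort_domain("forward_sv must be > 0")
  if (any(VTI_AO <= 0)) abort_domain("VTI_AO must be > 0")
  forward_sv / VTI_AO
}

#' @rdname doppler_geometry
#' @export
mitral_area_from_diameters <- function(d1, d2) {
  if (any(d1 <= 0) || any(d2 <= 0)) abort_domain("mitral diameters must be > 0")
  pi * d1 * d2 / 4
}

PATIENT_SCHEMA_VERSION <- "1.0"

# fields that must be present (after HR/T reconciliation)
.mandatory_fields <- c(
  "id", "forward_lvot_sv", "T", "T_EJ", "D_LVOT", "VTI_LVOT",
  "D_AO", "VTI_AO", "EOA_AV", "EDV", "ESV", "SBP", "DBP"
)
.optional_fields <- c("HR", "EOA_MV", "d1", "d2", "EOA_AR", "EOA_MR")

#' Construct and validate a patient record
#'
#' A `patient_record` bundles the per-patient inputs of the circuit model:
#' the forward LVOT stroke volume, cycle timing, valve effective orifice
#' areas, chamber volumes and cuff pressures.  `HR` (beats/min) and `T` (s)
#' are mutually derivable; supply either (both are accepted when consistent
#' to 1%).  The mitral orifice may be given directly as `EOA_MV` or as the
#' ellipse diameters `d1`,`d2`; an explicit `EOA_MV` wins.  Regurgitant
#' orifice areas `EOA_AR`/`EOA_MR` are optional and, when absent, the
#' corresponding reverse valve branch is simply not built.
#'
#' @param ... named fields, see Details in [load_patient()].
#' @return An object of class `patient_record` (a named list) with derived
#'   members `A_AO`, `A_LVOT` and a reconciled `T`/`HR` pair.
#' @seealso [load_patient()], [write_patient()]
#' @export
patient_record <- function(...) {
  rec <- list(...)
  if (length(rec) == 1L && is.list(rec[[1L]]) && is.null(names(rec)))
    rec <- rec[[1L]]
  validate_patient_record(rec)
}

validate_patient_record <- function(rec) {
  # HR <-> T reconciliation ([[ avoids partial matching of "T" to "T_EJ")
  if (is.null(rec[["T"]]) && !is.null(rec[["HR"]])) rec$T <- 60 / rec[["HR"]]
  if (!is.null(rec[["T"]]) && !is.null(rec[["HR"]])) {
    if (abs(rec[["T"]] - 60 / rec[["HR"]]) > 0.01 * rec[["T"]])
      abort_validation("HR and T are inconsistent by more than 1%")
  }
  if (!is.null(rec[["T"]])) rec$HR <- 60 / rec[["T"]]

  missing <- setdiff(.mandatory_fields, names(rec))
  if (length(missing))
    abort_validation(paste0("missing mandatory field(s): ",
                            paste(missing, collapse = ", ")))
  num <- setdiff(.mandatory_fields, "id")
  for (f in num) {
    v <- rec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      abort_validation(paste0("field ", f, " must be a finite scalar"))
    if (v <= 0) abort_validation(paste0("field ", f, " must be > 0"))
    rec[[f]] <- as.numeric(v)   # JSON integers come back typed as integer
  }
  for (f in .optional_fields)
    if (!is.null(rec[[f]]) && is.numeric(rec[[f]]))
      rec[[f]] <- as.numeric(rec[[f]])

  # mitral orifice: explicit EOA_MV takes precedence over the ellipse
  if (is.null(rec$EOA_MV)) {
    if (is.null(rec$d1) || is.null(rec$d2))
      abort_validation("either EOA_MV or both mitral diameters d1,d2 required")
    rec$EOA_MV <- mitral_area_from_diameters(rec$d1, rec$d2)
  }

  rec$A_AO <- ascending_aorta_area(rec$D_AO)
  rec$A_LVOT <- pi * rec$D_LVOT^2 / 4

  if (rec$T_EJ >= rec$T) abort_validation("T_EJ must be < T")
  if (rec$SBP <= rec$DBP) abort_validation("SBP must be > DBP")
  if (rec$EDV <= rec$ESV) abort_validation("EDV must be > ESV")
  if (rec$EOA_AV >= rec$A_AO)
    abort_validation("EOA_AV must be < ascending aorta area A_AO")
  if (!is.null(rec$EOA_AR) && rec$EOA_AR >= rec$A_LVOT)
    abort_validation("EOA_AR must be < LVOT area A_LVOT")
  for (f in c("EOA_MV", "EOA_AR", "EOA_MR"))
    if (!is.null(rec[[f]]) && rec[[f]] <= 0)
      abort_validation(paste0("field ", f, " must be > 0"))

  structure(rec, class = "patient_record")
}

#' Read / write patient records as JSON
#'
#' Patient records are serialized as flat JSON objects carrying a
#' `schema_version` stamp.  `load_patient()` validates on read: a missing
#' mandatory field raises a schema error naming the field, and any
#' physiological invariant violation (e.g. `SBP <= DBP`, `EOA_AV >= A_AO`)
#' raises a validation error.  The write/load round trip is lossless.
#'
#' @param path file path.
#' @param rec a [patient_record()].
#' @return `load_patient()` returns a validated `patient_record`;
#'   `write_patient()` returns `path` invisibly.
#' @export
load_patient <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("no such file: ", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$schema_version <- NULL
  patient_record(x)
}

#' @rdname load_patient
#' @export
write_patient <- function(rec, path) {
  stopifnot(inherits(rec, "patient_record"))
  out <- rec[intersect(c(.mandatory_fields, .optional_fields), names(rec))]
  out <- c(list(schema_version = PATIENT_SCHEMA_VERSION), out)
  # I(17) significant digits guarantees a bit-exact double round trip
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record> id:", x$id, "\n")
  cat(sprintf("  T %.3f s (HR %.1f), T_EJ %.3f s\n", x$T, x$HR, x$T_EJ))
  cat(sprintf("  Forward LVOT-SV %.1f mL, EDV/ESV %.0f/%.0f mL\n",
              x$forward_lvot_sv, x$EDV, x$ESV))
  cat(sprintf("  SBP/DBP %.0f/%.0f mmHg\n", x$SBP, x$DBP))
  cat(sprintf("  EOA_AV %.2f, EOA_MV %.2f cm2; A_AO %.2f, A_LVOT %.2f cm2\n",
              x$EOA_AV, x$EOA_MV, x$A_AO, x$A_LVOT))
  if (!is.null(x$EOA_AR)) cat(sprintf("  EOA_AR %.2f cm2\n", x$EOA_AR))
  if (!is.null(x$EOA_MR)) cat(sprintf("  EOA_MR %.2f cm2\n", x$EOA_MR))
  invisible(x)
}

#' A nominal healthy patient record
#'
#' The baseline configuration used to tune the upper-body resistance split
#' and as a convenient example input: HR 60, normal valve areas, 120/80
#' cuff pressures, forward stroke volume ~75 mL.
#'
#' @param ... fields overriding the defaults.
#' @return A validated [patient_record()].
#' @export
healthy_patient_record <- function(...) {
  defaults <- list(
    id = "healthy-baseline",
    HR = 60, T_EJ = 0.33,
    D_LVOT = 2.2, VTI_LVOT = 19.74,
    D_AO = 3.0, VTI_AO = 37.5,
    EOA_MV = 4.0,
    EDV = 130, ESV = 55,
    SBP = 120, DBP = 80
  )
  over <- list(...)
  defaults[names(over)] <- over
  if (is.null(defaults$forward_lvot_sv))
    defaults$forward_lvot_sv <- forward_lvot_sv(defaults$D_LVOT, defaults$VTI_LVOT)
  if (is.null(defaults$EOA_AV))
    defaults$EOA_AV <- eoa_av_continuity(defaults$forward_lvot_sv, defaults$VTI_AO)
  patient_record(defaults)
}
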