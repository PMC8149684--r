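#' Unit conventions and conversion constants
#'
#' The package works in clinical "mixed" units throughout: pressures in mmHg,
#' volumes in mL, times in s, lengths/areas in cm/cm2.  Resistances are
#' mmHg.s/mL, compliances mL/mmHg, inertances mmHg.s2/mL.  Dynamic-pressure
#' (Bernoulli) and inertial valve terms are evaluated in CGS (dyn/cm2, with
#' blood density in g/mL) and divided by 1333.22 to obtain mmHg.
#'
#' @format `DYN_CM2_PER_MMHG` is the scalar 1333.22 (dyn/cm2 per mmHg);
#'   `J_PER_MMHG_ML` is 1.33322e-4 (joule per mmHg.mL).
#' @name units
NULL

#' @rdname units
#' @export
DYN_CM2_PER_MMHG <- 1333.22

#' @rdname units
#' @export
J_PER_MMHG_ML <- 1.33322e-4

# blood density, g/mL (1050 kg/m3)
RHO_BLOOD <- 1.05

# condition helpers -----------------------------------------------------

abort_validation <- function(msg, call. = FALSE) {
  cnd <- structure(
    class = c("lpm_validation_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cnd)
}

abort_domain <- function(msg) {
  cnd <- structure(
    class = c("lpm_domain_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cnd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# seeded RNG scope that restores the caller's random state on exit
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
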