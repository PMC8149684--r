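#' Lame constants from Young's modulus and Poisson's ratio
#'
#' `lambda = E nu / ((1+nu)(1-2nu))`, `mu = E / (2(1+nu))`.
#' The incompressible limit `nu = 0.5` is rejected.
#'
#' @param young_E Young's modulus, Pa.
#' @param poisson_nu Poisson's ratio in (-1, 0.5).
#' @return Named list `lambda`, `mu` (Pa).
#' @export
lame_constants <- function(young_E, poisson_nu) {
  if (young_E <= 0) abort_domain("young_E must be > 0")
  if (poisson_nu <= -1 || poisson_nu >= 0.5)
    abort_domain("poisson_nu must lie in (-1, 0.5); 0.5 is the incompressible limit")
  list(lambda = young_E * poisson_nu / ((1 + poisson_nu) * (1 - 2 * poisson_nu)),
       mu = young_E / (2 * (1 + poisson_nu)))
}

#' @rdname lame_constants
#' @param lambda,mu Lame constants, Pa.
#' @export
young_poisson_from_lame <- function(lambda, mu) {
  if (mu <= 0) abort_domain("mu must be > 0")
  list(young_E = mu * (3 * lambda + 2 * mu) / (lambda + mu),
       poisson_nu = lambda / (2 * (lambda + mu)))
}

.check_tensor3 <- function(A, name = "tensor") {
  if (!is.matrix(A) || !all(dim(A) == c(3, 3)) || any(!is.finite(A)))
    abort_domain(paste0(name, " must be a finite 3x3 matrix"))
  invisible(A)
}

#' Green-Lagrange strain from the deformation gradient
#'
#' With the convention `F = I + t(grad u)`, the strain is
#' `E = (grad u + t(grad u) + grad u . t(grad u)) / 2`, equivalently
#' `E = (t(F) F - I) / 2`: symmetric, zero for rigid rotations
#' (frame-indifferent).  Note that many texts use the transposed
#' displacement-gradient convention; the formula `E = (t(F)F - I)/2` is
#' invariant to that choice.
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @return 3x3 symmetric strain tensor.
#' @export
green_lagrange_strain <- function(F) {
  .check_tensor3(F, "F")
  if (det(F) <= 0) abort_domain("inverted element: det(F) must be > 0")
  (crossprod(F) - diag(3)) / 2
}

#' St. Venant-Kirchhoff second Piola-Kirchhoff stress
#'
#' Isotropic Hooke law in the Green-Lagrange strain:
#' `Sigma = lambda tr(E) I + 2 mu E`.
#'
#' @param Estrain 3x3 symmetric Green-Lagrange strain.
#' @param lambda,mu Lame constants, Pa.
#' @return 3x3 symmetric stress tensor, Pa.
#' @export
svk_second_piola <- function(Estrain, lambda, mu) {
  .check_tensor3(Estrain, "Estrain")
  if (max(abs(Estrain - t(Estrain))) > 1e-12 * max(1, max(abs(Estrain))))
    abort_domain("Estrain must be symmetric")
  lambda * sum(diag(Estrain)) * diag(3) + 2 * mu * Estrain
}

#' Push-forward of the second Piola-Kirchhoff stress to Cauchy stress
#'
#' `sigma = F Sigma t(F) / det(F)`; symmetric whenever `Sigma` is, and
#' objective: a rotation `F = R` gives `sigma = R Sigma t(R)` with
#' invariants preserved.
#'
#' @param F 3x3 deformation gradient, `det(F) > 0`.
#' @param Sigma 3x3 second Piola-Kirchhoff stress, Pa.
#' @return 3x3 Cauchy stress, Pa.
#' @export
cauchy_from_second_piola <- function(F, Sigma) {
  .check_tensor3(F, "F"); .check_tensor3(Sigma, "Sigma")
  J <- det(F)
  if (J <= 0) abort_domain("det(F) must be > 0")
  F %*% Sigma %*% t(F) / J
}

#' Robin pressure boundary coefficients
#'
#' The added-mass Robin condition for interface pressure,
#' `p + (rho_s h_s / rho_f) dp/dn = 0`, uses an effective wall thickness
#' built from the dilatational wave speed:
#' `h_s = dt sqrt((lambda + 2 mu)/rho_s)`.
#'
#' @param dt time-step size, s.
#' @param lambda,mu solid Lame constants, Pa.
#' @param rho_s solid density, kg/m3 (default 1050).
#' @param rho_fluid fluid density, kg/m3 (default 1060).
#' @return Named list `h_s` (m) and `alpha = rho_s h_s / rho_fluid` (m).
#' @export
robin_coefficients <- function(dt, lambda, mu, rho_s = 1050, rho_fluid = 1060) {
  if (dt <= 0 || rho_s <= 0 || rho_fluid <= 0 || lambda + 2 * mu <= 0)
    abort_domain("need dt > 0, densities > 0 and lambda + 2 mu > 0")
  h_s <- dt * sqrt((lambda + 2 * mu) / rho_s)
  list(h_s = h_s, alpha = rho_s * h_s / rho_fluid)
}

# Plane-stress equibiaxial SVK modulus: Sigma_hoop = Cps * E_hoop
.plane_stress_biaxial_modulus <- function(lambda, mu) {
  2 * mu * (3 * lambda + 2 * mu) / (lambda + 2 * mu)
}

#' Quasi-static diastolic pressure of a spherical SVK shell
#'
#' The reduced compliant-chamber surrogate used for Young's-modulus
#' calibration: a thin-walled sphere of unloaded volume `V0` and wall
#' thickness `h`, loaded by internal pressure.  With equibiaxial stretch
#' `lam = (V/V0)^(1/3)`, the membrane Green strain is `(lam^2-1)/2`, the
#' plane-stress SVK hoop stress follows, and the Laplace relation gives
#'
#' `P(V) = (h Cps / R0) (lam^2 - 1) / lam`   (Pa; returned in mmHg)
#'
#' where `Cps` is the plane-stress biaxial modulus and `R0` the unloaded
#' radius.  `P` is linear in Young's modulus and zero at `V = V0` for all
#' moduli, and stiffer walls give uniformly lower volume at a given
#' pressure.
#'
#' @param V chamber volume(s), mL.
#' @param young_E Young's modulus, Pa.
#' @param chamber list with `unloaded_volume` (mL) and `wall_thickness`
#'   (cm).
#' @param poisson_nu Poisson's ratio (default 0.4).
#' @return Pressure(s), mmHg.
#' @export
shell_pressure <- function(V, young_E, chamber, poisson_nu = 0.4) {
  if (any(V < chamber$unloaded_volume))
    abort_domain("V must be >= the unloaded volume")
  lm <- lame_constants(young_E, poisson_nu)
  Cps <- .plane_stress_biaxial_modulus(lm$lambda, lm$mu)
  R0 <- (3 * chamber$unloaded_volume / (4 * pi))^(1 / 3)  # cm
  lam <- (V / chamber$unloaded_volume)^(1 / 3)
  P_pa <- chamber$wall_thickness * Cps / R0 * (lam^2 - 1) / lam
  P_pa / 133.322  # Pa -> mmHg
}

#' Calibrate Young's modulus against a diastolic P-V limb
#'
#' Reproduces the material-property interpolation step: candidate moduli
#' generate surrogate-chamber diastolic P-V curves, and the modulus whose
#' curve best matches the target limb (least-squares in pressure) is
#' returned.  Because the shell pressure is linear in the modulus, the
#' optimum is found in closed form and then verified against the bracket;
#' a bracket not containing a sign change of the mismatch is an error.
#'
#' @param target_V,target_P the diastolic limb: volumes (mL, monotone
#'   increasing) and pressures (mmHg).
#' @param chamber surrogate geometry, see [shell_pressure()].
#' @param poisson_nu Poisson's ratio (default 0.4).
#' @param bracket Young's-modulus search interval, Pa.
#' @return List with `young_E` (Pa), `rmse` (mmHg) and the fitted limb
#'   `P_hat`.
#' @export
calibrate_young_modulus <- function(target_V, target_P, chamber,
                                    poisson_nu = 0.4,
                                    bracket = c(1e3, 1e7)) {
  if (length(target_V) != length(target_P) || length(target_V) < 2)
    abort_domain("target limb needs >= 2 matched (V, P) samples")
  if (any(diff(target_V) <= 0))
    abort_domain("target diastolic limb must be monotone in V")
  g <- shell_pressure(target_V, 1, chamber, poisson_nu)  # per unit modulus
  mismatch <- function(E) sum((E * g - target_P) * g)
  mlo <- mismatch(bracket[1]); mhi <- mismatch(bracket[2])
  if (sign(mlo) == sign(mhi) && mlo != 0)
    abort_domain(sprintf(
      "no bracket: mismatch gradient has sign %+d at E=%.3g and %+d at E=%.3g",
      sign(mlo), bracket[1], sign(mhi), bracket[2]))
  E_hat <- sum(target_P * g) / sum(g^2)  # closed-form least squares
  E_hat <- min(max(E_hat, bracket[1]), bracket[2])
  P_hat <- E_hat * g
  list(young_E = E_hat,
       rmse = sqrt(mean((P_hat - target_P)^2)),
       P_hat = P_hat)
}
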