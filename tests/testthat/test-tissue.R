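test_that("Lame constants match hand values and invert exactly", {
  lm <- lame_constants(1e5, 0.3)
  expect_equal(lm$lambda, 57692.3077, tolerance = 1e-8)
  expect_equal(lm$mu, 38461.5385, tolerance = 1e-8)
  lm0 <- lame_constants(1e5, 0)
  expect_equal(lm0$lambda, 0)
  expect_equal(lm0$mu, 5e4)
  back <- young_poisson_from_lame(lm$lambda, lm$mu)
  expect_equal(back$young_E, 1e5, tolerance = 1e-12)
  expect_equal(back$poisson_nu, 0.3, tolerance = 1e-12)
  expect_error(lame_constants(1e5, 0.5), class = "lpm_domain_error")
})

test_that("Green-Lagrange strain: stretch, rotation objectivity, inversion guard", {
  expect_equal(green_lagrange_strain(diag(3)), matrix(0, 3, 3))
  Fd <- diag(c(1.1, 1, 1))
  Es <- green_lagrange_strain(Fd)
  expect_equal(Es[1, 1], (1.1^2 - 1) / 2, tolerance = 1e-15)
  expect_equal(Es[2, 2], 0); expect_equal(Es[1, 2], 0)
  withr::with_seed(3, {
    for (i in 1:100) {
      R <- random_rotation()
      expect_lt(max(abs(green_lagrange_strain(R))), 1e-12)
      # objectivity: a superposed rotation leaves the strain unchanged
      F1 <- diag(3) + matrix(stats::rnorm(9, sd = 0.05), 3)
      if (det(F1) <= 0) next
      expect_equal(green_lagrange_strain(R %*% F1),
                   green_lagrange_strain(F1), tolerance = 1e-12)
    }
  })
  expect_error(green_lagrange_strain(diag(c(-1, 1, 1))),
               class = "lpm_domain_error")
})

test_that("SVK stress closed forms: hydrostatic, pure shear", {
  lam <- 5e4; mu <- 3e4
  expect_equal(svk_second_piola(matrix(0, 3, 3), lam, mu), matrix(0, 3, 3))
  eps <- 0.01
  S <- svk_second_piola(eps * diag(3), lam, mu)
  expect_equal(S, (3 * lam + 2 * mu) * eps * diag(3), tolerance = 1e-12)
  gam <- 0.02
  Esh <- matrix(0, 3, 3); Esh[1, 2] <- Esh[2, 1] <- gam / 2
  Ssh <- svk_second_piola(Esh, lam, mu)
  expect_equal(Ssh[1, 2], mu * gam, tolerance = 1e-12)
  expect_equal(sum(diag(Ssh)), 0)
  expect_error(svk_second_piola(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3),
                                lam, mu),
               class = "lpm_domain_error")
})

test_that("Cauchy push-forward: identity, rotation objectivity, uniform scaling", {
  S <- matrix(c(3, 1, 0, 1, 2, 0, 0, 0, 1), 3)
  expect_equal(cauchy_from_second_piola(diag(3), S), S)
  withr::with_seed(8, {
    R <- random_rotation()
    sig <- cauchy_from_second_piola(R, S)
    expect_equal(sig, R %*% S %*% t(R), tolerance = 1e-12)
    expect_equal(sum(diag(sig)), sum(diag(S)), tolerance = 1e-12)
    expect_equal(det(sig), det(S), tolerance = 1e-9)
  })
  cF <- 1.3
  expect_equal(cauchy_from_second_piola(cF * diag(3), S), S / cF,
               tolerance = 1e-12)
})

test_that("small-strain SVK stress matches linear elasticity", {
  lam <- 6e4; mu <- 2.5e4
  withr::with_seed(21, {
    G <- matrix(stats::rnorm(9, sd = 1e-4), 3)   # displacement gradient
    Fdef <- diag(3) + t(G)
    E_nl <- green_lagrange_strain(Fdef)
    E_lin <- (G + t(G)) / 2
    S_nl <- svk_second_piola(E_nl, lam, mu)
    S_lin <- lam * sum(diag(E_lin)) * diag(3) + 2 * mu * E_lin
    expect_lt(max(abs(S_nl - S_lin)) / max(abs(S_lin)), 1e-3)
  })
})

test_that("stress power is non-negative along proportional loading", {
  lam <- 6e4; mu <- 2.5e4
  E0 <- matrix(c(0.02, 0.005, 0, 0.005, -0.01, 0, 0, 0, 0.015), 3)
  for (s in seq(0.1, 1, by = 0.1)) {
    S <- svk_second_piola(s * E0, lam, mu)
    expect_gte(sum(S * E0), 0)   # Sigma : dE along the path
  }
})

test_that("Robin pressure-BC coefficients", {
  rb <- robin_coefficients(1e-4, lambda = 5e5, mu = 2.5e5, rho_s = 1000,
                           rho_fluid = 1000)
  expect_equal(rb$h_s, 1e-4 * sqrt(1e6 / 1000), tolerance = 1e-12)
  expect_equal(rb$h_s, 3.1623e-3, tolerance = 1e-4)
  # dt -> 0 gives the pure-Dirichlet limit
  expect_lt(robin_coefficients(1e-9, 5e5, 2.5e5)$h_s, 1e-7)
  # alpha scales linearly in rho_s... at fixed h_s the density enters
  # both h_s (inverse sqrt) and alpha (linear)
  r1 <- robin_coefficients(1e-4, 5e5, 2.5e5, rho_s = 1000, rho_fluid = 1000)
  r2 <- robin_coefficients(1e-4, 5e5, 2.5e5, rho_s = 1000, rho_fluid = 2000)
  expect_equal(r2$alpha, r1$alpha / 2, tolerance = 1e-12)
  expect_error(robin_coefficients(-1, 5e5, 2.5e5), class = "lpm_domain_error")
})

test_that("spherical-shell surrogate: reference state, stiffness monotonicity", {
  chamber <- list(unloaded_volume = 60, wall_thickness = 1)
  # zero-pressure point maps to the unloaded volume for any modulus
  for (E in c(2e4, 6e4, 2e5))
    expect_equal(shell_pressure(60, E, chamber), 0)
  # stiffer walls give uniformly higher pressure at each volume
  V <- seq(65, 120, by = 5)
  p1 <- shell_pressure(V, 4e4, chamber)
  p2 <- shell_pressure(V, 8e4, chamber)
  expect_true(all(p2 > p1))
  expect_equal(p2, 2 * p1, tolerance = 1e-12)  # linear in the modulus
})

test_that("Young's-modulus calibration round trip recovers the truth", {
  chamber <- list(unloaded_volume = 60, wall_thickness = 1)
  E_true <- 6e4   # 60 kPa
  V <- seq(60, 130, by = 5)
  P <- shell_pressure(V, E_true, chamber)
  cal <- calibrate_young_modulus(V, P, chamber)
  expect_lt(abs(cal$young_E - E_true) / E_true, 0.02)
  expect_lt(cal$rmse, 1e-9)
  # a bracket that excludes the optimum on both sides errors informatively
  expect_error(calibrate_young_modulus(V, P, chamber, bracket = c(1e3, 2e3)),
               class = "lpm_domain_error")
})
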