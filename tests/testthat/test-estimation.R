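test_that("total systemic resistance uses the DBP + PP/3 mean estimator", {
  expect_equal(total_systemic_resistance(120, 80, 83.33), 1.120045,
               tolerance = 1e-6)
  expect_equal(total_systemic_resistance(100, 100, 50), 2)  # pulseless limit
  # homogeneity: halving CO doubles TSR
  expect_equal(total_systemic_resistance(120, 80, 41.665),
               2 * total_systemic_resistance(120, 80, 83.33))
  expect_error(total_systemic_resistance(120, 80, 0),
               class = "lpm_domain_error")
})

test_that("R_SA seed subtracts the fixed series resistances, with guarded fallback", {
  p <- circulation_params()
  expect_equal(initial_rsa(1.12, p), 1.12 - 0.15)
  expect_warning(r <- initial_rsa(0.10, p), "falling back")
  expect_equal(r, 0.8)
  expect_gt(initial_rsa(0.16, p), 0)
})

test_that("two-stage order is enforced", {
  rec <- healthy_patient_record()
  expect_error(fit_systemic(rec, circulation_params()),
               class = "lpm_domain_error")
})

test_that("stage 1 returns the analytic seed when it already matches", {
  fx <- fitted_synth_patient()
  rec <- fx$cohort[[1]]$record
  # the generator's record SV is itself a steady-model output, so the
  # analytic seed pi*SV/(2 t_ee) reproduces it to well under 0.1%
  p <- fit_qmpv(rec, circulation_params(R_ub = tuned_r_ub()))
  expect_true(attr(p, "sv_converged"))
  expect_lte(attr(p, "n_evals"), 2)
  expect_equal(p$Q_MPV, pi * rec$forward_lvot_sv / (2 * rec$T_EJ),
               tolerance = 1e-9)
})

test_that("model stroke volume is monotone increasing in Q_MPV", {
  rec <- healthy_patient_record()
  valves <- build_patient_valves(rec)
  p <- circulation_params(R_ub = tuned_r_ub())
  qs <- seq(250, 450, length.out = 5)
  svs <- vapply(qs, function(q) {
    p$Q_MPV <- q
    attr(simulate_to_steady(lpm_model(p, valves, rec)), "cycle_volumes")[["AV"]]
  }, 0)
  expect_true(all(diff(svs) > 0))
})

test_that("increasing the aortic compliance alone decreases pulse pressure", {
  rec <- healthy_patient_record()
  valves <- build_patient_valves(rec)
  p <- circulation_params(Q_MPV = pi * rec$forward_lvot_sv / (2 * rec$T_EJ),
                          R_ub = tuned_r_ub())
  pp <- vapply(c(0.5, 1.0, 2.0), function(cao) {
    p$C_ao <- cao
    wf <- simulate_to_steady(lpm_model(p, valves, rec))
    max(wf$P_ao) - min(wf$P_ao)
  }, 0)
  expect_true(all(diff(pp) < 0))
})

test_that("upper-body tuning hits the 15% split and responds monotonically", {
  r_ub <- tuned_r_ub()
  rec <- healthy_patient_record()
  valves <- build_patient_valves(rec)
  frac_at <- function(r) {
    p <- circulation_params(Q_MPV = pi * rec$forward_lvot_sv / (2 * rec$T_EJ),
                            R_ub = r)
    cv <- attr(simulate_to_steady(lpm_model(p, valves, rec)), "cycle_volumes")
    cv[["upper_body"]] / cv[["systemic_out"]]
  }
  f <- frac_at(r_ub)
  expect_gte(f, 0.145); expect_lte(f, 0.155)
  # raising R_ub lowers the fraction
  expect_lt(frac_at(2 * r_ub), f)
  # fraction is insensitive to the source amplitude (< 2% drift at +/-20%)
  p <- circulation_params(Q_MPV = pi * rec$forward_lvot_sv / (2 * rec$T_EJ),
                          R_ub = r_ub)
  fr <- vapply(c(0.8, 1.2), function(s) {
    p$Q_MPV <- p$Q_MPV * s
    cv <- attr(simulate_to_steady(lpm_model(p, valves, rec)), "cycle_volumes")
    cv[["upper_body"]] / cv[["systemic_out"]]
  }, 0)
  expect_lt(max(abs(fr - f) / f), 0.02)
})

test_that("end-to-end fit recovers a noise-free synthetic patient", {
  fx <- fitted_synth_patient()
  ft <- fx$fit
  rec <- fx$cohort[[1]]$record
  truth <- fx$cohort[[1]]$truth
  expect_true(ft$converged)
  expect_lt(abs(ft$sv_error), 0.01 * rec$forward_lvot_sv)
  expect_lt(abs(ft$sbp_error), 1)
  expect_lt(abs(ft$dbp_error), 1)
  expect_lt(abs(ft$params$Q_MPV - truth$Q_MPV) / truth$Q_MPV, 0.02)
  # EDV anchoring reproduces the measured loop position
  expect_equal(attr(ft$waveforms, "EDV"), rec$EDV, tolerance = 1e-3)
  # objective decreases monotonically across accepted optimizer iterates,
  # up to the steady-solver's ~1e-4 mmHg reproducibility floor (~1e-4
  # mmHg^2 on the deviance once residuals are sub-millimetre-of-mercury)
  trace <- attr(ft$params, "rss_trace")
  expect_gte(length(trace), 1)
  expect_true(all(diff(trace) <= 1e-4))
  expect_lt(trace[length(trace)], trace[1])
})

test_that("the fit is deterministic: identical inputs give identical results", {
  fx <- fitted_synth_patient()
  rec <- fx$cohort[[1]]$record
  f1 <- fit_patient(rec, R_ub = tuned_r_ub())
  f2 <- fit_patient(rec, R_ub = tuned_r_ub())
  expect_identical(f1$params$Q_MPV, f2$params$Q_MPV)
  expect_identical(f1$params$C_ao, f2$params$C_ao)
  expect_identical(f1$sv_error, f2$sv_error)
  expect_identical(as.data.frame(f1$waveforms), as.data.frame(f2$waveforms))
})

test_that("a record missing its pressures fails before any simulation", {
  expect_error(healthy_patient_record(SBP = NULL),
               class = "lpm_validation_error")
})
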