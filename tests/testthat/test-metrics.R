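test_that("ejection fraction and its reduced-EF classification", {
  expect_equal(ejection_fraction(120, 80), 1 / 3, tolerance = 1e-12)
  expect_equal(ejection_fraction(100, 0), 1)
  expect_true(ef_reduced(0.40))
  expect_false(ef_reduced(0.41))
  expect_error(ejection_fraction(80, 80), class = "lpm_domain_error")
})

test_that("stroke work: rectangle loop, degenerate loop, orientation invariance", {
  # rectangle 100 mmHg x 70 mL = 7000 mmHg.mL
  P <- c(10, 110, 110, 10); V <- c(50, 50, 120, 120)
  expect_equal(lv_workload(P, V), 7000 * 1.33322e-4, tolerance = 1e-12)
  expect_equal(lv_workload(P, V), 0.9333, tolerance = 1e-4)
  expect_equal(lv_workload(rev(P), rev(V)), lv_workload(P, V))
  expect_equal(lv_workload(c(10, 50, 90), c(60, 60, 60)), 0)  # zero area
  expect_error(lv_workload(1:2, 1:2), class = "lpm_domain_error")
})

test_that("shoelace stroke work agrees with trapezoidal contour integration", {
  th <- seq(0, 2 * pi, length.out = 4001)[-4001]
  P <- 60 + 45 * sin(th) + 5 * sin(2 * th)
  V <- 90 + 35 * cos(th)
  shoelace <- lv_workload(P, V) / 1.33322e-4
  Pc <- c(P, P[1]); Vc <- c(V, V[1])
  trap <- abs(sum(diff(Vc) * (head(Pc, -1) + tail(Pc, -1)) / 2))
  expect_equal(shoelace, trap, tolerance = 1e-9)
})

test_that("SAC estimator and low-compliance flag", {
  expect_equal(systemic_arterial_compliance(60, 120, 80), 1.5)
  expect_equal(systemic_arterial_compliance(60, 160, 80),
               systemic_arterial_compliance(60, 120, 80) / 2)
  expect_true(sac_low(0.9)); expect_false(sac_low(1.4))
  expect_error(systemic_arterial_compliance(60, 80, 80),
               class = "lpm_domain_error")
})

test_that("E/A detection on a constructed biphasic inflow", {
  T <- 1; t_ee <- 0.3
  t <- seq(0, 1, length.out = 1001)
  # E peak 300 mL/s at 0.45 s, A peak 150 mL/s at 0.85 s
  q <- 300 * exp(-((t - 0.45) / 0.05)^2) + 150 * exp(-((t - 0.85) / 0.04)^2)
  waves <- data.frame(t = t, Q_MV = q)
  ea <- ea_ratio(waves, eoa_mv = 4, t_ee = t_ee, T = T)
  expect_true(ea$defined)
  expect_equal(ea$E_peak, 75, tolerance = 1e-2)
  expect_equal(ea$A_peak, 37.5, tolerance = 1e-2)
  expect_equal(ea$ratio, 2.0, tolerance = 1e-2)
  expect_true(ea$normal)
  # monophasic inflow: undefined ratio flag
  mono <- data.frame(t = t, Q_MV = 300 * exp(-((t - 0.5) / 0.08)^2))
  ea1 <- ea_ratio(mono, 4, t_ee = t_ee, T = T)
  expect_false(ea1$defined)
  expect_true(is.na(ea1$ratio))
})

test_that("TAWSS: constant and rectified-sine closed forms, band classifier", {
  t <- seq(0, 0.8, length.out = 2001)
  expect_equal(tawss(t, rep(0.5, length(t)), 0.8), 0.5, tolerance = 1e-12)
  A <- 0.9
  expect_equal(tawss(t, abs(A * sin(2 * pi * t / 0.8)), 0.8), 2 * A / pi,
               tolerance = 1e-6)
  expect_true(tawss_normal(0.5)); expect_false(tawss_normal(1.5))
  expect_error(tawss(c(-0.1, 0.5), c(1, 1), 0.8), class = "lpm_domain_error")
})

test_that("vortex sphericity index and threshold", {
  si <- sphericity_index(3, 2)
  expect_equal(si$si, 1.5); expect_false(si$normal)
  expect_equal(sphericity_index(2, 2)$si, 1)
  expect_true(sphericity_index(5, 2)$normal)
  # scale invariance
  expect_equal(sphericity_index(6, 4)$si, si$si)
  expect_error(sphericity_index(0, 1), class = "lpm_domain_error")
})

test_that("pressure summaries extract phase-restricted extrema exactly", {
  t <- seq(0, 1, length.out = 1001)
  t_ee <- 0.3
  waves <- data.frame(
    t = t,
    P_LV = 100 * sin(pi * t / 0.45)^2,
    P_LA = 12 + 6 * sin(2 * pi * t),
    P_ao = 80 + 40 * exp(-((t - 0.2) / 0.1)^2),
    Q_MV = pmax(0, 250 * sin(pi * (t - 0.35) / 0.6)))
  ps <- pressure_summaries(waves, t_ee = t_ee, T = 1)
  expect_equal(ps$max_P_LV, max(waves$P_LV))
  expect_equal(ps$max_P_ao, max(waves$P_ao))
  expect_equal(ps$min_P_ao, min(waves$P_ao))
  expect_gte(ps$max_transmitral_PG, 0)
  expect_gte(ps$max_AV_PG, 0)
  expect_equal(ps$max_transmitral_PG,
               max((waves$P_LA - waves$P_LV)[t > t_ee]))
  expect_error(pressure_summaries(waves[0, ], t_ee = t_ee, T = 1),
               class = "lpm_domain_error")
})

test_that("metrics are pure functions of the waveform set", {
  wf <- healthy_waveforms()
  rec <- healthy_patient_record()
  m1 <- hemodynamic_metrics(wf, rec)
  m2 <- hemodynamic_metrics(wf, rec)
  expect_identical(m1, m2)
  expect_gt(m1$EF, 0); expect_lt(m1$EF, 1)
  expect_gt(m1$lv_workload_J, 0)
})
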