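# shared fixtures; everything is generated in code at test time

# memoized upper-body tuning (one steady-solve family per test run)
.fixture_cache <- new.env(parent = emptyenv())

tuned_r_ub <- function() {
  if (is.null(.fixture_cache$r_ub))
    .fixture_cache$r_ub <- tune_upper_body()
  .fixture_cache$r_ub
}

# a healthy steady solve, computed once
healthy_waveforms <- function() {
  if (is.null(.fixture_cache$wf)) {
    rec <- healthy_patient_record()
    p <- circulation_params(Q_MPV = pi * rec$forward_lvot_sv / (2 * rec$T_EJ),
                            R_ub = tuned_r_ub())
    .fixture_cache$wf <- simulate_to_steady(
      lpm_model(p, build_patient_valves(rec), rec))
  }
  .fixture_cache$wf
}

# a single noise-free synthetic patient with known truth, fitted once
fitted_synth_patient <- function() {
  if (is.null(.fixture_cache$fit1)) {
    coh <- generate_cohort(synth_config(seed = 42, n = 1,
                                        include_regurgitation = 0),
                           R_ub = tuned_r_ub())
    ft <- fit_patient(coh[[1]]$record, R_ub = tuned_r_ub())
    .fixture_cache$fit1 <- list(cohort = coh, fit = ft)
  }
  .fixture_cache$fit1
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
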