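test_that("free chloride accounts for salt stoichiometry", {
  sols <- load_fixture_solutions()
  expect_equal(free_chloride(sols$acsf), 133.5)
  expect_equal(free_chloride(sols$pipette_cscl), 152)
  glucose_only <- solution_recipe("sham", c(glucose = 25))
  expect_equal(free_chloride(glucose_only), 0)
  expect_error(solution_recipe("bad", c(XyCl9 = 10)), "XyCl9")
})

test_that("Nernst potential and concentration are exact inverses and monotone", {
  expect_equal(nernst_potential(133.5, 133.5, 29), 0)
  expect_equal(nernst_concentration(0, 87.3, 31), 87.3)
  e <- seq(-80, 20, by = 7.3)
  round_trip <- nernst_potential(nernst_concentration(e, 133.5, 29), 133.5, 29)
  expect_lt(max(abs(round_trip - e)), 1e-9)
  cl <- nernst_concentration(e, 133.5, 29)
  expect_true(all(diff(cl) > 0))  # monotone in E_rev
  expect_error(nernst_concentration(-25, -1), "positive")
  expect_error(nernst_potential(0, 10), "positive")
})

test_that("high-chloride pipette solution predicts a near-zero reversal potential", {
  sols <- load_fixture_solutions()
  e <- nernst_potential(free_chloride(sols$pipette_cscl),
                        free_chloride(sols$acsf), 29)
  expect_equal(e, 3.4, tolerance = 0.02)
  # within one s.e.m. of the measured -1.4 +/- 5.2 mV whole-cell value
  expect_lt(abs(e - (-1.4)), 5.2)
})

test_that("inferred chloride is robust across the 28-30 C bath range", {
  cl <- vapply(c(28, 29, 30), function(tc) {
    nernst_concentration(-25, 133.5, tc)
  }, numeric(1))
  expect_true(all(abs(cl - 51) <= 0.3 + abs(51.1 - 51)))
  expect_lt(max(cl) - min(cl), 0.6)
})

test_that("baseline statistics and response amplitude honour their windows", {
  tr <- sweep_trace(seq(0, 100, 0.5), rep(3.25, 201), stim_onset_ms = 50)
  bs <- baseline_stats(tr)
  expect_equal(bs$mean_pA, 3.25)
  expect_equal(bs$sd_pA, 0)
  expect_equal(response_amplitude(tr), 0)
  set.seed(2)
  noisy <- sweep_trace(seq(0, 500, 0.1), rnorm(5001, 0, 2),
                       stim_onset_ms = 400)
  expect_equal(baseline_stats(noisy)$sd_pA, 2, tolerance = 0.05)
  expect_error(sweep_trace(seq(0, 10, 0.5), rep(0, 21), stim_onset_ms = 5,
                           baseline_window = c(-5, 2)),
               "inside the trace")
  # amplitude of an average equals the average of aligned amplitudes
  t1 <- sim_evoked_trace(trace_sim_params(amplitude_pA = -60, noise_sd_pA = 0))
  t2 <- sim_evoked_trace(trace_sim_params(amplitude_pA = -120, noise_sd_pA = 0))
  avg <- t1
  avg$current_pA <- (t1$current_pA + t2$current_pA) / 2
  expect_equal(response_amplitude(avg),
               (response_amplitude(t1) + response_amplitude(t2)) / 2,
               tolerance = 1e-9)
})

test_that("10-90% rise time is analytic on a ramp and matches the kernel oracle", {
  t <- seq(0, 200, 0.1)
  cur <- rep(0, length(t))
  ramp <- t >= 60 & t <= 70
  cur[ramp] <- -(t[ramp] - 60) * 10  # 0 to -100 pA over 10 ms
  cur[t > 70] <- -100
  tr <- sweep_trace(t, cur, stim_onset_ms = 50, baseline_window = c(0, 50))
  expect_equal(rise_time_10_90(tr, smooth_ms = 0), 8.0, tolerance = 1e-6)
  # noiseless difference-of-exponentials vs dense-grid root-finding oracle
  p <- trace_sim_params(rise_tau_ms = 5, decay_tau_ms = 100, noise_sd_pA = 0)
  tr2 <- sim_evoked_trace(p)
  oracle <- psc_rise_time(5, 100)
  expect_lt(abs(rise_time_10_90(tr2) - oracle), tr2$sample_period_ms)
  # flat trace is a non-responder
  flat <- sweep_trace(seq(0, 100, 0.5), rep(0, 201), stim_onset_ms = 50)
  expect_error(rise_time_10_90(flat), "non-responder")
})

test_that("monoexponential decay fit is exact on a pure exponential", {
  tr <- pure_exponential_trace(tau_ms = 100)
  fit <- fit_monoexp_decay(tr)
  expect_lt(abs(fit$tau_ms - 100), 0.1)
  expect_lt(fit$rmse, 1e-6)
  # pure noise cannot be fit
  set.seed(4)
  noise <- sweep_trace(seq(0, 600, 0.1), rnorm(6001, 0, 3),
                       stim_onset_ms = 50)
  expect_error(fit_monoexp_decay(noise), "non-responder|failed|outside")
})

test_that("kinetics operators recover generator ground truth at 5% noise", {
  p <- trace_sim_params(noise_sd_pA = 5, seed = 42)
  tr <- sim_evoked_trace(p)
  true_rise <- psc_rise_time(p$rise_tau_ms, p$decay_tau_ms)
  k <- kinetics_summary(tr)
  expect_lt(abs(k$decay_tau_ms - p$decay_tau_ms) / p$decay_tau_ms, 0.05)
  expect_lt(abs(k$rise_time_ms - true_rise) / true_rise, 0.10)
  expect_lt(abs(k$latency_ms - p$latency_ms) / p$latency_ms, 0.15)
  expect_lt(abs(k$amplitude_pA - p$amplitude_pA) / abs(p$amplitude_pA), 0.20)
})

test_that("latency handles zero delay and never-crossing traces", {
  tr0 <- sim_evoked_trace(trace_sim_params(latency_ms = 0, noise_sd_pA = 0))
  expect_lt(synaptic_latency(tr0), tr0$sample_period_ms + 1e-9)
  set.seed(6)
  quiet <- sweep_trace(seq(0, 100, 0.1), rnorm(1001, 0, 1),
                       stim_onset_ms = 50)
  expect_error(synaptic_latency(quiet, k_sd = 6), "non-responder")
})

test_that("reversal potential comes from the I-V x-intercept", {
  iv <- data.frame(holding_mV = c(-70, 30), amplitude_pA = c(-45, 55))
  fit <- reversal_from_iv(iv)
  expect_equal(fit$e_rev_mV, -25)
  expect_equal(fit$slope_nS, 1)
  expect_equal(fit$intercept_pA, 25)
  flat <- data.frame(holding_mV = c(-70, 0, 30), amplitude_pA = c(0, 0, 0))
  expect_error(reversal_from_iv(flat), "undefined reversal")
  expect_error(reversal_from_iv(data.frame(holding_mV = c(1, 1),
                                           amplitude_pA = c(0, 5))),
               "distinct")
  # chloride inference is invariant to current unit rescaling (pA -> nA)
  iv_nA <- transform(iv, amplitude_pA = amplitude_pA / 1000)
  expect_equal(reversal_from_iv(iv_nA)$e_rev_mV, -25, tolerance = 1e-9)
})

test_that("noisy I-V series recover the true reversal potential on average", {
  e_hat <- vapply(1:1000, function(s) {
    iv <- sim_iv_series(iv_sim_params(e_rev_true_mV = -25, noise_sd_pA = 5,
                                      seed = s))
    reversal_from_iv(iv)$e_rev_mV
  }, numeric(1))
  expect_lt(abs(mean(e_hat) - (-25)), 1)
})

test_that("per-cell chloride estimation composes regression, Nernst and recipe", {
  sols <- load_fixture_solutions()
  exact <- data.frame(holding_mV = c(-70, 30),
                      amplitude_pA = c(-70, 30) + 20.7)
  est <- estimate_chloride_per_cell(exact, sols$acsf)
  expect_equal(est$cl_out_mM, 133.5)
  expect_equal(est$mean_cl_in_mM, 60.3, tolerance = 0.01)
  at_zero <- data.frame(holding_mV = c(-70, 30), amplitude_pA = c(-70, 30))
  expect_equal(estimate_chloride_per_cell(at_zero, sols$acsf)$mean_cl_in_mM,
               133.5)
  # cohort of noisy cells recovers truth within its own s.e.m.
  cohort <- lapply(1:30, function(s) {
    sim_iv_series(iv_sim_params(e_rev_true_mV = -25, noise_sd_pA = 5,
                                seed = 100 + s))
  })
  est2 <- estimate_chloride_per_cell(cohort, sols$acsf)
  truth <- nernst_concentration(-25, 133.5, 29)
  expect_lt(abs(est2$mean_cl_in_mM - truth), 2 * est2$sem_cl_in_mM)
})

test_that("responder fractions pool counts and stay between per-model rates", {
  counts <- data.frame(model = c("SU-DIPG-VI", "SU-DIPG-XIII-FL"),
                       responders = c(31, 3), cells = c(78, 7))
  rf <- responder_fraction(counts)
  expect_equal(rf$pooled, 34 / 85)
  expect_equal(round(rf$pooled, 3), 0.4)
  expect_true(rf$pooled >= min(rf$per_model$fraction) &&
                rf$pooled <= max(rf$per_model$fraction))
  zero <- responder_fraction(data.frame(model = "m", responders = 0,
                                        cells = 9))
  expect_equal(zero$pooled, 0)
  expect_error(responder_fraction(data.frame(model = "m", responders = 5,
                                             cells = 4)), "responders")
})
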