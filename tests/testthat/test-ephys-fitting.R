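# Whole-cell analysis pipeline: peaks, reversal, Boltzmann fits, gating
# endpoints, time constants, decay and recovery fits.

test_that("peak extraction respects sign, window and capacitance", {
  t <- seq(0, 10, 0.1)
  zero <- make_trace_set(-40, t, list(rep(0, length(t))))
  expect_equal(extract_peak_currents(zero, smooth_ms = 0)$peak_pA, 0)

  one <- make_trace_set(-40, 5, list(-800), c_m = 10)
  pk <- extract_peak_currents(one, settle_ms = 0, smooth_ms = 0)
  expect_equal(pk$peak_pA, -800)
  expect_equal(pk$density_pA_pF, -80)

  expect_error(extract_peak_currents(zero, window = c(20, 30)), "window")
})

test_that("reversal potential is interpolated from the zero crossing", {
  iv <- data.frame(v_mV = c(15, 20), peak_pA = c(-10, 10))
  expect_equal(estimate_reversal(iv), 17.5)

  cfg <- ephys_sim_config(noise_sd = 0, seed = 5)
  fam <- simulate_activation_family(cfg)
  e <- estimate_reversal(extract_peak_currents(fam, smooth_ms = 0))
  expect_lt(abs(e - cfg$e_na), 5)  # within one voltage step

  all_in <- data.frame(v_mV = c(-40, -20, 0), peak_pA = c(-5, -8, -3))
  expect_error(estimate_reversal(all_in), "reversal")
})

test_that("Boltzmann fit inverts exact and noisy samples", {
  tru <- boltzmann_params(-96.14, 7.17, "inactivation")
  v <- seq(-140, -50, 5)
  pts <- data.frame(v_mV = v, g_over_gmax = boltzmann_curve(v, tru))
  fit <- fit_steady_state_boltzmann(pts, "inactivation")
  expect_equal(fit$vhalf, -96.14, tolerance = 1e-6)
  expect_equal(fit$k, 7.17, tolerance = 1e-6)
  # noise-free residual is numerically zero relative to the signal
  expect_lt(attr(fit, "rss"), 1e-10 * sum(pts$g_over_gmax^2))

  # mean recovery over noisy replicates stays within half a millivolt
  est <- t(sapply(1:30, function(s) {
    set.seed(s)
    y <- boltzmann_curve(v, tru) + rnorm(length(v), 0, 0.02)
    f <- fit_steady_state_boltzmann(data.frame(v_mV = v, g_over_gmax = y),
                                    "inactivation")
    c(f$vhalf, f$k)
  }))
  expect_lt(abs(mean(est[, 1]) + 96.14), 0.5)
  expect_lt(abs(mean(est[, 2]) - 7.17), 0.5)

  flat <- data.frame(v_mV = v, g_over_gmax = rep(0.5, length(v)))
  expect_error(fit_steady_state_boltzmann(flat, "inactivation"), "degenerate")
})

test_that("gating endpoints follow the cube-root construction", {
  act <- boltzmann_params(-42.62, 7.28, "activation")
  inact <- boltzmann_params(-96.14, 7.17, "inactivation")

  ep_mid <- derive_gating_endpoints(act, inact, -120, -42.62)
  expect_equal(ep_mid$m_inf, 0.793700526, tolerance = 1e-8)

  ep <- derive_gating_endpoints(act, inact, -120, -20)
  expect_equal(ep$m_inf, 0.9855201531, tolerance = 1e-8)
  # holding potential saturates the gates
  expect_lt(ep$m0, 0.05)
  expect_gt(ep$h0, 0.95)
})

test_that("m3h time-constant fit inverts noise-free conductance sweeps", {
  act <- boltzmann_params(-42.62, 7.28, "activation")
  inact <- boltzmann_params(-96.14, 7.17, "inactivation")
  e_na <- 19.58
  gmax <- 75
  t <- seq(0, 50, 0.008)
  ep <- derive_gating_endpoints(act, inact, -120, -20)
  s <- hh_state(ep$m0, ep$m_inf, ep$h0, ep$h_inf, tau_m = 0.5, tau_h = 3,
                gmax = gmax, offset = 0.2)
  ts <- make_trace_set(-20, t, list(hh_m3h_timecourse(t, s) * (-20 - e_na)))
  fit <- fit_hh_time_constants(ts, act, inact, gmax = gmax, e_na = e_na)
  expect_true(fit$converged)
  expect_equal(fit$tau_m, 0.5, tolerance = 1e-4)
  expect_equal(fit$tau_h, 3, tolerance = 1e-4)
  expect_equal(fit$offset, 0.2, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10 * sum((hh_m3h_timecourse(t, s))^2))

  # a sweep at the reversal potential is skipped, the pipeline continues
  ts2 <- make_trace_set(c(e_na, -20), t,
                        list(rep(0, length(t)),
                             hh_m3h_timecourse(t, s) * (-20 - e_na)))
  fit2 <- fit_hh_time_constants(ts2, act, inact, gmax = gmax, e_na = e_na)
  expect_identical(fit2$converged[fit2$v_mV == e_na], FALSE)
  expect_identical(fit2$converged[fit2$v_mV == -20], TRUE)
})

test_that("double-exponential decay fit recovers planted components", {
  t <- seq(0, 50, 0.008)
  tru <- decay_params(300, 60, 1, 12)
  fit <- fit_inactivation_double_exp(t, double_exp_decay(t, tru),
                                     settle_ms = 0)
  expect_equal(fit$a1, 300, tolerance = 1e-5)
  expect_equal(fit$a2, 60, tolerance = 1e-5)
  expect_equal(fit$tau1, 1, tolerance = 1e-5)
  expect_equal(fit$tau2, 12, tolerance = 1e-5)
  expect_true(attr(fit, "prefers_double"))

  # a pure mono-exponential leaves no second component to find
  mono <- fit_inactivation_double_exp(t, -400 * exp(-t / 3), settle_ms = 0)
  second <- min(mono$a1, mono$a2)
  expect_true(second < 1e-3 * 400 || !attr(mono, "prefers_double"))

  # noisy recovery of the fast time constant within 15% (median)
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    y <- double_exp_decay(t, tru) + rnorm(length(t), 0, 10)
    f <- fit_inactivation_double_exp(t, y, settle_ms = 0)
    abs(f$tau1 - 1)
  }, 0)
  expect_lt(median(errs), 0.15)
})

test_that("recovery fit returns tau and the exact ln2 half-time", {
  t <- seq(3, 72, 3)
  fit <- fit_recovery_timecourse(data.frame(interval_ms = t,
                                            ratio = recovery_fraction(t, 10)))
  expect_equal(fit$tau_ms, 10, tolerance = 1e-6)
  expect_equal(fit$t_half_ms, 6.931471806, tolerance = 1e-6)
  expect_identical(fit$t_half_ms, fit$tau_ms * log(2))
  expect_error(fit_recovery_timecourse(data.frame(interval_ms = 1:3,
                                                  ratio = c(0.1, 0.2, 0.3))),
               "interval")
})

test_that("voltage-shift correction translates voltages only", {
  tab <- data.frame(v_mV = c(-90.64, -50), tau = c(1.2, 3.4))
  expect_identical(apply_voltage_shift(tab, 0), tab)
  shifted <- apply_voltage_shift(tab, -5.5)
  expect_equal(shifted$v_mV[1], -96.14)
  expect_identical(shifted$tau, tab$tau)
  expect_equal(apply_voltage_shift(apply_voltage_shift(tab, 3.7), -3.7)$v_mV,
               tab$v_mV)
})

test_that("full pipeline recovers gating parameters at recording noise", {
  # 10 cells per replicate at 20 pA noise; medians of the per-replicate
  # cell means must stay within 1 mV (vhalf) and 0.5 mV (k)
  res <- t(sapply(1:50, function(s) {
    cells <- t(sapply(1:10, function(ci) {
      cfg <- ephys_sim_config(noise_sd = 20, seed = s * 1000 + ci)
      a <- analyze_activation_family(simulate_activation_family(cfg))
      c(a$boltzmann$vhalf, a$boltzmann$k, a$e_na, a$gmax)
    }))
    colMeans(cells)
  }))
  med <- apply(res, 2, median)
  h0 <- boltzmann_curve(-120, boltzmann_params(-96.14, 7.17, "inactivation"))
  expect_lt(abs(med[1] - (-42.62)), 1)
  expect_lt(abs(med[2] - 7.28), 0.5)
  expect_lt(abs(med[3] - 19.58), 1)
  expect_lt(abs(med[4] - 75 * h0) / (75 * h0), 0.05)
})

test_that("combined cell analysis keeps the ln2 identity and charge range", {
  cfg <- ephys_sim_config(noise_sd = 5, dt_ms = 0.05, seed = 11)
  fit <- analyze_ephys_cell(simulate_activation_family(cfg),
                            simulate_inactivation_family(cfg),
                            simulate_recovery_family(cfg, tau_rec = 7.64))
  expect_identical(fit$t_half_ms, fit$recovery_tau_ms * log(2))
  expect_equal(fit$recovery_tau_ms, 7.64, tolerance = 0.05)
  expect_gt(fit$z_act, 3)
  expect_lt(fit$z_act, 4)
  expect_equal(fit$inact$vhalf, -96.14, tolerance = 0.5)
})
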