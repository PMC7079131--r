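# Closed-form gating model components.

test_that("Boltzmann curve hits its landmarks in both senses", {
  act <- boltzmann_params(-42.62, 7.28, "activation")
  inact <- boltzmann_params(-96.14, 7.17, "inactivation")

  expect_equal(boltzmann_curve(-42.62, act), 0.5)
  expect_equal(boltzmann_curve(-96.14, inact), 0.5)
  # unit-slope displacement on the inactivation side
  expect_equal(boltzmann_curve(-96.14 + 7.17, inact), 1 / (1 + exp(1)))
  # frozen direct-arithmetic value
  expect_equal(boltzmann_curve(-20, act), 0.9571864212, tolerance = 1e-8)

  # activation increases, inactivation decreases with voltage
  v <- seq(-140, 40, 5)
  expect_true(all(diff(boltzmann_curve(v, act)) > 0))
  expect_true(all(diff(boltzmann_curve(v, inact)) < 0))

  # saturation within 1e-4 at vhalf +/- 10k for arbitrary parameters
  for (p in list(act, inact, boltzmann_params(0, 3, "activation"))) {
    lims <- sort(boltzmann_curve(p$vhalf + c(-10, 10) * p$k, p))
    expect_lt(lims[1], 1e-4)
    expect_gt(lims[2], 1 - 1e-4)
  }

  expect_error(boltzmann_params(-40, -2), "k")
})

test_that("Nernst prediction matches the sodium-gradient arithmetic", {
  expect_equal(nernst_potential(35, 35), 0)
  expect_equal(nernst_potential(70, 35, 58), 17.45973975, tolerance = 1e-8)
  expect_equal(nernst_potential(350, 35, 58), 58)
  expect_error(nernst_potential(-1, 35), "positive")
})

test_that("chord conductance handles zero current and the singular point", {
  expect_equal(conductance_from_current(0, -40, 19.58), 0)
  expect_equal(conductance_from_current(-500, -40, 19.58), 8.392077878,
               tolerance = 1e-8)
  expect_error(conductance_from_current(-500, 19.58, 19.58), "driving force")
})

test_that("m3h time course matches its endpoints and stays bounded", {
  s <- hh_state(m0 = 0.1, m_inf = 0.9, h0 = 0.95, h_inf = 0.05,
                tau_m = 0.4, tau_h = 2, gmax = 50, offset = 0.5)
  expect_equal(hh_m3h_timecourse(0, s), 50 * 0.1^3 * 0.95 + 0.5)
  expect_equal(hh_m3h_timecourse(1e5, s), 50 * 0.9^3 * 0.05 + 0.5,
               tolerance = 1e-9)
  # frozen unit-parameter value
  u <- hh_state(0, 1, 1, 0, 1, 1, 1, 0)
  expect_equal(hh_m3h_timecourse(1, u), 0.09291915768, tolerance = 1e-9)
  # bounded by [offset, gmax + offset] when endpoints are in [0, 1]
  g <- hh_m3h_timecourse(seq(0, 50, 0.01), s)
  expect_true(all(g >= s$offset - 1e-12 & g <= s$gmax + s$offset + 1e-12))
})

test_that("recovery fraction is a monotone mono-exponential", {
  expect_equal(recovery_fraction(0, 7.64), 0)
  expect_equal(recovery_fraction(7.64 * log(2), 7.64), 0.5)
  expect_equal(recovery_fraction(72, 7.64), 0.9999192444, tolerance = 1e-9)
  # half recovery near 5.29 ms at tau 7.64 ms
  expect_equal(recovery_fraction(5.29, 7.64), 0.5, tolerance = 1e-3)
  t <- seq(0, 100, 0.5)
  r <- recovery_fraction(t, 10)
  expect_true(all(diff(r) > 0))
  expect_true(all(r < 1))
  expect_error(recovery_fraction(1, -1), "tau")
})

test_that("double-exponential decay evaluates and orders its components", {
  p <- decay_params(300, 60, 1, 12)
  expect_equal(double_exp_decay(0, p), -360)
  expect_equal(double_exp_decay(1, decay_params(1, 1, 1, 10)),
               -1.272716859, tolerance = 1e-8)
  # a2 = 0 reduces to a mono-exponential in tau1
  mono <- decay_params(100, 0, 2, 50)
  t <- seq(0, 20, 0.1)
  expect_equal(double_exp_decay(t, mono), -100 * exp(-t / 2))
  # tau1 < tau2 enforced by relabelling
  swapped <- decay_params(60, 300, 12, 1)
  expect_equal(swapped$tau1, 1)
  expect_equal(swapped$a1, 300)
})

test_that("gating charge from the slope factor spans the 3-4 range", {
  expect_equal(charge_from_slope(25.43405912, 295.15), 1, tolerance = 1e-8)
  z_act <- charge_from_slope(7.28, 295.15)
  expect_equal(z_act, 3.49368944, tolerance = 1e-7)
  expect_gt(z_act, 3)
  expect_lt(z_act, 4)
  expect_equal(charge_from_slope(6.47, 295.15), 3.931075599, tolerance = 1e-7)
  expect_error(charge_from_slope(0), "k")
})
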