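test_that("Boltzmann activation curve has the closed form and saturates", {
  na <- sodium_spec(half_activation = -40, slope = 6)
  expect_equal(m_inf(-40, na), 0.5)
  expect_equal(m_inf(-34, na), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(m_inf(1e4, na), 1)
  expect_lt(m_inf(-1e4, na), 1e-100)
  v <- seq(-90, 20, by = 0.5)
  expect_true(all(diff(m_inf(v, na)) > 0))
  expect_true(all(m_inf(v, na) > 0 & m_inf(v, na) < 1))
  expect_error(m_inf(NaN, na), "non-finite")
})

test_that("discretization reproduces the cylinder geometry", {
  cell <- build_cell()
  expect_equal(cell$n_soma, 50)
  expect_equal(cell$n_axon, 600)
  # Total soma membrane area pi * d * l, recovered from the capacitances.
  area_soma <- sum(cell$cap[1:50]) / (0.75 * 1e3) / 1e-8  # um^2
  expect_equal(area_soma, pi * 50 * 50, tolerance = 1e-9)
  # Axial edge conductance within the axon: (pi d^2/4) / (R_a dx).
  g_axon <- 1e6 * (pi * 1^2 / 4) / (150e4 * 1)
  expect_equal(cell$gax[100 + cell$n_soma], g_axon, tolerance = 1e-12)
  # Junction edge: series combination of the two half-segments.
  r_half_soma <- 150e4 * 0.5 / (pi * 50^2 / 4)
  r_half_axon <- 150e4 * 0.5 / (pi * 1^2 / 4)
  expect_equal(cell$gax[cell$n_soma], 1e6 / (r_half_soma + r_half_axon),
               tolerance = 1e-12)
  expect_equal(cell$injection_node, 25)
  expect_error(build_cell(morphology_spec(x_na = 700)), "x_na")
  expect_error(build_cell(morphology_spec(dx = 700)), "spatial step")
})

test_that("passive steady state solves the stationary system exactly", {
  cell <- desk_cell(40, sodium = sodium_spec(peak_conductance = 0))
  v0 <- passive_steady_state(cell, 0)
  expect_equal(v0, rep(-75, length(cell$cap)), tolerance = 1e-12)
  # Superposition of responses.
  n <- length(cell$cap)
  i1 <- numeric(n); i1[cell$injection_node] <- 0.2
  i2 <- numeric(n); i2[cell$na_node] <- -0.1
  va <- passive_steady_state(cell, i1)
  vb <- passive_steady_state(cell, i2)
  vab <- passive_steady_state(cell, i1 + i2)
  expect_equal(vab - v0, (va - v0) + (vb - v0), tolerance = 1e-10)
})

test_that("somatic input resistance matches the sealed-end cable formula", {
  cell <- build_cell()  # full 1 um resolution
  r_num <- input_resistance(cell)
  r_ana <- analytic_input_resistance()
  expect_lt(abs(r_num - r_ana) / r_ana, 0.005)
})

test_that("backward Euler: fixed point, charge balance, relaxation", {
  cell <- desk_cell(40, sodium = sodium_spec(peak_conductance = 0))
  st <- cell_state(cell)
  st2 <- step_cell(cell, st, 0, 0.05)
  expect_equal(st2$voltages, st$voltages, tolerance = 1e-12)

  # Single implicit step: injected charge = capacitive change + leak loss.
  dt <- 0.05
  i_inj <- 0.5
  st3 <- step_cell(cell, st, i_inj, dt)
  dq_cap <- sum(cell$cap * (st3$voltages - st$voltages))
  q_leak <- sum(cell$gleak * (st3$voltages - (-75))) * dt
  expect_equal(i_inj * dt, dq_cap + q_leak, tolerance = 1e-10)

  # Constant current relaxes to the direct linear-solve profile.
  r <- axogain:::run_cell(cell, rep(0.1, round(800 / dt)), dt)
  v_ss <- passive_steady_state(cell, 0.1)
  expect_lt(max(abs(r$state$voltages - v_ss)), 1e-8)
})

test_that("gating variable stays within [0, 1] under strong drive", {
  cell <- desk_cell(40)
  pol <- desk_policy()$policy
  for (s in 1:3) {
    ou <- ou_generate(ou_spec(0.3, 0.5, 5, dt = desk_dt, seed = s), 20000)
    r <- axogain:::run_cell(cell, ou$samples, desk_dt, policy = pol)
    expect_true(r$m >= 0 && r$m <= 1)
    expect_true(all(is.finite(r$state$voltages)))
  }
})

test_that("no sodium conductance means no spikes", {
  cell <- desk_cell(40, sodium = sodium_spec(peak_conductance = 0))
  pol <- reset_policy(-30, -10)
  ou <- ou_generate(ou_spec(0.05, 0.04, 5, dt = desk_dt, seed = 2), 100000)
  r <- axogain:::run_cell(cell, ou$samples, desk_dt, policy = pol)
  expect_length(r$spike_times, 0)
})

test_that("threshold calibration yields ordered thresholds and 2 ms latency", {
  cal <- desk_policy()
  pol <- cal$policy
  expect_gt(pol$detection_threshold, -60)
  expect_lt(pol$detection_threshold, pol$reset_threshold)
  expect_equal(cal$mean_latency, 2, tolerance = 0.05)

  # Constant current at the pilot value fires near-periodically at ~5 Hz.
  tr <- stimulus_trace(rep(cal$pilot_current, round(20500 / desk_dt)),
                       desk_dt, "constant")
  out <- simulate_trial(desk_cell(40), tr, pol, record_every = 0)
  rc <- rate_cv(out$spikes)
  expect_equal(rc$rate, 5, tolerance = 0.4)
  expect_lt(rc$cv, 0.02)
})

test_that("calibration still works for the steep-activation variant", {
  cell <- desk_cell(40, sodium = sodium_spec(slope = 0.1))
  cal <- cached("cal_ka01", calibrate_thresholds(cell, dt = desk_dt))
  expect_true(is.finite(cal$policy$detection_threshold))
  expect_true(is.finite(cal$policy$reset_threshold))
  expect_equal(cal$mean_latency, 2, tolerance = 0.1)
})

test_that("spike times converge under dt and dx refinement", {
  pol <- desk_policy()$policy
  # Several independent short stretches rather than one long one: the
  # fluctuation-driven dynamics amplifies perturbations over long horizons.
  med <- c()
  frac <- c()
  for (s in 4:6) {
    cc <- convergence_check(
      morphology_spec(x_na = 40, dx = desk_dx, soma_dx = desk_soma_dx),
      passive_spec(), sodium_spec(), pol,
      mu = test_mu, sigma = test_sigma, tau = 5,
      duration = 2000, dt = desk_dt, seed = s)
    med <- c(med, cc$median_shift_ms)
    frac <- c(frac, cc$frac_matched)
  }
  # Matched spikes reproduce with sub-ms precision; a minority of
  # near-threshold spikes may appear or vanish under refinement because
  # the fluctuation-driven trajectory amplifies perturbations (the gain
  # analysis is insensitive to this, as per-resolution pipelines agree).
  expect_gte(mean(frac, na.rm = TRUE), 0.6)
  expect_lt(stats::median(med, na.rm = TRUE), 0.5)
})
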