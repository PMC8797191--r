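passive_desk <- function(x_na = 40)
  desk_cell(x_na, sodium = sodium_spec(peak_conductance = 0))

test_that("sinusoidal transfer impedance: DC limit and linearity", {
  cell <- passive_desk(40)
  probe_node <- cell$na_node
  # DC transfer resistance from the direct linear solve.
  v1 <- passive_steady_state(cell, 1)
  v0 <- passive_steady_state(cell, 0)
  r_dc <- v1[probe_node] - v0[probe_node]

  z <- transfer_impedance_sine(cell, 0.5, probe = 40, dt = desk_dt)
  expect_equal(z$impedance_mohm, r_dc, tolerance = 0.01)

  z2 <- transfer_impedance_sine(cell, 20, probe = 40, amplitude = 0.02,
                                dt = desk_dt)
  z1 <- transfer_impedance_sine(cell, 20, probe = 40, amplitude = 0.01,
                                dt = desk_dt)
  expect_equal(z2$impedance_mohm, z1$impedance_mohm, tolerance = 1e-6)

  expect_error(transfer_impedance_sine(desk_cell(40), 10), "passive")
})

test_that("high-frequency damping grows with probe distance", {
  cell <- passive_desk(200)
  z_near <- transfer_impedance_sine(cell, 100, probe = 20, dt = desk_dt)
  z_far <- transfer_impedance_sine(cell, 100, probe = 200, dt = desk_dt)
  expect_lt(z_far$impedance_mohm, z_near$impedance_mohm)
})

test_that("OU and sinusoidal impedance estimates agree mid-band", {
  cell <- passive_desk(40)
  freqs <- c(5, 10, 20, 50, 100, 200)
  zs <- transfer_impedance_sine(cell, freqs, probe = 40, dt = desk_dt)
  zo <- transfer_impedance_ou(cell, ou_spec(0, 0.05, 5, dt = desk_dt,
                                            seed = 14),
                              probe = 40, duration = 120000)
  z_interp <- approx(zo$frequency_hz, zo$impedance_mohm, xout = freqs)$y
  expect_lt(max(abs(z_interp / zs$impedance_mohm - 1)), 0.05)
})

test_that("phase plots: ramp line, translation invariance, alignment", {
  v_ramp <- seq(-70, -30, by = 0.5 * 0.1)  # 0.5 mV/ms at dt = 0.1
  pp <- phase_plot(v_ramp, dt = 0.1)
  expect_lt(diff(range(pp$dvdt)), 1e-9)
  expect_equal(pp$dvdt[1], 0.5, tolerance = 1e-9)

  cal <- desk_policy()
  p1 <- ap_phase_plot(desk_cell(40), cal$policy, cal$pilot_current,
                      dt = desk_dt)
  # Alignment puts the pre-upstroke local minimum at the origin.
  expect_equal(min(abs(p1$v)) + min(abs(p1$dvdt)), 0, tolerance = 0.2)
  # Translation invariance: offsetting the trace leaves the plot fixed.
  r <- axogain:::run_cell(desk_cell(40),
                          rep(cal$pilot_current, round(3000 / desk_dt)),
                          desk_dt, policy = cal$policy,
                          record_nodes = desk_cell(40)$na_node,
                          record_every = 1)
  v <- r$rec[, 1]
  seg <- which(diff(v) < -15)
  i0 <- seg[1] + 2
  i1 <- seg[2] - 1
  a <- phase_plot(v[i0:i1], desk_dt, alignment = "local_minimum")
  b <- phase_plot(v[i0:i1] + 10, desk_dt, alignment = "local_minimum")
  expect_equal(a$v, b$v, tolerance = 1e-9)
  expect_equal(a$dvdt, b$dvdt, tolerance = 1e-9)
})

test_that("axonal AP initiation speeds up with initiation-site distance", {
  # Larger x_Na -> less lateral drain -> faster upstroke at matched rate,
  # read out as dV/dt at +5 mV above the aligned minimum.
  dvdt_at5 <- c()
  for (x in c(20, 40, 80)) {
    cell <- desk_cell(x)
    cal <- cached(paste0("cal_x", x),
                  calibrate_thresholds(cell, dt = desk_dt))
    pp <- ap_phase_plot(cell, cal$policy, cal$pilot_current, dt = desk_dt)
    dvdt_at5 <- c(dvdt_at5, pp$dvdt[which.min(abs(pp$v - 5))])
  }
  expect_true(all(diff(dvdt_at5) > 0))
})
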