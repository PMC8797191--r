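test_that("passive limit: a single equilibrium at the clamped profile", {
  cell <- build_cell(morphology_spec(x_na = 40),
                     sodium = sodium_spec(peak_conductance = 0))
  eq <- axonal_equilibria(cell, -55)
  expect_equal(nrow(eq$equilibria), 1)
  v_prof <- passive_steady_state(cell, 0, clamp_node = cell$injection_node,
                                 clamp_value = -55)
  expect_equal(eq$equilibria$voltage, v_prof[cell$na_node],
               tolerance = 1e-6)
  expect_true(eq$equilibria$stable)
})

test_that("equilibrium count: smooth at 20 um, bistable at 40 um", {
  cell20 <- build_cell(morphology_spec(x_na = 20))
  for (v in seq(-60, -50, by = 1))
    expect_equal(nrow(axonal_equilibria(cell20, v)$equilibria), 1)

  cell40 <- build_cell(morphology_spec(x_na = 40))
  eq <- axonal_equilibria(cell40, -57)
  expect_equal(nrow(eq$equilibria), 3)
  expect_equal(eq$equilibria$stable, c(TRUE, FALSE, TRUE))
  # Equilibria satisfy the current balance to high precision.
  resid <- axogain:::na_balance(eq$equilibria$voltage, cell40, eq$lateral)
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("fold window matches brute-force root counting", {
  cell40 <- build_cell(morphology_spec(x_na = 40))
  w <- bistable_clamp_window(cell40)
  vs <- seq(-62, -52, by = 0.1)
  n3 <- vapply(vs, function(v)
    nrow(axonal_equilibria(cell40, v)$equilibria), 0L)
  brute <- range(vs[n3 == 3])
  expect_equal(w[1], brute[1], tolerance = 0.15)
  expect_equal(w[2], brute[2], tolerance = 0.15)
})

test_that("critical distance agrees with a brute-force grid scan", {
  cd <- cached("critical_distance", critical_distance())
  # Brute force on a 0.5 um grid with a fine clamp sweep.
  brute <- NA
  for (x in seq(25, 31, by = 0.5)) {
    cell <- build_cell(morphology_spec(x_na = x, dx = 0.1))
    if (!is.null(bistable_clamp_window(cell))) { brute <- x; break }
  }
  expect_false(is.na(brute))
  expect_lte(abs(cd - brute), 0.5)

  # Doubling the sodium conductance strengthens the sodium current and
  # moves the onset closer to the soma (the bistable window also shifts to
  # lower clamp voltages, so compare over a wide clamp range).
  cd1w <- critical_distance(v_soma_range = c(-70, -45))
  cd2w <- critical_distance(sodium = sodium_spec(peak_conductance =
                                                   2 * 5.23e-9),
                            v_soma_range = c(-70, -45))
  expect_lt(cd2w, cd1w)
})

test_that("voltage-clamp sweep follows the stable branch and jumps", {
  cell40 <- build_cell(morphology_spec(x_na = 40))
  sweep <- cached("sweep40",
                  vclamp_sweep(cell40, seq(-60, -50, by = 0.25)))
  expect_true(all(sweep$converged))
  # Time-domain stationary states match the algebraic stable equilibria.
  for (i in c(1, 9, 17, 25, 41)) {
    eq <- axonal_equilibria(cell40, sweep$v_soma[i])
    stable_v <- eq$equilibria$voltage[eq$equilibria$stable]
    expect_lt(min(abs(stable_v - sweep$v_axon[i])), 0.1)
  }
  jump <- sweep_jump_voltage(sweep)
  expect_false(is.na(jump))
  expect_gt(jump, -57)
  expect_lt(jump, -54.5)
  # The jump lands at the fold: the upper edge of the bistable window.
  w <- bistable_clamp_window(cell40)
  expect_equal(jump, w[2], tolerance = 0.25)

  # Below the critical distance the sweep is continuous.
  cell20 <- build_cell(morphology_spec(x_na = 20))
  s20 <- vclamp_sweep(cell20, seq(-60, -50, by = 0.5))
  expect_lt(max(diff(s20$v_axon)), 2)
})

test_that("Thevenin reduction is exact and weakens with distance", {
  cells <- lapply(c(20, 40, 80), function(x)
    build_cell(morphology_spec(x_na = x)))
  lats <- lapply(cells, lateral_current_line, v_soma_clamp = -55)
  g <- vapply(lats, `[[`, 0, "conductance")
  expect_true(all(diff(g) < 0))  # conductance decreases with x_Na

  # Offset vanishes at the open-circuit voltage.
  for (l in lats)
    expect_equal(l$conductance * l$v_open + l$offset, 0, tolerance = 1e-12)

  # The affine reduction reproduces full clamped solves for test currents.
  cell <- cells[[2]]
  lat <- lats[[2]]
  for (i_test in c(-0.3, 0.15, 0.4)) {
    iv <- numeric(length(cell$cap))
    iv[cell$na_node] <- i_test
    v <- passive_steady_state(cell, iv, clamp_node = cell$injection_node,
                              clamp_value = -55)
    expect_equal(v[cell$na_node], lat$v_open + lat$r_th * i_test,
                 tolerance = 1e-9)
  }
})

test_that("current-clamp ramp decouples gradually, passive cell never", {
  ramp <- slow_ramp(0, 0.06, 5000, dt = desk_dt)

  pcell <- desk_cell(40, sodium = sodium_spec(peak_conductance = 0))
  tr <- cclamp_ramp(pcell, ramp, detection_threshold = 0, record_every = 5)
  expect_lt(max(abs(tr$v_soma - tr$v_axon)), 1.5)

  cell <- desk_cell(40)
  tr2 <- cclamp_ramp(cell, ramp, detection_threshold = -25,
                     record_every = 1)
  # Gradual decoupling: no jump between consecutive samples (0.05 ms).
  expect_lt(max(abs(diff(tr2$v_axon))), 2)
  expect_gt(max(tr2$v_axon - tr2$v_soma), 3)  # but real decoupling occurs

  # Steep activation: the axon tracks the soma until V_1/2, then departs.
  # (The steep variant has no sub-V_1/2 sodium boost, so its rheobase is
  # higher and the ramp must reach further.)
  kcell <- desk_cell(40, sodium = sodium_spec(slope = 0.1))
  ramp2 <- slow_ramp(0, 0.15, 6000, dt = desk_dt)
  tr3 <- cclamp_ramp(kcell, ramp2, detection_threshold = -25,
                     record_every = 1)
  dep <- which(abs(tr3$v_axon - tr3$v_soma) > 2)[1]
  expect_false(is.na(dep))
  expect_equal(tr3$v_axon[dep], -40, tolerance = 1.5)
  before <- tr3$v_axon < -41
  expect_lt(max(abs(tr3$v_axon - tr3$v_soma)[before]), 2)

  # A too-fast ramp is rejected by the quasi-static guard.
  expect_error(cclamp_ramp(cell, slow_ramp(0, 2, 20, dt = desk_dt)),
               "too fast")
})
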