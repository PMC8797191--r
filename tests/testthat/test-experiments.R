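test_that("fig1 preset reproduces the bifurcation summary and writes files", {
  out <- file.path(tempdir(), "fig1run")
  cfg <- experiment_config("fig1", overrides = list(x_na = c(20, 40)),
                           seed = 3, out_dir = out)
  b1 <- run_experiment(cfg)
  expect_equal(b1$summary$critical_distance_um, 27.6, tolerance = 0.05)
  expect_equal(b1$summary$jump_voltage_mv, -55.9, tolerance = 0.02)
  expect_true(all(c("x_na", "v_soma", "voltage", "stable") %in%
                    names(b1$branches)))
  expect_true(file.exists(file.path(out, "fig1_summary.json")))
  expect_true(file.exists(file.path(out, "fig1_branches.csv")))

  # Re-execution with the same config reproduces identical outputs.
  j1 <- readLines(file.path(out, "fig1_summary.json"))
  b2 <- run_experiment(cfg)
  j2 <- readLines(file.path(out, "fig1_summary.json"))
  expect_identical(j1, j2)
  expect_identical(b1$summary, b2$summary)
  expect_identical(b1$vclamp, b2$vclamp)
})

test_that("config hashing separates configs; hashes are stable", {
  a <- config_hash(list(x = 1, y = "b"))
  expect_identical(a, config_hash(list(x = 1, y = "b")))
  expect_false(identical(a, config_hash(list(x = 2, y = "b"))))
})

test_that("a single-point cutoff surface equals the direct pipeline run", {
  scale <- list(n_trials = 10, dt = desk_dt, dx = desk_dx,
                soma_dx = desk_soma_dx, n_surrogates = 40,
                n_resamples = 100, pilot_duration = 20000,
                verify_duration = 40000)
  cache <- file.path(tempdir(), "surfcache")
  surf <- cutoff_surface(axis1 = list(name = "x_na", values = 40),
                         axis2 = list(name = "gbar_mult", values = 1),
                         tau = 5, scale = scale, seed = 5,
                         cache_dir = cache)
  expect_true(surf$ok[1, 1])
  # Cached rerun is instantaneous and bit-identical.
  t0 <- proc.time()
  surf2 <- cutoff_surface(axis1 = list(name = "x_na", values = 40),
                          axis2 = list(name = "gbar_mult", values = 1),
                          tau = 5, scale = scale, seed = 5,
                          cache_dir = cache)
  expect_lt((proc.time() - t0)[[3]], 5)
  expect_identical(surf$cutoff, surf2$cutoff)
  # The stored cutoff is the direct pipeline cutoff for that condition.
  direct <- axogain:::condition_gain(list(x_na = 40, gbar_mult = 1), 5,
                                     working_point(), scale,
                                     mix_seed(5, 1 * 211 + 1),
                                     cache_dir = cache)
  expect_identical(surf$cutoff[1, 1], direct$curve$cutoff_frequency)
})

test_that("spike trains round-trip through the CSV dialect", {
  sp <- list(spike_train(c(600, 900.25), 20000, 500),
             spike_train(numeric(0), 20000, 500),
             spike_train(1500, 20000, 500))
  fp <- tempfile(fileext = ".csv")
  write_spike_trains(sp, fp)
  df <- read.csv(fp)
  expect_equal(df$trial_id, c(1, 1, 3))
  expect_equal(df$spike_time_ms, c(600, 900.25, 1500))
})

test_that("model config YAML round-trips the spec fields", {
  fp <- tempfile(fileext = ".yaml")
  writeLines(c("morphology:", "  x_na: 20", "  dx: 2", "  soma_dx: 5",
               "passive:", "  axial_resistivity: 750",
               "sodium:", "  slope: 1"), fp)
  cfg <- read_model_config(fp)
  expect_equal(cfg$morphology$x_na, 20)
  expect_equal(cfg$passive$axial_resistivity, 750)
  expect_equal(cfg$sodium$slope, 1)
  cell <- build_cell(cfg$morphology, cfg$passive, cfg$sodium)
  expect_equal(cell$n_axon, 300)
})
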