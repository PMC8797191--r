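# Estimator tests run on the inhomogeneous-Poisson fixture (see
# helper-fixtures.R), whose true dynamic gain is known by construction.

test_that("STA reflects the causal filter and vanishes for shuffled pairs", {
  fx <- lowpass_fx()
  sta <- compute_sta(fx$currents, fx$spikes, fx_cfg)
  expect_length(sta$lags, 8001)
  expect_equal(sta$mean_rate, 10, tolerance = 0.5)
  # Causal filter: pre-spike current elevated, peak at negative lag.
  expect_lt(sta$lags[which.max(sta$sta_current)], 0)
  expect_gt(max(sta$sta_current), 0)
  # STA decays toward zero at the window edges.
  core <- max(abs(sta$sta_current))
  edge <- mean(abs(sta$sta_current[abs(sta$lags) > 300]))
  expect_lt(edge, 0.1 * core)

  # Shuffled pairing destroys the correlation (residual is sampling noise).
  sh <- compute_sta(fx$currents[c(31:60, 1:30)], fx$spikes, fx_cfg)
  expect_lt(max(abs(sh$sta_current)), 0.4 * core)
})

test_that("STA variance scales inversely with the number of trials", {
  fx <- lowpass_fx()
  sta_of <- function(idx) compute_sta(fx$currents[idx], fx$spikes[idx],
                                      fx_cfg)$sta_current
  # Pointwise variance across disjoint 10-trial and 30-trial estimates.
  v10 <- apply(sapply(list(1:10, 11:20, 21:30, 31:40, 41:50, 51:60),
                      sta_of), 1, var)
  v30 <- apply(sapply(list(1:30, 31:60), sta_of), 1, var)
  ratio <- mean(v10) / mean(v30)
  expect_gt(ratio, 1.5)  # expected 3, generous for sampling noise
})

test_that("gain recovery: low-pass fixture within the bootstrap CI", {
  g <- lowpass_curve()
  truth <- Mod(lowpass_fx()$transfer$evaluate(g$frequencies))
  sig <- g$significant & g$frequencies <= 200
  expect_gt(sum(sig), 10)
  covered <- truth[sig] >= g$ci_low[sig] & truth[sig] <= g$ci_high[sig]
  expect_gte(mean(covered), 0.9)
  expect_equal(g$cutoff_frequency, sqrt(3) * 20, tolerance = 0.25)
})

test_that("flat filter gives a flat gain curve at the imposed level", {
  fx <- cached("fx_flat",
               poisson_fixture(10, fixture_filter("flat", gain = 30),
                               fx_ou, n_trials = 120, seed = 23))
  g <- estimate_gain(fx$currents, fx$spikes, fx_ou,
                     gain_config(n_trials = 120, dt = 0.1, dt_sta = 0.1,
                                 n_surrogates = 0, n_resamples = 200),
                     seed = 2)
  band <- g$frequencies >= 3 & g$frequencies <= 100
  expect_equal(mean(g$gain[band]), 30, tolerance = 0.1)
  expect_lt(diff(range(g$gain[band])) / 30, 0.5)
})

test_that("analytic and empirical denominators agree in the mid-band", {
  fx <- lowpass_fx()
  cfg_emp <- fx_cfg
  cfg_emp$denominator <- "empirical"
  g_ana <- lowpass_curve()
  g_emp <- estimate_gain(fx$currents, fx$spikes, fx_ou, cfg_emp, seed = 8)
  band <- g_ana$frequencies >= 2 & g_ana$frequencies <= 200
  ratio <- g_emp$gain[band] / g_ana$gain[band]
  expect_lt(max(abs(ratio - 1)), 0.1)
})

test_that("unit linearity: scaling currents scales gain inversely", {
  fx <- lowpass_fx()
  cur2 <- lapply(fx$currents[1:20], function(tr) {
    tr$samples <- tr$samples * 2
    tr
  })
  ou2 <- ou_spec(0, 0.1, 5, dt = 0.1)
  cfg <- gain_config(n_trials = 20, dt = 0.1, dt_sta = 0.1,
                     n_surrogates = 0, n_resamples = 100)
  g1 <- estimate_gain(fx$currents[1:20], fx$spikes[1:20], fx_ou, cfg,
                      seed = 3)
  g2 <- estimate_gain(cur2, fx$spikes[1:20], ou2, cfg, seed = 3)
  expect_equal(g2$gain, g1$gain / 2, tolerance = 1e-10)
})

test_that("gaussian denoising: constants preserved, white-noise variance", {
  f <- seq(1.25, 1000, by = 1.25)
  const <- rep(3 + 4i, length(f))
  sm <- gaussian_denoise(f, const)
  expect_equal(sm$response, rep(3 + 4i, length(sm$frequencies)),
               tolerance = 1e-12)

  # Narrow filters converge to the input (nearest-bin identity).
  x <- complex(real = sin(f / 50), imaginary = cos(f / 70))
  sm2 <- gaussian_denoise(f, x, frac_width = 1e-6)
  nearest <- vapply(sm2$frequencies,
                    function(fc) x[which.min(abs(f - fc))], 0i)
  expect_equal(sm2$response, nearest, tolerance = 1e-9)

  # White complex noise: variance reduction equals sum of squared weights.
  fb <- filter_bank(f)
  i100 <- which.min(abs(fb$centers - 100))
  set.seed(4)
  noise <- matrix(complex(real = rnorm(length(f) * 400),
                          imaginary = rnorm(length(f) * 400)),
                  length(f))
  sm3 <- fb$weights %*% noise
  ratio <- var(Re(sm3[i100, ])) / 1
  expect_equal(ratio, sum(fb$weights[i100, ]^2), tolerance = 0.35)
})

test_that("null fixture: gain stays below the significance threshold", {
  fx <- cached("fx_null",
               poisson_fixture(10, fixture_filter("zero"), fx_ou,
                               n_trials = 20, seed = 11))
  g <- estimate_gain(fx$currents, fx$spikes, fx_ou,
                     gain_config(n_trials = 20, dt = 0.1, dt_sta = 0.1,
                                 n_surrogates = 150, n_resamples = 100),
                     seed = 6)
  expect_gte(mean(!g$significant), 0.9)
})

test_that("significance threshold scales with spike count", {
  fx <- lowpass_fx()
  thr_of <- function(idx) {
    cfg <- gain_config(n_trials = length(idx), dt = 0.1, dt_sta = 0.1,
                       n_surrogates = 100, n_resamples = 100)
    g <- estimate_gain(fx$currents[idx], fx$spikes[idx], fx_ou, cfg,
                       seed = 9)
    mean(g$significance[g$frequencies > 100])
  }
  r <- thr_of(1:15) / thr_of(1:60)
  expect_equal(r, 2, tolerance = 0.4)  # ~ sqrt(60/15)
})

test_that("degenerate bootstrap: identical trials give zero-width CI", {
  fx <- lowpass_fx()
  reps <- rep(1L, 8)
  cfg <- gain_config(n_trials = 8, dt = 0.1, dt_sta = 0.1,
                     n_surrogates = 0, n_resamples = 50)
  g <- estimate_gain(fx$currents[reps], fx$spikes[reps], fx_ou, cfg,
                     seed = 12)
  expect_equal(g$ci_low, g$gain, tolerance = 1e-12)
  expect_equal(g$ci_high, g$gain, tolerance = 1e-12)
})

test_that("cutoff frequency: closed form, flat curve, insignificance", {
  f0 <- 30
  f <- 10^seq(0, 3, by = 1 / 40)
  curve <- list(frequencies = f, gain = 100 / sqrt(1 + (f / f0)^2),
                significant = rep(TRUE, length(f)))
  expect_equal(cutoff_frequency(curve), sqrt(3) * f0, tolerance = 0.02)

  flat <- list(frequencies = f, gain = rep(5, length(f)),
               significant = rep(TRUE, length(f)))
  expect_true(is.na(cutoff_frequency(flat)))

  none <- list(frequencies = f, gain = rep(5, length(f)),
               significant = rep(FALSE, length(f)))
  expect_error(cutoff_frequency(none), "below the significance")
})

test_that("same seed reproduces the gain curve exactly", {
  fx <- lowpass_fx()
  cfg <- gain_config(n_trials = 10, dt = 0.1, dt_sta = 0.1,
                     n_surrogates = 30, n_resamples = 50)
  g1 <- estimate_gain(fx$currents[1:10], fx$spikes[1:10], fx_ou, cfg,
                      seed = 31)
  g2 <- estimate_gain(fx$currents[1:10], fx$spikes[1:10], fx_ou, cfg,
                      seed = 31)
  expect_identical(g1$gain, g2$gain)
  expect_identical(g1$significance, g2$significance)
  expect_identical(g1$ci_low, g2$ci_low)
})
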