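# Poisson-fixture ground truth shared by the estimator tests and the
# acceptance property suite.
fx_ou <- ou_spec(0, 0.05, 5, dt = 0.1)
fx_cfg <- gain_config(n_trials = 60, dt = 0.1, dt_sta = 0.1,
                      n_surrogates = 120, n_resamples = 300)

lowpass_fx <- function() {
  cached("fx_lowpass",
         poisson_fixture(10, fixture_filter("lowpass", gain = 40, f_c = 20),
                         fx_ou, n_trials = 60, seed = 21))
}

lowpass_curve <- function() {
  cached("fx_lowpass_curve",
         estimate_gain(lowpass_fx()$currents, lowpass_fx()$spikes, fx_ou,
                       fx_cfg, seed = 8))
}
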