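#' Ornstein-Uhlenbeck stimulus specification
#'
#' Parameters of the Gaussian colored-noise current
#' `tau dI = (mu - I) dt + sqrt(2 tau) sigma dW`, whose stationary law is
#' `N(mu, sigma^2)` with exponential autocorrelation `exp(-lag/tau)` and
#' two-sided power spectral density `P(f) = 2 tau sigma^2 / (1 + (2 pi tau
#' f)^2)`.
#'
#' @param mu Mean current (nA).
#' @param sigma Stationary standard deviation (nA).
#' @param tau Correlation time (ms).
#' @param dt Sampling step (ms).
#' @param seed Integer seed (optional).
#' @return An object of class `ou_spec`.
#' @export
ou_spec <- function(mu, sigma, tau, dt = 0.025, seed = NULL) {
  stopifnot(sigma >= 0, tau > 0, dt > 0)
  structure(list(mu = mu, sigma = sigma, tau = tau, dt = dt, seed = seed),
            class = "ou_spec")
}

#' Sampled current waveform
#'
#' @param samples Current samples (nA), one per `dt` step.
#' @param dt Sampling step (ms).
#' @param kind One of `"ou"`, `"sinusoid"`, `"constant"`, `"ramp"`.
#' @param params The generating specification.
#' @param seed Seed used, if any.
#' @return An object of class `stimulus_trace`.
#' @export
stimulus_trace <- function(samples, dt, kind, params = NULL, seed = NULL) {
  stopifnot(length(samples) > 0, all(is.finite(samples)), dt > 0)
  structure(list(samples = as.numeric(samples), dt = dt, kind = kind,
                 params = params, seed = seed),
            class = "stimulus_trace")
}

#' Generate an Ornstein-Uhlenbeck current trace
#'
#' Uses the exact discretization
#' `I_{k+1} = mu + (I_k - mu) a + sigma sqrt(1 - a^2) xi_k` with
#' `a = exp(-dt/tau)` and standard normal `xi_k`, so the sampled statistics
#' carry no time-step bias. The initial sample is drawn from the stationary
#' distribution `N(mu, sigma^2)`.
#'
#' @param spec An [ou_spec()].
#' @param n_steps Number of samples.
#' @return A [stimulus_trace()] of kind `"ou"`.
#' @export
ou_generate <- function(spec, n_steps) {
  stopifnot(inherits(spec, "ou_spec"), n_steps > 0)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (spec$sigma == 0)
    return(stimulus_trace(rep(spec$mu, n_steps), spec$dt, "ou", spec,
                          spec$seed))
  a <- exp(-spec$dt / spec$tau)
  s <- spec$sigma * sqrt(1 - a^2)
  x0 <- stats::rnorm(1, 0, spec$sigma)
  if (n_steps == 1) {
    x <- x0
  } else {
    innov <- stats::rnorm(n_steps - 1, 0, s)
    x <- c(x0, stats::filter(innov, a, method = "recursive", init = x0))
  }
  stimulus_trace(spec$mu + as.numeric(x), spec$dt, "ou", spec, spec$seed)
}

#' Two-sided power spectral density of the OU process
#'
#' @param f Frequency (Hz); vectorized.
#' @param tau Correlation time (ms).
#' @param sigma Stationary standard deviation (nA).
#' @return PSD (nA^2/Hz); integrates to `sigma^2` over all frequencies.
#' @export
ou_psd <- function(f, tau, sigma) {
  tau_s <- tau / 1000
  2 * tau_s * sigma^2 / (1 + (2 * pi * tau_s * f)^2)
}

#' Sinusoidal probe current
#'
#' @param amplitude Amplitude (nA).
#' @param frequency Frequency (Hz); must be below the Nyquist frequency of
#'   `dt`.
#' @param offset Constant offset (nA).
#' @param dt Sampling step (ms).
#' @param n_steps Number of samples.
#' @return A [stimulus_trace()] of kind `"sinusoid"`.
#' @export
sinusoid <- function(amplitude, frequency, offset = 0, dt = 0.025,
                     n_steps) {
  nyquist <- 1000 / (2 * dt)
  if (frequency >= nyquist)
    stop(sprintf("frequency %g Hz at or above Nyquist (%g Hz)", frequency,
                 nyquist))
  t_s <- (seq_len(n_steps) - 1) * dt / 1000
  stimulus_trace(offset + amplitude * sin(2 * pi * frequency * t_s), dt,
                 "sinusoid",
                 list(amplitude = amplitude, frequency = frequency,
                      offset = offset))
}

#' Slowly increasing (or decreasing) current ramp
#'
#' @param start,end Start and end currents (nA).
#' @param duration Ramp duration (ms).
#' @param dt Sampling step (ms).
#' @return A [stimulus_trace()] of kind `"ramp"`.
#' @export
slow_ramp <- function(start, end, duration, dt = 0.025) {
  stopifnot(duration > 0)
  n <- max(2, round(duration / dt))
  stimulus_trace(seq(start, end, length.out = n), dt, "ramp",
                 list(start = start, end = end, duration = duration))
}

#' Deterministic per-trial seed derivation
#'
#' Mixes a trial index into a root seed so trials are reproducible
#' independently of execution order. The result stays below 2^31.
#'
#' @param root Root integer seed.
#' @param index Trial index (1-based).
#' @return An integer seed.
#' @export
mix_seed <- function(root, index) {
  as.integer((as.numeric(root) * 48271 + as.numeric(index) * 1000003) %%
               2147483629 + 1)
}

#' Linear transfer functions for the estimator-validation fixture
#'
#' @param kind `"lowpass"` (first-order, corner `f_c`), `"flat"`, or
#'   `"zero"`.
#' @param gain DC gain (Hz/nA).
#' @param f_c Corner frequency (Hz) for the low-pass filter.
#' @return A list with the filter parameters and an `evaluate(f)` function
#'   returning the complex response.
#' @export
fixture_filter <- function(kind = c("lowpass", "flat", "zero"), gain = 40,
                           f_c = 20) {
  kind <- match.arg(kind)
  evaluate <- switch(kind,
    lowpass = function(f) gain / (1 + 1i * f / f_c),
    flat = function(f) rep(gain + 0i, length(f)),
    zero = function(f) rep(0i, length(f)))
  list(kind = kind, gain = gain, f_c = f_c, evaluate = evaluate)
}

#' Inhomogeneous-Poisson validation fixture with a known linear response
#'
#' Generates OU current traces and spike trains whose instantaneous rate is a
#' known linear functional of the input, `nu(t) = nu0 + (h * dI)(t)`, so the
#' true dynamic gain equals `|H(f)|` by construction. This allows the
#' STA-based estimator to be validated without the cable simulator.
#'
#' @param baseline_rate Baseline rate `nu0` (Hz).
#' @param transfer A [fixture_filter()].
#' @param ou An [ou_spec()] (its `seed` is ignored; per-trial seeds are
#'   derived from `seed`).
#' @param n_trials Number of trials.
#' @param trial_length Recorded duration per trial (ms).
#' @param burn_in Discarded initial duration (ms).
#' @param seed Root seed.
#' @return A list with `currents` (list of [stimulus_trace()]), `spikes`
#'   (list of [spike_train()]), and `transfer`.
#' @export
poisson_fixture <- function(baseline_rate, transfer, ou, n_trials = 50,
                            trial_length = 20000, burn_in = 500, seed = 1) {
  stopifnot(baseline_rate > 0, n_trials > 0)
  n <- round((trial_length + burn_in) / ou$dt)
  currents <- vector("list", n_trials)
  spikes <- vector("list", n_trials)
  a <- if (transfer$kind == "lowpass")
    exp(-ou$dt * 2 * pi * transfer$f_c / 1000) else 0
  clipped <- 0L
  for (i in seq_len(n_trials)) {
    si <- mix_seed(seed, i)
    tr <- ou_generate(ou_spec(ou$mu, ou$sigma, ou$tau, ou$dt, seed = si), n)
    di <- tr$samples - ou$mu
    mod <- switch(transfer$kind,
      zero = numeric(n),
      flat = transfer$gain * di,
      lowpass = as.numeric(stats::filter((1 - a) * transfer$gain * di, a,
                                         method = "recursive")))
    rate <- baseline_rate + mod
    neg <- rate < 0
    clipped <- clipped + sum(neg)
    rate[neg] <- 0
    p <- rate * ou$dt / 1000
    hit <- stats::runif(n) < p
    st <- (which(hit) - 0.5) * ou$dt
    st <- st[st > burn_in]
    currents[[i]] <- tr
    spikes[[i]] <- spike_train(st, trial_duration = trial_length,
                               burn_in = burn_in, seed = si)
  }
  if (clipped > 0.001 * n * n_trials)
    stop("rate modulation too deep: >0.1% of samples clipped at zero")
  list(currents = currents, spikes = spikes, transfer = transfer)
}
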