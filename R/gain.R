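#' Configuration of the dynamic-gain estimation pipeline
#'
#' Defaults follow the production-scale analysis (20000 trials of 20 s, 500
#' cyclic-shift surrogates, 400 bootstrap groups of 50 trials, 1000
#' resamples); desk-scale runs lower `n_trials` (the bootstrap then falls
#' back to smaller groups).
#'
#' @param n_trials Number of trials.
#' @param trial_length Recorded duration per trial (ms).
#' @param burn_in Discarded initial duration per trial (ms).
#' @param window Spike-triggered-average window length (ms), centered on the
#'   spike.
#' @param dt Integration time step (ms).
#' @param dt_sta STA sampling step (ms); currents are block-averaged from
#'   `dt` to `dt_sta` before accumulation.
#' @param n_surrogates Number of cyclic-shift surrogates for the
#'   significance threshold.
#' @param shift_range Cyclic shift range (ms) for surrogates.
#' @param group_size,n_groups Bootstrap grouping (trials per group, number
#'   of groups).
#' @param n_resamples Bootstrap resamples of the grand average.
#' @param frac_width Fractional width of the Gaussian filter bank (filter sd
#'   = `frac_width * f_c`).
#' @param centers_per_decade Log-spaced filter-bank centers per decade.
#' @param f_max Upper frequency limit (Hz).
#' @param denominator `"analytic_psd"` (closed-form OU power spectrum) or
#'   `"empirical"` (windowed input autocorrelation spectrum).
#' @return An object of class `gain_config`.
#' @export
gain_config <- function(n_trials = 300, trial_length = 20000, burn_in = 500,
                        window = 800, dt = 0.05, dt_sta = 0.1,
                        n_surrogates = 500, shift_range = c(1000, 19000),
                        group_size = 50, n_groups = 400, n_resamples = 1000,
                        frac_width = 0.25, centers_per_decade = 20,
                        f_max = 1000,
                        denominator = c("analytic_psd", "empirical")) {
  denominator <- match.arg(denominator)
  stopifnot(n_trials > 0, window > 0, shift_range[1] >= 0,
            shift_range[2] <= trial_length, dt_sta >= dt,
            abs(dt_sta / dt - round(dt_sta / dt)) < 1e-9)
  structure(list(n_trials = n_trials, trial_length = trial_length,
                 burn_in = burn_in, window = window, dt = dt,
                 dt_sta = dt_sta, n_surrogates = n_surrogates,
                 shift_range = shift_range, group_size = group_size,
                 n_groups = n_groups, n_resamples = n_resamples,
                 frac_width = frac_width,
                 centers_per_decade = centers_per_decade, f_max = f_max,
                 denominator = denominator),
            class = "gain_config")
}

# Block-average a current trace from dt to dt_sta and drop the burn-in.
decimate_current <- function(samples, dt, dt_sta, burn_in) {
  k <- round(dt_sta / dt)
  x <- samples[-seq_len(round(burn_in / dt))]
  if (k == 1) return(x)
  n <- (length(x) %/% k) * k
  colMeans(matrix(x[seq_len(n)], nrow = k))
}

# Nearest-sample indices (1-based) of spike times relative to recording
# start; samples are centered at (j - 0.5) * dt_sta.
spike_sample_index <- function(t_rel, dt_sta, n) {
  pmin(pmax(floor(t_rel / dt_sta) + 1L, 1L), n)
}

# Streaming accumulator over trials for the gain pipeline: grand STA, group
# STAs for the bootstrap, cyclic-shift surrogate STAs, and the empirical
# input spectrum. All cross-correlations keep "sum over spikes" semantics;
# dividing by the total recorded time yields the input-output correlation.
new_gain_accumulator <- function(config) {
  halfw <- round(config$window / 2 / config$dt_sta)
  w <- 2L * halfw + 1L
  env <- new.env(parent = emptyenv())
  env$halfw <- halfw
  env$config <- config
  env$sta_sum <- numeric(w)
  env$n_used <- 0
  env$n_all <- 0
  env$total_time_ms <- 0
  env$mean_current_sum <- 0
  env$surr <- matrix(0, w, config$n_surrogates)
  env$group_size <- if (config$n_trials >= config$group_size *
                          config$n_groups) config$group_size else 1L
  env$n_groups_eff <- ceiling(config$n_trials / env$group_size)
  env$group_sums <- matrix(0, w, env$n_groups_eff)
  env$auto_sum <- NULL
  env$n_trials_seen <- 0L
  env
}

add_gain_trial <- function(env, samples, dt, spike_times_rel) {
  cfg <- env$config
  x <- decimate_current(samples, dt, cfg$dt_sta, cfg$burn_in)
  n <- length(x)
  mu_hat <- mean(x)
  dI <- x - mu_hat
  idx <- spike_sample_index(spike_times_rel, cfg$dt_sta, n)
  acc <- cpp_sta_accumulate(dI, as.integer(idx) - 1L, env$halfw)
  env$sta_sum <- env$sta_sum + acc$sum
  env$n_used <- env$n_used + acc$n
  env$n_all <- env$n_all + length(idx)
  env$total_time_ms <- env$total_time_ms + n * cfg$dt_sta
  env$mean_current_sum <- env$mean_current_sum + mu_hat
  env$n_trials_seen <- env$n_trials_seen + 1L
  g <- ceiling(env$n_trials_seen / env$group_size)
  env$group_sums[, g] <- env$group_sums[, g] + acc$sum

  f_di <- stats::fft(dI)
  if (is.null(env$auto_sum)) env$auto_sum <- numeric(n)
  env$auto_sum <- env$auto_sum + Mod(f_di)^2

  if (cfg$n_surrogates > 0 && length(idx)) {
    s <- numeric(n)
    tb <- tabulate(idx, nbins = n)
    cc <- Re(stats::fft(f_di * Conj(stats::fft(tb)), inverse = TRUE)) / n
    smin <- ceiling(cfg$shift_range[1] / cfg$dt_sta)
    smax <- floor(cfg$shift_range[2] / cfg$dt_sta)
    shifts <- as.integer(floor(stats::runif(cfg$n_surrogates, smin,
                                            smax + 1)))
    cpp_shift_accumulate(cc, shifts, env$halfw, env$surr)
  }
  invisible(env)
}

# Lag axis (ms) of the accumulated STA.
acc_lags <- function(env) {
  (-env$halfw:env$halfw) * env$config$dt_sta
}

#' Compute the spike-triggered average current
#'
#' Averages mean-subtracted current segments in a window centered on each
#' spike (nearest-sample alignment); segments clipped at trial edges are
#' excluded. The input-output correlation follows as
#' `C_Inu(lag) = mean_rate * STA(lag)`.
#'
#' @param currents List of [stimulus_trace()] objects (one per trial).
#' @param spikes List of matching [spike_train()] objects.
#' @param config A [gain_config()]; its `window`, `dt_sta` and `burn_in`
#'   fields are used.
#' @return An object of class `sta_result` with `lags` (ms), `sta_current`
#'   (nA), `n_spikes`, `mean_rate` (Hz) and `mean_current` (nA).
#' @export
compute_sta <- function(currents, spikes, config = gain_config()) {
  stopifnot(length(currents) == length(spikes), length(currents) > 0)
  cfg <- config
  cfg$n_trials <- length(currents)
  cfg$n_surrogates <- 0L
  env <- new_gain_accumulator(cfg)
  for (i in seq_along(currents)) {
    tr <- currents[[i]]
    sp <- spikes[[i]]
    add_gain_trial(env, tr$samples, tr$dt, sp$spike_times - sp$burn_in)
  }
  if (env$n_used == 0) stop("no spikes within the STA window")
  structure(list(lags = acc_lags(env),
                 sta_current = env$sta_sum / env$n_used,
                 n_spikes = env$n_all,
                 mean_rate = env$n_all / (env$total_time_ms / 1000),
                 mean_current = env$mean_current_sum / env$n_trials_seen,
                 accumulator = env),
            class = "sta_result")
}

# Positive FFT frequencies (Hz) of the STA window and the index set kept.
window_freqs <- function(halfw, dt_sta, f_max) {
  n <- 2L * halfw
  f <- (seq_len(n) - 1) / (n * dt_sta / 1000)
  keep <- which(f > 0 & f <= f_max)
  list(f = f[keep], keep = keep, n = n)
}

# Continuous-time Fourier transform of a windowed correlation given as
# columns of lag-domain values (lags -halfw..halfw); returns the positive
# frequency rows. Input may be a vector or matrix.
correlation_fft <- function(cmat, halfw, dt_sta, keep) {
  cmat <- as.matrix(cmat)
  n <- 2L * halfw
  # Drop the last (+window/2) lag and wrap so lag zero leads.
  wrapped <- rbind(cmat[(halfw + 1):(2 * halfw), , drop = FALSE],
                   cmat[seq_len(halfw), , drop = FALSE])
  ft <- stats::mvfft(wrapped) * (dt_sta / 1000)
  ft[keep, , drop = FALSE]
}

#' Gaussian filter bank for complex spectra
#'
#' Builds the smoothing matrix of a bank of Gaussian filters with log-spaced
#' centers (constant number per decade) and frequency-proportional widths
#' (sd = `frac_width * f_c`), applied jointly to the real and imaginary
#' parts. Weights are normalized per center.
#'
#' @param freqs Input frequency grid (Hz), uniform and positive.
#' @param frac_width Fractional filter width.
#' @param centers_per_decade Centers per decade.
#' @param f_range Range of center frequencies (Hz); defaults to the grid
#'   range.
#' @return A list with `centers` (Hz) and `weights` (matrix, centers x
#'   freqs).
#' @export
filter_bank <- function(freqs, frac_width = 0.25, centers_per_decade = 20,
                        f_range = range(freqs)) {
  lc <- seq(log10(f_range[1]), log10(f_range[2]),
            by = 1 / centers_per_decade)
  centers <- 10^lc
  wts <- matrix(0, length(centers), length(freqs))
  for (i in seq_along(centers)) {
    sd_i <- frac_width * centers[i]
    w <- exp(-0.5 * ((freqs - centers[i]) / sd_i)^2)
    # Guarantee support even when the filter is narrower than the grid.
    if (sum(w) == 0) w[which.min(abs(freqs - centers[i]))] <- 1
    wts[i, ] <- w / sum(w)
  }
  list(centers = centers, weights = wts)
}

#' Denoise a complex spectrum with a Gaussian filter bank
#'
#' @param freqs Frequency grid (Hz) of `spectrum`.
#' @param spectrum Complex spectrum on `freqs` (vector or matrix with
#'   frequencies in rows).
#' @param frac_width,centers_per_decade See [filter_bank()].
#' @return A list with `frequencies` (the filter centers) and `response`
#'   (smoothed complex values).
#' @export
gaussian_denoise <- function(freqs, spectrum, frac_width = 0.25,
                             centers_per_decade = 20) {
  fb <- filter_bank(freqs, frac_width, centers_per_decade)
  sp <- as.matrix(spectrum)
  sm <- fb$weights %*% sp
  list(frequencies = fb$centers,
       response = if (ncol(sm) == 1) sm[, 1] else sm)
}

# Internal: assemble numerator spectra, denominator, smoothing and gain for
# an accumulator. Returns the full bundle used by the public entry points.
finalize_gain <- function(env, tau, sigma) {
  cfg <- env$config
  halfw <- env$halfw
  t_tot_s <- env$total_time_ms / 1000
  wf <- window_freqs(halfw, cfg$dt_sta, cfg$f_max)
  fb <- filter_bank(wf$f, cfg$frac_width, cfg$centers_per_decade)

  # Empirical windowed input autocorrelation spectrum (per-trial circular
  # autocorrelation, averaged, truncated to the STA window).
  nfull <- length(env$auto_sum)
  acf_full <- Re(stats::fft(env$auto_sum / env$n_trials_seen,
                            inverse = TRUE)) / nfull^2
  c_ii <- acf_full[c((nfull - halfw + 1):nfull, 1:(halfw + 1))]
  den_emp_full <- Re(correlation_fft(c_ii, halfw, cfg$dt_sta, wf$keep)[, 1])
  den_ana_full <- ou_psd(wf$f, tau, sigma)
  den_full <- if (cfg$denominator == "analytic_psd") den_ana_full
              else den_emp_full
  den_centers <- as.numeric(fb$weights %*% den_full)

  smooth_gain <- function(c_cols) {
    num <- correlation_fft(c_cols, halfw, cfg$dt_sta, wf$keep)
    resp <- (fb$weights %*% num) / den_centers
    resp
  }

  c_grand <- env$sta_sum / t_tot_s
  response <- smooth_gain(c_grand)[, 1]

  list(env = env, freqs = wf$f, keep = wf$keep, fb = fb,
       den_full = den_full, den_centers = den_centers,
       den_analytic = den_ana_full, den_empirical = den_emp_full,
       t_tot_s = t_tot_s, smooth_gain = smooth_gain,
       response = response, centers = fb$centers)
}

#' Linear response function from an STA
#'
#' Implements the frequency-domain estimator: the Fourier transform of the
#' input-output correlation (`mean_rate * STA`, equal to the windowed
#' spike-summed current divided by total time) divided by the input power
#' spectrum -- the closed-form OU spectrum in `"analytic_psd"` mode, or the
#' windowed empirical input autocorrelation spectrum in `"empirical"` mode.
#' The complex numerator is denoised with the Gaussian filter bank before
#' division.
#'
#' @param sta A [compute_sta()] result.
#' @param ou The [ou_spec()] of the stimulus used.
#' @param config A [gain_config()].
#' @return A list with `frequencies` (Hz, filter-bank centers), `response`
#'   (complex) and `gain` (Hz/nA).
#' @export
linear_response <- function(sta, ou, config = gain_config()) {
  env <- sta$accumulator
  env$config$denominator <- config$denominator
  env$config$f_max <- config$f_max
  env$config$frac_width <- config$frac_width
  env$config$centers_per_decade <- config$centers_per_decade
  fin <- finalize_gain(env, ou$tau, ou$sigma)
  list(frequencies = fin$centers, response = fin$response,
       gain = Mod(fin$response))
}

#' Cyclic-shift significance threshold
#'
#' Runs the full estimation pipeline on surrogates in which all AP times of
#' a trial are cyclically shifted by the same random interval (drawn from
#' `config$shift_range`, per trial and per surrogate), realizing the null
#' hypothesis that spikes are independent of the input. The pointwise 95th
#' percentile over surrogates is the significance threshold curve.
#'
#' @param currents,spikes Paired lists of trials.
#' @param ou The stimulus [ou_spec()].
#' @param config A [gain_config()].
#' @param seed RNG seed for the random shifts.
#' @return A list with `frequencies` and `threshold` (Hz/nA).
#' @export
significance_threshold <- function(currents, spikes, ou,
                                   config = gain_config(), seed = 1) {
  cfg <- config
  cfg$n_trials <- length(currents)
  set.seed(seed)
  env <- new_gain_accumulator(cfg)
  for (i in seq_along(currents)) {
    add_gain_trial(env, currents[[i]]$samples, currents[[i]]$dt,
                   spikes[[i]]$spike_times - spikes[[i]]$burn_in)
  }
  fin <- finalize_gain(env, ou$tau, ou$sigma)
  list(frequencies = fin$centers,
       threshold = surrogate_threshold(fin))
}

# 95th percentile gain over the cyclic-shift surrogates.
surrogate_threshold <- function(fin, prob = 0.95) {
  env <- fin$env
  if (env$config$n_surrogates == 0) return(NULL)
  g <- Mod(fin$smooth_gain(fin$env$surr / fin$t_tot_s))
  apply(g, 1, stats::quantile, probs = prob, names = FALSE)
}

# Bootstrap confidence band from the stored group sums.
bootstrap_band <- function(fin, probs = c(0.025, 0.975)) {
  env <- fin$env
  g_n <- ncol(env$group_sums)
  if (g_n < 2) return(NULL)
  cfg <- env$config
  lo <- hi <- NULL
  chunks <- split(seq_len(cfg$n_resamples),
                  ceiling(seq_len(cfg$n_resamples) / 250))
  gains <- matrix(NA_real_, length(fin$centers), cfg$n_resamples)
  col0 <- 0L
  for (ch in chunks) {
    m <- stats::rmultinom(length(ch), g_n, rep(1 / g_n, g_n))
    c_b <- (env$group_sums %*% m) / fin$t_tot_s
    gains[, col0 + seq_along(ch)] <- Mod(fin$smooth_gain(c_b))
    col0 <- col0 + length(ch)
  }
  list(low = apply(gains, 1, stats::quantile, probs = probs[1],
                   names = FALSE),
       high = apply(gains, 1, stats::quantile, probs = probs[2],
                    names = FALSE))
}

#' Bootstrap confidence interval of a gain curve
#'
#' Trials are pooled into groups (`config$group_size` each, falling back to
#' per-trial groups when there are fewer than `group_size * n_groups`
#' trials); the grand average STA is bootstrap-resampled over groups
#' `config$n_resamples` times and the gain recomputed per resample;
#' pointwise 2.5/97.5 percentiles are returned.
#'
#' @param currents,spikes Paired lists of trials.
#' @param ou The stimulus [ou_spec()].
#' @param config A [gain_config()].
#' @param seed RNG seed for the resampling.
#' @return A list with `frequencies`, `ci_low`, `ci_high` (Hz/nA).
#' @export
bootstrap_ci <- function(currents, spikes, ou, config = gain_config(),
                         seed = 1) {
  cfg <- config
  cfg$n_trials <- length(currents)
  cfg$n_surrogates <- 0L
  env <- new_gain_accumulator(cfg)
  for (i in seq_along(currents)) {
    add_gain_trial(env, currents[[i]]$samples, currents[[i]]$dt,
                   spikes[[i]]$spike_times - spikes[[i]]$burn_in)
  }
  fin <- finalize_gain(env, ou$tau, ou$sigma)
  set.seed(seed)
  band <- bootstrap_band(fin)
  list(frequencies = fin$centers, ci_low = band$low, ci_high = band$high)
}

#' Cutoff frequency of a dynamic gain curve
#'
#' The frequency at which the gain has decayed by a factor of two from its
#' reference value. The reference is the gain at the lowest significant
#' frequency (or the curve maximum over the significant band with
#' `reference = "peak"`); the cutoff is the smallest frequency, log-linearly
#' interpolated between grid points, at which the gain falls to half the
#' reference and stays below for the next two grid points.
#'
#' @param curve A `gain_curve` (see [run_gain_pipeline()]) or a list with
#'   `frequencies`, `gain` and optionally `significant`.
#' @param reference `"lowest_significant"` or `"peak"`.
#' @return Cutoff frequency (Hz), or `NA` if the gain never decays to half
#'   the reference within the curve.
#' @export
cutoff_frequency <- function(curve,
                             reference = c("lowest_significant", "peak")) {
  reference <- match.arg(reference)
  f <- curve$frequencies
  g <- curve$gain
  sig <- curve$significant %||% rep(TRUE, length(g))
  if (!any(sig)) stop("gain curve entirely below the significance threshold")
  i0 <- if (reference == "peak") which.max(ifelse(sig, g, -Inf))
        else which(sig)[1]
  ref <- g[i0]
  target <- ref / 2
  n <- length(g)
  for (i in seq(i0 + 1, n)) {
    if (i > n) break
    below_next <- (i + 1 > n || g[i + 1] <= target) &&
      (i + 2 > n || g[i + 2] <= target)
    if (g[i] <= target && below_next) {
      lf <- log10(f[(i - 1):i])
      lg <- log10(g[(i - 1):i])
      return(10^(lf[1] + (lf[2] - lf[1]) *
                   (log10(target) - lg[1]) / (lg[2] - lg[1])))
    }
  }
  NA_real_
}

#' Log-log slope of the high-frequency gain decay
#'
#' Straight-line fit of `log10(gain)` against `log10(frequency)` over the
#' significant frequencies within `band`.
#'
#' @param curve A `gain_curve`.
#' @param band Frequency band (Hz).
#' @param significant_only Restrict to significant frequencies.
#' @return The fitted slope (dimensionless).
#' @export
gain_loglog_slope <- function(curve, band = c(30, 200),
                              significant_only = TRUE) {
  f <- curve$frequencies
  g <- curve$gain
  keep <- f >= band[1] & f <= band[2] & g > 0
  if (significant_only && !is.null(curve$significant))
    keep <- keep & curve$significant
  if (sum(keep) < 3) stop("fewer than 3 usable frequencies in the band")
  stats::coef(stats::lm(log10(g[keep]) ~ log10(f[keep])))[[2]]
}

# Assemble the public gain_curve object from a finalized accumulator.
make_gain_curve <- function(fin, tau, sigma, meta = list()) {
  gain <- Mod(fin$response)
  thr <- surrogate_threshold(fin)
  band <- bootstrap_band(fin)
  curve <- structure(list(
    frequencies = fin$centers, response = fin$response, gain = gain,
    ci_low = band$low %||% rep(NA_real_, length(gain)),
    ci_high = band$high %||% rep(NA_real_, length(gain)),
    significance = thr %||% rep(NA_real_, length(gain)),
    significant = if (is.null(thr)) rep(TRUE, length(gain)) else gain > thr,
    n_spikes = fin$env$n_all, mean_rate = fin$env$n_all / fin$t_tot_s,
    tau = tau, sigma = sigma, config = fin$env$config, meta = meta),
    class = "gain_curve")
  curve$cutoff_frequency <- tryCatch(cutoff_frequency(curve),
                                     error = function(e) NA_real_)
  curve
}

#' Estimate the dynamic gain from paired currents and spike trains
#'
#' Runs the complete estimation pipeline -- STA, Fourier transform,
#' filter-bank denoising, input-spectrum division, cyclic-shift significance
#' threshold and bootstrap confidence band -- on existing trials (from the
#' simulator or from the Poisson validation fixture).
#'
#' @param currents,spikes Paired lists of trials.
#' @param ou The stimulus [ou_spec()].
#' @param config A [gain_config()].
#' @param seed RNG seed (surrogate shifts and bootstrap resampling).
#' @return A `gain_curve` object.
#' @export
estimate_gain <- function(currents, spikes, ou, config = gain_config(),
                          seed = 1) {
  cfg <- config
  cfg$n_trials <- length(currents)
  set.seed(seed)
  env <- new_gain_accumulator(cfg)
  for (i in seq_along(currents)) {
    add_gain_trial(env, currents[[i]]$samples, currents[[i]]$dt,
                   spikes[[i]]$spike_times - spikes[[i]]$burn_in)
  }
  fin <- finalize_gain(env, ou$tau, ou$sigma)
  make_gain_curve(fin, ou$tau, ou$sigma)
}

#' Simulate trials and estimate the dynamic gain
#'
#' Orchestrates the production pipeline for a calibrated model variant:
#' per-trial OU stimulus generation (counter-based per-trial seeds),
#' simulation with detection and forced reset, streaming STA accumulation,
#' and the full gain estimation with significance threshold, bootstrap
#' confidence band and cutoff extraction.
#'
#' @param cell A [build_cell()] result.
#' @param policy A calibrated [reset_policy()].
#' @param mu,sigma Calibrated OU parameters (nA).
#' @param tau OU correlation time (ms).
#' @param config A [gain_config()].
#' @param seed Root seed; trial `i` uses `mix_seed(seed, i)`.
#' @param progress Print progress every this many trials (0 = silent).
#' @return A `gain_curve` object; `meta` carries the operating-point
#'   statistics actually realized (rate, CV) and the configuration.
#' @export
run_gain_pipeline <- function(cell, policy, mu, sigma, tau,
                              config = gain_config(), seed = 1,
                              progress = 0) {
  cfg <- config
  env <- new_gain_accumulator(cfg)
  n_steps <- round((cfg$trial_length + cfg$burn_in) / cfg$dt)
  isi <- c()
  for (i in seq_len(cfg$n_trials)) {
    ou <- ou_generate(ou_spec(mu, sigma, tau, cfg$dt,
                              seed = mix_seed(seed, i)), n_steps)
    r <- run_cell(cell, ou$samples, cfg$dt, policy = policy)
    st <- r$spike_times[r$spike_times > cfg$burn_in]
    isi <- c(isi, diff(st))
    add_gain_trial(env, ou$samples, cfg$dt, st - cfg$burn_in)
    if (progress > 0 && i %% progress == 0)
      message(sprintf("trial %d/%d (%d spikes)", i, cfg$n_trials,
                      env$n_all))
  }
  fin <- finalize_gain(env, tau, sigma)
  cv <- if (length(isi) >= 2) stats::sd(isi) / mean(isi) else NA_real_
  make_gain_curve(fin, tau, sigma,
                  meta = list(mu = mu, sigma = sigma, tau = tau, seed = seed,
                              rate = env$n_all / fin$t_tot_s, cv = cv))
}

#' @export
print.gain_curve <- function(x, ...) {
  cat("dynamic gain curve\n")
  cat(sprintf("  %d frequencies in [%.3g, %.3g] Hz, %d spikes (rate %.2f Hz)\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$n_spikes, x$mean_rate))
  cat(sprintf("  low-frequency gain %.3g Hz/nA, cutoff %.3g Hz\n",
              x$gain[which(x$significant)[1]], x$cutoff_frequency))
  invisible(x)
}

#' @export
as.data.frame.gain_curve <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies, gain = x$gain,
             ci_low = x$ci_low, ci_high = x$ci_high,
             significance = x$significance,
             significant_flag = x$significant)
}

#' Write a gain curve to CSV with a JSON sidecar
#'
#' @param curve A `gain_curve`.
#' @param path CSV output path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_gain_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  meta <- c(curve$meta,
            list(cutoff_frequency = curve$cutoff_frequency,
                 n_spikes = curve$n_spikes, mean_rate = curve$mean_rate,
                 tau = curve$tau, sigma = curve$sigma,
                 config = curve$config[setdiff(names(curve$config), "")]))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
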