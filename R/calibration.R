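#' Operating-point specification
#'
#' Dynamic gain curves are only comparable when the evoked AP trains have the
#' same statistics; models are therefore probed at a fixed operating point,
#' either (firing rate, ISI coefficient of variation) or (firing rate, fixed
#' stimulus standard deviation).
#'
#' @param target_rate Target mean firing rate (Hz).
#' @param rate_tolerance Tolerance on the rate (Hz).
#' @param target_cv Target coefficient of variation of the inter-spike
#'   interval distribution.
#' @param cv_tolerance Tolerance on the CV.
#' @param mode `"rate_and_cv"` or `"rate_and_fixed_std"`.
#' @param fixed_std Stimulus standard deviation (nA) for the
#'   `"rate_and_fixed_std"` mode.
#' @return An object of class `working_point`.
#' @export
working_point <- function(target_rate = 5, rate_tolerance = 0.25,
                          target_cv = 0.85, cv_tolerance = 0.05,
                          mode = c("rate_and_cv", "rate_and_fixed_std"),
                          fixed_std = NA) {
  mode <- match.arg(mode)
  stopifnot(target_rate > 0, rate_tolerance > 0, cv_tolerance > 0)
  if (mode == "rate_and_fixed_std") stopifnot(is.finite(fixed_std))
  structure(list(target_rate = target_rate,
                 rate_tolerance = rate_tolerance, target_cv = target_cv,
                 cv_tolerance = cv_tolerance, mode = mode,
                 fixed_std = fixed_std),
            class = "working_point")
}

#' Pooled firing rate and ISI coefficient of variation
#'
#' @param spikes A [spike_train()] or a list of them.
#' @return A list with `rate` (Hz, total spikes over total recorded time),
#'   `cv` (pooled over trials, intervals never spanning trial boundaries;
#'   `NA` if fewer than two intervals), `n_spikes` and `n_isi`.
#' @export
rate_cv <- function(spikes) {
  if (inherits(spikes, "spike_train")) spikes <- list(spikes)
  total_time <- sum(vapply(spikes, function(s) s$trial_duration, 0)) / 1000
  n_spikes <- sum(vapply(spikes, function(s) length(s$spike_times), 0L))
  isi <- unlist(lapply(spikes, function(s) diff(s$spike_times)))
  cv <- if (length(isi) >= 2) stats::sd(isi) / mean(isi) else NA_real_
  list(rate = n_spikes / total_time, cv = cv, n_spikes = n_spikes,
       n_isi = length(isi))
}

# Internal: rate/cv of one long OU-driven pilot run.
pilot_stats <- function(cell, policy, mu, sigma, tau, dt, duration, burn_in,
                        seed) {
  n <- round((duration + burn_in) / dt)
  ou <- ou_generate(ou_spec(mu, sigma, tau, dt, seed = seed), n)
  r <- run_cell(cell, ou$samples, dt, policy = policy)
  st <- r$spike_times[r$spike_times > burn_in]
  rate_cv(spike_train(st, trial_duration = duration, burn_in = burn_in,
                      seed = seed))
}

#' F-I curve under constant current
#'
#' @param cell A [build_cell()] result.
#' @param policy A [reset_policy()].
#' @param mu_values Constant currents (nA).
#' @param dt Integration step (ms).
#' @param duration Simulated time per point (ms).
#' @return A data.frame with `mu` and `rate` (Hz).
#' @export
fi_curve <- function(cell, policy, mu_values, dt = 0.05, duration = 10000) {
  rate <- vapply(mu_values, function(m)
    constant_current_rate(cell, policy, m, dt, duration), 0)
  data.frame(mu = mu_values, rate = rate)
}

#' Find OU stimulus parameters for a prescribed operating point
#'
#' Searches the OU mean and standard deviation that drive the model to the
#' working point, by nested one-dimensional bisection: the inner loop tunes
#' `mu` for the firing rate at fixed `sigma`; the outer loop tunes `sigma`
#' for the ISI CV (the CV is controlled almost exclusively by `sigma` once
#' the rate is matched). The returned point is verified on a held-out pilot
#' run with a fresh seed.
#'
#' @param cell A [build_cell()] result.
#' @param policy A [reset_policy()].
#' @param wp A [working_point()].
#' @param tau OU correlation time (ms).
#' @param dt Integration step (ms).
#' @param seed Root seed for the pilot simulations.
#' @param pilot_duration Simulated time per search evaluation (ms).
#' @param verify_duration Simulated time for the held-out verification (ms).
#' @param mu_hint,sigma_hint Optional starting guesses (nA).
#' @param max_iter Outer-loop iteration cap.
#' @return A list with `mu`, `sigma` (nA), `rate`, `cv` (from the held-out
#'   verification), `converged`, and the search trace `history`.
#' @export
find_operating_point <- function(cell, policy, wp = working_point(), tau = 5,
                                 dt = 0.05, seed = 1,
                                 pilot_duration = 100000,
                                 verify_duration = 500000,
                                 mu_hint = NULL, sigma_hint = NULL,
                                 max_iter = 25) {
  burn_in <- 500
  eval_i <- 0
  history <- list()
  evaluate <- function(mu, sigma) {
    eval_i <<- eval_i + 1
    st <- pilot_stats(cell, policy, mu, sigma, tau, dt, pilot_duration,
                      burn_in, mix_seed(seed, eval_i))
    history[[length(history) + 1]] <<- c(mu = mu, sigma = sigma,
                                         rate = st$rate, cv = st$cv)
    st
  }

  if (is.null(mu_hint)) {
    # Rheobase-level starting point from a short constant-current bisection.
    lo <- 0
    hi <- find_exciting_current(cell, dt)
    while (constant_current_rate(cell, policy, hi, dt, 5000) <
             wp$target_rate) hi <- hi * 1.5
    for (i in 1:12) {
      mid <- (lo + hi) / 2
      if (constant_current_rate(cell, policy, mid, dt, 5000) <
            wp$target_rate) lo <- mid else hi <- mid
    }
    mu_hint <- (lo + hi) / 2
  }

  tune_mu <- function(sigma, mu_start) {
    # Expand a bracket around mu_start, then bisect on the pilot rate.
    step <- max(0.2 * sigma, 0.005)
    lo <- mu_start
    st <- evaluate(lo, sigma)
    if (abs(st$rate - wp$target_rate) <= 0.6 * wp$rate_tolerance)
      return(list(mu = lo, stats = st))
    if (st$rate < wp$target_rate) {
      hi <- lo + step
      st_hi <- evaluate(hi, sigma)
      while (st_hi$rate < wp$target_rate) {
        lo <- hi
        hi <- hi + step
        st_hi <- evaluate(hi, sigma)
      }
      st <- st_hi
    } else {
      hi <- lo
      lo <- hi - step
      st <- evaluate(lo, sigma)
      while (st$rate > wp$target_rate) {
        hi <- lo
        lo <- lo - step
        st <- evaluate(lo, sigma)
      }
    }
    best <- list(mu = NA, stats = NULL, err = Inf)
    for (i in 1:10) {
      mid <- (lo + hi) / 2
      st <- evaluate(mid, sigma)
      err <- abs(st$rate - wp$target_rate)
      if (err < best$err) best <- list(mu = mid, stats = st, err = err)
      if (err <= 0.6 * wp$rate_tolerance) break
      if (st$rate < wp$target_rate) lo <- mid else hi <- mid
    }
    list(mu = best$mu, stats = best$stats)
  }

  if (wp$mode == "rate_and_fixed_std") {
    fit <- tune_mu(wp$fixed_std, mu_hint)
    mu <- fit$mu
    sigma <- wp$fixed_std
  } else {
    # Coarse phase: CV is monotone increasing in sigma at matched rate.
    sigma <- sigma_hint %||% 0.05
    s_lo <- NA
    s_hi <- NA
    mu <- mu_hint
    for (it in seq_len(max_iter)) {
      fit <- tune_mu(sigma, mu)
      mu <- fit$mu
      cv <- fit$stats$cv
      if (is.na(cv)) cv <- 0
      if (abs(cv - wp$target_cv) <= 0.8 * wp$cv_tolerance) break
      if (cv < wp$target_cv) s_lo <- sigma else s_hi <- sigma
      sigma <- if (is.na(s_lo)) sigma / 1.6
               else if (is.na(s_hi)) sigma * 1.6
               else (s_lo + s_hi) / 2
    }
  }

  # Polish phase: longer pilots beat the estimator noise of the short ones;
  # proportional corrections with damped empirical sensitivities
  # (d rate / d mu from the search history, d CV / d ln sigma ~ 0.35).
  h <- do.call(rbind, history)
  slope <- 300
  if (nrow(h) >= 2) {
    dmu <- diff(h[, "mu"])
    drate <- diff(h[, "rate"])
    ok <- which(abs(dmu) > 1e-4 & h[-1, "sigma"] == h[-nrow(h), "sigma"])
    if (length(ok)) slope <- stats::median(drate[ok] / dmu[ok])
  }
  slope <- min(max(slope, 50), 2000)
  long_dur <- 4 * pilot_duration
  polish <- list()
  best <- list(err = Inf)
  for (round in 1:6) {
    st <- pilot_stats(cell, policy, mu, sigma, tau, dt, long_dur, burn_in,
                      mix_seed(seed, 5000 + round))
    obs <- c(mu = mu, sigma = sigma, rate = st$rate, cv = st$cv)
    history[[length(history) + 1]] <- obs
    polish[[length(polish) + 1]] <- obs
    err <- abs(st$rate - wp$target_rate) / wp$rate_tolerance +
      if (wp$mode == "rate_and_cv" && !is.na(st$cv))
        abs(st$cv - wp$target_cv) / wp$cv_tolerance else 0
    if (err < best$err) best <- list(err = err, mu = mu, sigma = sigma)
    rate_ok <- abs(st$rate - wp$target_rate) <= 0.6 * wp$rate_tolerance
    cv_ok <- wp$mode == "rate_and_fixed_std" ||
      (!is.na(st$cv) && abs(st$cv - wp$target_cv) <= 0.5 * wp$cv_tolerance)
    if (rate_ok && cv_ok) {
      best <- list(err = err, mu = mu, sigma = sigma)
      break
    }
    sigma_old <- sigma
    if (wp$mode == "rate_and_cv") {
      # Local regression of CV on log sigma over the long evaluations;
      # proportional fallback (dCV/dln sigma ~ 0.4) until two usable points.
      ph <- do.call(rbind, polish)
      b <- NA
      if (nrow(ph) >= 2 && diff(range(log(ph[, "sigma"]))) > 0.04) {
        fit <- stats::lm(ph[, "cv"] ~ log(ph[, "sigma"]))
        b <- stats::coef(fit)[[2]]
      }
      if (!is.finite(b) || b < 0.15 || b > 1.5) b <- 0.4
      fac <- exp((wp$target_cv - st$cv) / b)
      sigma <- sigma * min(max(fac, 0.75), 1.35)
    }
    # Rate correction, with a cross-term compensating the sigma change
    # (at fixed rate, mu trades against sigma with slope ~ 0.35).
    mu <- mu + (wp$target_rate - st$rate) / slope -
      0.35 * (sigma - sigma_old)
  }
  mu <- best$mu
  sigma <- best$sigma

  st <- pilot_stats(cell, policy, mu, sigma, tau, dt, verify_duration,
                    burn_in, mix_seed(seed, 99991))
  converged <- abs(st$rate - wp$target_rate) <= wp$rate_tolerance &&
    (wp$mode == "rate_and_fixed_std" ||
       abs(st$cv - wp$target_cv) <= wp$cv_tolerance)
  list(mu = mu, sigma = sigma, rate = st$rate, cv = st$cv,
       converged = converged,
       history = do.call(rbind, history))
}
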