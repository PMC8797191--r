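#' Initial cell state
#'
#' @param cell A [build_cell()] result.
#' @param v Uniform initial voltage (mV); defaults to the leak reversal.
#' @return An object of class `cell_state` with fields `voltages`, `m`,
#'   `time`.
#' @export
cell_state <- function(cell, v = cell$passive$leak_reversal) {
  structure(list(voltages = rep(v, length(cell$cap)),
                 m = m_inf(v, cell$sodium), time = 0),
            class = "cell_state")
}

# Low-level wrapper around the compiled integrator. All indices 1-based on the
# R side. `policy = NULL` disables detection and reset.
run_cell <- function(cell, stim, dt, policy = NULL, state = NULL,
                     record_nodes = integer(0), record_every = 0,
                     do_reset = !is.null(policy),
                     stop_at_detect = FALSE, relax_tol = 0,
                     clamp_node = NULL, clamp_vals = numeric(0)) {
  if (is.null(state)) state <- cell_state(cell)
  do_detect <- !is.null(policy)
  det <- if (do_detect) policy$detection_threshold else 1e9
  rth <- if (do_detect) policy$reset_threshold else 1e9
  rv <- if (do_detect) policy$reset_voltage else cell$passive$leak_reversal
  m_reset <- if (do_detect) m_inf(policy$gating_reset_voltage, cell$sodium)
             else 0
  res <- cpp_simulate(cell$cap, cell$gleak, cell$gax,
                      cell$passive$leak_reversal,
                      cell$injection_node - 1L, cell$na_node - 1L,
                      cell$gbar, cell$sodium$reversal,
                      cell$sodium$half_activation, cell$sodium$slope,
                      cell$sodium$activation_time_constant,
                      stim, dt, det, rth, rv, m_reset,
                      do_reset && do_detect, do_detect, stop_at_detect,
                      state$voltages, state$m,
                      as.integer(record_nodes) - 1L, as.integer(record_every),
                      relax_tol,
                      if (is.null(clamp_node)) -1L else
                        as.integer(clamp_node) - 1L,
                      clamp_vals)
  res$state <- structure(list(voltages = res$v, m = res$m,
                              time = state$time + res$steps_done * dt),
                         class = "cell_state")
  res
}

#' Advance the cell state by one backward-Euler step
#'
#' The gating variable is advanced by exact exponential relaxation toward
#' `m_inf` of the pre-step axonal voltage; voltages are then advanced by an
#' implicit tridiagonal solve with the sodium conductance `gbar * m` held at
#' its updated value.
#'
#' @param cell A [build_cell()] result.
#' @param state A [cell_state()].
#' @param i_inj Injected current at the injection node (nA).
#' @param dt Time step (ms).
#' @return The advanced `cell_state`.
#' @export
step_cell <- function(cell, state, i_inj, dt) {
  stopifnot(dt > 0)
  run_cell(cell, stim = i_inj, dt = dt, state = state)$state
}

#' Simulate one trial with AP detection and forced reset
#'
#' Integrates the cell driven by `stimulus` injected at the soma middle.
#' APs are detected at the upward crossing of the detection threshold (spike
#' time linearly interpolated between samples); upon crossing the reset
#' threshold all node voltages are reset to the policy's reset voltage and the
#' gating variable to `m_inf` of the gating reset voltage. Spikes during the
#' burn-in period are discarded.
#'
#' @param cell A [build_cell()] result.
#' @param stimulus A [stimulus_trace()] covering `burn_in` plus the recorded
#'   duration.
#' @param policy A [reset_policy()], or `NULL` for a passive/no-detection run.
#' @param record_nodes Node indices to record (default: soma middle and the
#'   sodium node).
#' @param record_every Record every this many integration steps (0 disables
#'   trace recording).
#' @param burn_in Discarded initial period (ms).
#' @param state Optional initial [cell_state()].
#' @return A list with `spikes` (a [spike_train()]), `traces` (data.frame
#'   `time` plus one column per recorded node, or `NULL`), `latencies`
#'   (detect-to-reset delays, ms) and the final `state`.
#' @export
simulate_trial <- function(cell, stimulus, policy,
                           record_nodes = c(cell$injection_node,
                                            cell$na_node),
                           record_every = 1, burn_in = 500, state = NULL) {
  stopifnot(inherits(stimulus, "stimulus_trace"))
  dt <- stimulus$dt
  total <- length(stimulus$samples) * dt
  if (total <= burn_in) stop("stimulus shorter than the burn-in period")
  res <- run_cell(cell, stimulus$samples, dt, policy = policy, state = state,
                  record_nodes = record_nodes, record_every = record_every)
  st <- res$spike_times[res$spike_times > burn_in]
  spikes <- spike_train(st, trial_duration = total - burn_in,
                        burn_in = burn_in, seed = stimulus$seed %||% NA)
  traces <- NULL
  if (record_every > 0) {
    traces <- data.frame(time = res$rec_t)
    for (j in seq_along(record_nodes))
      traces[[paste0("node_", record_nodes[j])]] <- res$rec[, j]
  }
  list(spikes = spikes, traces = traces, latencies = res$latencies,
       state = res$state)
}

#' Self-convergence check of spike times under grid refinement
#'
#' Simulates the same Ornstein-Uhlenbeck current realization at the working
#' resolution and at halved `dt` and spatial steps, and reports the largest
#' per-spike timing shift. Used to validate coarsened desk-scale grids before
#' production runs.
#'
#' @param morph,passive,sodium Model specs (the morphology's `dx`/`soma_dx`
#'   define the working resolution).
#' @param policy A [reset_policy()].
#' @param mu,sigma,tau OU stimulus parameters (nA, nA, ms).
#' @param duration Simulated time (ms), burn-in included. Kept short by
#'   default: near-threshold trajectories of the fluctuation-driven model
#'   amplify any perturbation, so over long horizons even converged grids
#'   decorrelate spike by spike.
#' @param dt Working time step (ms).
#' @param seed RNG seed for the OU realization.
#' @return A list with `median_shift_ms`, `frac_matched` (fraction of
#'   spikes matched across resolutions within `match_tol`), `n_matched`,
#'   and the two spike vectors.
#' @param match_tol Matching tolerance (ms).
#' @export
convergence_check <- function(morph, passive, sodium, policy, mu, sigma, tau,
                              duration = 2000, dt = 0.05, seed = 1,
                              match_tol = 1) {
  fine_morph <- morphology_spec(morph$soma_diameter, morph$soma_length,
                                morph$axon_diameter, morph$axon_length,
                                morph$x_na, dx = morph$dx / 2,
                                soma_dx = morph$soma_dx / 2)
  coarse <- build_cell(morph, passive, sodium)
  fine <- build_cell(fine_morph, passive, sodium)
  n_fine <- ceiling(duration / (dt / 2))
  ou <- ou_generate(ou_spec(mu, sigma, tau, dt = dt / 2, seed = seed), n_fine)
  x_fine <- ou$samples
  x_coarse <- 0.5 * (x_fine[seq(1, n_fine - 1, by = 2)] +
                     x_fine[seq(2, n_fine, by = 2)])
  r_coarse <- run_cell(coarse, x_coarse, dt, policy = policy)
  r_fine <- run_cell(fine, x_fine, dt / 2, policy = policy)
  s1 <- r_coarse$spike_times
  s2 <- r_fine$spike_times
  # Greedy nearest-neighbour matching, so one extra/missing spike does not
  # poison the comparison of all later spikes.
  shifts <- c()
  used <- rep(FALSE, length(s2))
  for (t1 in s1) {
    d <- abs(s2 - t1)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= match_tol) {
      shifts <- c(shifts, d[j])
      used[j] <- TRUE
    }
  }
  n_total <- max(length(s1), length(s2))
  list(median_shift_ms = if (length(shifts)) stats::median(shifts)
                         else NA_real_,
       frac_matched = if (n_total > 0) length(shifts) / n_total
                      else NA_real_,
       n_matched = length(shifts), coarse_spikes = s1, fine_spikes = s2)
}
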