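#' Thevenin reduction of the clamped passive cable at the sodium node
#'
#' With the somatic voltage clamped, the passive structure seen from the
#' sodium node is reduced to an affine current-voltage relation: the net
#' current drawn from the sodium node (axial plus local leak) is
#' `I_lat(V) = conductance * V + offset = (V - v_open) / r_th`. Computed
#' exactly from two linear solves of the clamped passive cable (unit current
#' and zero current at the sodium node).
#'
#' @param cell A [build_cell()] result (its sodium conductance is excluded
#'   from the reduction).
#' @param v_soma_clamp Clamped somatic voltage (mV), applied at the injection
#'   node.
#' @return A list with `conductance` (uS), `offset` (nA), `v_open` (the
#'   stationary sodium-node voltage with zero sodium current, mV) and `r_th`
#'   (MOhm).
#' @export
lateral_current_line <- function(cell, v_soma_clamp) {
  k <- cell$na_node
  v0 <- passive_steady_state(cell, 0, clamp_node = cell$injection_node,
                             clamp_value = v_soma_clamp)
  iu <- numeric(length(cell$cap))
  iu[k] <- 1
  v1 <- passive_steady_state(cell, iu, clamp_node = cell$injection_node,
                             clamp_value = v_soma_clamp)
  r_th <- v1[k] - v0[k]
  list(conductance = 1 / r_th, offset = -v0[k] / r_th, v_open = v0[k],
       r_th = r_th)
}

# Net current balance at the sodium node: sodium influx minus lateral outflow.
# Roots are the stationary axonal voltages for the clamped cell.
na_balance <- function(v, cell, lat) {
  cell$gbar * m_inf(v, cell$sodium) * (cell$sodium$reversal - v) -
    (v - lat$v_open) / lat$r_th
}

#' Stationary axonal voltages under somatic voltage clamp
#'
#' Finds all equilibria of the axonal voltage at the sodium node with the
#' somatic voltage clamped: roots of the sodium current versus lateral
#' current balance, located by sign-change bracketing on `[-80, 60]` mV and
#' polished with [stats::uniroot()]. Stability follows from the sign of the
#' derivative of the net current at the root.
#'
#' @param cell A [build_cell()] result.
#' @param v_soma_clamp Clamped somatic voltage (mV).
#' @param v_range Search interval for the axonal voltage (mV).
#' @param grid_step Bracketing grid step (mV).
#' @return A list of class `equilibrium_set` with `v_soma_clamp`,
#'   `equilibria` (data.frame `voltage`, `stable`) and `lateral` (the
#'   [lateral_current_line()] reduction).
#' @export
axonal_equilibria <- function(cell, v_soma_clamp, v_range = c(-80, 60),
                              grid_step = 0.02) {
  lat <- lateral_current_line(cell, v_soma_clamp)
  grid <- seq(v_range[1], v_range[2], by = grid_step)
  fv <- na_balance(grid, cell, lat)
  roots <- numeric(0)
  sgn <- sign(fv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    r <- stats::uniroot(na_balance, c(grid[i], grid[i + 1]), cell = cell,
                        lat = lat, tol = 1e-12)
    roots <- c(roots, r$root)
  }
  # Exact zeros on the grid (rare) count as roots too.
  roots <- sort(unique(c(roots, grid[fv == 0])))
  eps <- 1e-6
  stable <- vapply(roots, function(v) {
    (na_balance(v + eps, cell, lat) - na_balance(v - eps, cell, lat)) < 0
  }, logical(1))
  structure(list(v_soma_clamp = v_soma_clamp,
                 equilibria = data.frame(voltage = roots, stable = stable),
                 lateral = lat),
            class = "equilibrium_set")
}

# Does any clamped somatic voltage in the range yield three equilibria?
has_three_equilibria <- function(cell, v_soma_values) {
  for (v in v_soma_values) {
    if (nrow(axonal_equilibria(cell, v)$equilibria) >= 3) return(TRUE)
  }
  FALSE
}

#' Clamp-voltage window with three coexisting axonal equilibria
#'
#' Because the Thevenin reduction is affine in the clamped somatic voltage,
#' the clamp value at which a given axonal voltage is stationary is a smooth
#' scalar function `Vc(V)`; three equilibria coexist exactly for clamp values
#' strictly between its local extrema (the two folds). This locates the
#' bistable window without gridding the clamp voltage.
#'
#' @param cell A [build_cell()] result.
#' @param v_probe Axonal voltage range scanned for folds (mV).
#' @param dv Scan resolution (mV).
#' @return `c(lower, upper)` clamp voltages bounding the bistable window
#'   (mV), or `NULL` if the equilibrium is unique for every clamp value.
#' @export
bistable_clamp_window <- function(cell, v_probe = c(-75, 20), dv = 0.005) {
  lat1 <- lateral_current_line(cell, -60)
  lat2 <- lateral_current_line(cell, -50)
  beta <- (lat2$v_open - lat1$v_open) / 10
  alpha <- lat1$v_open + 60 * beta
  r_th <- lat1$r_th
  v <- seq(v_probe[1], v_probe[2], by = dv)
  i_na <- cell$gbar * m_inf(v, cell$sodium) * (cell$sodium$reversal - v)
  vc <- (v - r_th * i_na - alpha) / beta
  d <- sign(diff(vc))
  flips <- which(d[-1] * d[-length(d)] < 0) + 1
  if (!length(flips)) return(NULL)
  c(min(vc[flips]), max(vc[flips]))
}

#' Critical sodium-channel distance for axonal bistability
#'
#' Smallest distance `x_na` of the sodium point conductance from the soma for
#' which some clamped somatic voltage in `v_soma_range` yields three
#' coexisting axonal equilibria. Located by bisection on `x_na` to `xtol`,
#' rebuilding the cell with a fine axonal grid at each candidate distance and
#' testing for a non-empty [bistable_clamp_window()] intersecting the clamp
#' range (so the result does not depend on a clamp-voltage grid step).
#'
#' @param morph,passive,sodium Model specs (the morphology's `x_na` is
#'   ignored).
#' @param v_soma_range Clamped somatic voltage range considered (mV).
#' @param x_bracket Initial bracket for `x_na` (um).
#' @param xtol Bisection tolerance (um).
#' @param dx_axon Axonal grid step used for the scan (um); fine by default so
#'   the sodium site lands within `xtol` of the requested position.
#' @return Critical distance (um).
#' @export
critical_distance <- function(morph = morphology_spec(),
                              passive = passive_spec(),
                              sodium = sodium_spec(),
                              v_soma_range = c(-60, -50),
                              x_bracket = c(5, 60), xtol = 0.1,
                              dx_axon = 0.1) {
  probe <- function(x) {
    m <- morphology_spec(morph$soma_diameter, morph$soma_length,
                         morph$axon_diameter, morph$axon_length,
                         x_na = x, dx = dx_axon, soma_dx = morph$soma_dx)
    w <- bistable_clamp_window(build_cell(m, passive, sodium))
    !is.null(w) && w[1] < v_soma_range[2] && w[2] > v_soma_range[1]
  }
  lo <- x_bracket[1]
  hi <- x_bracket[2]
  if (probe(lo)) return(lo)
  if (!probe(hi))
    stop("no multistability for any x_na in the scanned bracket")
  while (hi - lo > xtol) {
    mid <- (lo + hi) / 2
    if (probe(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Quasi-static somatic voltage-clamp sweep
#'
#' For each clamped somatic voltage, relaxes the full model (sodium active)
#' to stationarity by time-domain integration, carrying the state from one
#' clamp value to the next so the sweep follows a branch and inherits its
#' hysteresis. The stationary axonal voltage is recorded per clamp value.
#'
#' @param cell A [build_cell()] result.
#' @param v_soma_values Clamped somatic voltages (mV), in sweep order.
#' @param dt Integration step (ms).
#' @param step_budget Maximum simulated time per clamp value (ms).
#' @param relax_tol Stationarity criterion on `|dV/dt|` (mV/ms).
#' @return A data.frame with `v_soma`, `v_axon`, `converged`.
#' @export
vclamp_sweep <- function(cell, v_soma_values, dt = 0.025, step_budget = 500,
                         relax_tol = 1e-6) {
  state <- cell_state(cell)
  n_steps <- round(step_budget / dt)
  out <- data.frame(v_soma = v_soma_values, v_axon = NA_real_,
                    converged = NA)
  for (i in seq_along(v_soma_values)) {
    v <- v_soma_values[i]
    state$voltages[cell$injection_node] <- v
    res <- run_cell(cell, stim = rep(0, n_steps), dt = dt, state = state,
                    relax_tol = relax_tol, clamp_node = cell$injection_node,
                    clamp_vals = v)
    state <- res$state
    out$v_axon[i] <- state$voltages[cell$na_node]
    out$converged[i] <- res$converged
  }
  out
}

#' Locate the discontinuity in an upward voltage-clamp sweep
#'
#' @param sweep A [vclamp_sweep()] result for an increasing clamp sequence.
#' @param min_jump Smallest axonal voltage change between consecutive clamp
#'   values counted as a discontinuity (mV).
#' @return The somatic voltage at the jump (midpoint of the bracketing clamp
#'   values, mV), or `NA` if the sweep is continuous.
#' @export
sweep_jump_voltage <- function(sweep, min_jump = 5) {
  d <- diff(sweep$v_axon)
  i <- which(d > min_jump)
  if (!length(i)) return(NA_real_)
  (sweep$v_soma[i[1]] + sweep$v_soma[i[1] + 1]) / 2
}

#' Bifurcation scan over sodium-channel positions
#'
#' @param morph,passive,sodium Model specs.
#' @param x_na_values Sodium positions to scan (um).
#' @param v_soma_values Clamped somatic voltages (mV).
#' @return A list of class `bifurcation_scan` with `branches` (data.frame
#'   `x_na`, `v_soma`, `voltage`, `stable`), `critical_distance` (um) and
#'   `jump_voltage` per scanned `x_na` (fold voltage, mV; `NA` below the
#'   critical distance).
#' @export
bifurcation_scan <- function(morph = morphology_spec(),
                             passive = passive_spec(),
                             sodium = sodium_spec(),
                             x_na_values = seq(10, 60, by = 5),
                             v_soma_values = seq(-60, -50, by = 0.25)) {
  rows <- list()
  jumps <- rep(NA_real_, length(x_na_values))
  for (j in seq_along(x_na_values)) {
    m <- morphology_spec(morph$soma_diameter, morph$soma_length,
                         morph$axon_diameter, morph$axon_length,
                         x_na = x_na_values[j], dx = morph$dx,
                         soma_dx = morph$soma_dx)
    cell <- build_cell(m, passive, sodium)
    three_at <- c()
    for (v in v_soma_values) {
      eq <- axonal_equilibria(cell, v)
      rows[[length(rows) + 1]] <- data.frame(
        x_na = x_na_values[j], v_soma = v, voltage = eq$equilibria$voltage,
        stable = eq$equilibria$stable)
      if (nrow(eq$equilibria) >= 3) three_at <- c(three_at, v)
    }
    if (length(three_at)) jumps[j] <- max(three_at)
  }
  crit <- critical_distance(morph, passive, sodium,
                            v_soma_range = range(v_soma_values))
  structure(list(branches = do.call(rbind, rows),
                 critical_distance = crit,
                 x_na = x_na_values, jump_voltage = jumps),
            class = "bifurcation_scan")
}

#' Current-clamp ramp: axo-somatic decoupling trajectory
#'
#' Injects a slow current ramp at the soma (no forced reset) and records the
#' somatic and axonal voltages up to the first detection-threshold crossing,
#' exposing the gradual voltage decoupling that replaces the voltage-clamp
#' discontinuity in the dynamic case.
#'
#' @param cell A [build_cell()] result.
#' @param ramp A [slow_ramp()] stimulus.
#' @param detection_threshold Axonal voltage ending the run (mV).
#' @param record_every Recording decimation in integration steps.
#' @param max_drift Largest admissible quasi-static somatic drift (mV/ms);
#'   the ramp slope times the somatic input resistance must stay below it.
#' @return A data.frame with `time`, `v_soma`, `v_axon`.
#' @export
cclamp_ramp <- function(cell, ramp, detection_threshold = 0,
                        record_every = 10, max_drift = 0.5) {
  stopifnot(inherits(ramp, "stimulus_trace"), ramp$kind == "ramp")
  slope <- (ramp$params$end - ramp$params$start) / ramp$params$duration
  drift <- abs(slope) * input_resistance(cell)
  if (drift > max_drift)
    stop(sprintf("ramp too fast for quasi-static analysis: %.2f mV/ms",
                 drift))
  pol <- reset_policy(detection_threshold, detection_threshold + 1)
  res <- run_cell(cell, ramp$samples, ramp$dt, policy = pol,
                  do_reset = FALSE, stop_at_detect = TRUE,
                  record_nodes = c(cell$injection_node, cell$na_node),
                  record_every = record_every)
  data.frame(time = res$rec_t, v_soma = res$rec[, 1], v_axon = res$rec[, 2])
}
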