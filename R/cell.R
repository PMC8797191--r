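#' Build the spatially discretized cell
#'
#' Discretizes the soma and axon cylinders into a chain of nodes at segment
#' centers. Per-node membrane area is `pi * d * dx` for the node's section;
#' axial coupling between adjacent node centers is `(pi d^2 / 4) / (R_a dx)`;
#' the soma-axon junction edge uses the series combination of the two
#' half-segments' axial resistances. The sodium conductance is attached as an
#' absolute point conductance at the axon node nearest `x_na` (ties broken
#' toward the soma). Internal unit system: mV, ms, nA, uS, nF, um.
#'
#' @param morph A [morphology_spec()].
#' @param passive A [passive_spec()].
#' @param sodium A [sodium_spec()].
#' @return An object of class `discretized_cell` with fields
#'   `node_positions` (um; soma nodes at negative coordinates, axon nodes at
#'   positive coordinates, junction at 0), `cap` (nF), `gleak` (uS), `gax`
#'   (uS, per edge), `injection_node`, `na_node`, `n_soma`, `n_axon`,
#'   `gbar` (uS) and the three spec records.
#' @export
build_cell <- function(morph = morphology_spec(), passive = passive_spec(),
                       sodium = sodium_spec()) {
  stopifnot(inherits(morph, "morphology_spec"),
            inherits(passive, "passive_spec"),
            inherits(sodium, "sodium_spec"))
  n_soma <- max(1L, round(morph$soma_length / morph$soma_dx))
  n_axon <- max(1L, round(morph$axon_length / morph$dx))
  dx_s <- morph$soma_length / n_soma
  dx_a <- morph$axon_length / n_axon

  pos_soma <- -morph$soma_length + (seq_len(n_soma) - 0.5) * dx_s
  pos_axon <- (seq_len(n_axon) - 0.5) * dx_a
  pos <- c(pos_soma, pos_axon)
  n <- n_soma + n_axon

  # Membrane areas in cm^2 (1 um^2 = 1e-8 cm^2).
  area_s <- pi * morph$soma_diameter * dx_s * 1e-8
  area_a <- pi * morph$axon_diameter * dx_a * 1e-8
  area <- c(rep(area_s, n_soma), rep(area_a, n_axon))

  rm_node <- rep(passive$specific_membrane_resistance, n)
  cm_node <- rep(passive$specific_capacitance, n)
  for (ov in passive$region_overrides) {
    if (ov$end > morph$axon_length)
      stop("region override extends beyond the axon")
    sel <- c(rep(FALSE, n_soma), pos_axon >= ov$start & pos_axon <= ov$end)
    rm_node[sel] <- rm_node[sel] * ov$rm_factor
    cm_node[sel] <- cm_node[sel] * ov$cm_factor
  }

  cap <- cm_node * area * 1e3     # uF/cm^2 * cm^2 -> uF -> nF
  gleak <- area / rm_node * 1e6   # S -> uS

  # Axial resistances: R_a [Ohm cm] = 1e4 Ohm um; cross-sections in um^2.
  ra_um <- passive$axial_resistivity * 1e4
  xs_s <- pi * morph$soma_diameter^2 / 4
  xs_a <- pi * morph$axon_diameter^2 / 4
  r_edge <- numeric(n - 1)
  if (n_soma > 1) r_edge[seq_len(n_soma - 1)] <- ra_um * dx_s / xs_s
  if (n_axon > 1)
    r_edge[(n_soma + 1):(n - 1)] <- ra_um * dx_a / xs_a
  r_edge[n_soma] <- ra_um * (dx_s / 2) / xs_s + ra_um * (dx_a / 2) / xs_a
  gax <- 1e6 / r_edge             # Ohm -> uS

  injection_node <- ceiling(n_soma / 2)
  na_node <- n_soma + which.min(abs(pos_axon - morph$x_na))

  structure(list(node_positions = pos, cap = cap, gleak = gleak, gax = gax,
                 injection_node = injection_node, na_node = na_node,
                 n_soma = n_soma, n_axon = n_axon,
                 gbar = sodium$peak_conductance * 1e6,
                 morphology = morph, passive = passive, sodium = sodium),
            class = "discretized_cell")
}

#' @export
print.discretized_cell <- function(x, ...) {
  cat("discretized ball-and-stick cell\n")
  cat(sprintf("  nodes: %d soma + %d axon\n", x$n_soma, x$n_axon))
  cat(sprintf("  injection node %d (x = %.1f um), sodium node %d (x = %.1f um)\n",
              x$injection_node, x$node_positions[x$injection_node],
              x$na_node, x$node_positions[x$na_node]))
  cat(sprintf("  gbar = %.3g uS, E_L = %g mV\n", x$gbar,
              x$passive$leak_reversal))
  invisible(x)
}

#' Stationary voltage profile of the passive cell
#'
#' Directly solves the stationary linear system `G V = b` of the passive
#' (sodium excluded) discretized cell, optionally with one node voltage
#' clamped (Dirichlet condition).
#'
#' @param cell A [build_cell()] result.
#' @param i_inj Injected current (nA): a scalar applied at the injection node,
#'   or a vector of per-node currents.
#' @param clamp_node Optional node index held at `clamp_value`.
#' @param clamp_value Clamp voltage (mV).
#' @return Per-node stationary voltage (mV).
#' @export
passive_steady_state <- function(cell, i_inj = 0, clamp_node = NULL,
                                 clamp_value = NULL) {
  n <- length(cell$cap)
  if (length(i_inj) == 1) {
    b_inj <- numeric(n)
    b_inj[cell$injection_node] <- i_inj
  } else {
    stopifnot(length(i_inj) == n)
    b_inj <- i_inj
  }
  # Solve in deviation form U = V - E_L, so the resting state is exact and
  # the large axial/leak conductance ratio does not amplify roundoff.
  e_l <- cell$passive$leak_reversal
  diag <- cell$gleak
  low <- c(0, cell$gax)
  up <- c(cell$gax, 0)
  diag[seq_len(n - 1)] <- diag[seq_len(n - 1)] + cell$gax
  diag[2:n] <- diag[2:n] + cell$gax
  rhs <- b_inj
  low <- -low
  up <- -up
  if (!is.null(clamp_node)) {
    diag[clamp_node] <- 1
    low[clamp_node] <- 0
    up[clamp_node] <- 0
    rhs[clamp_node] <- clamp_value - e_l
  }
  e_l + as.numeric(cpp_tridiag_solve(low, diag, up, rhs))
}

#' Somatic input resistance of the passive cell
#'
#' @param cell A [build_cell()] result.
#' @param node Node at which to measure (defaults to the injection node).
#' @return Input resistance (MOhm).
#' @export
input_resistance <- function(cell, node = cell$injection_node) {
  n <- length(cell$cap)
  i0 <- numeric(n)
  i0[node] <- 1  # 1 nA
  v1 <- passive_steady_state(cell, i0)
  v0 <- passive_steady_state(cell, 0)
  (v1[node] - v0[node])  # mV / nA = MOhm
}
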