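#' Passive transfer impedance by sinusoidal probing
#'
#' Injects sinusoidal currents at the soma middle of a purely passive cell
#' (sodium peak conductance zero) and measures the voltage amplitude at a
#' probe position on the axon. Per frequency, at least `transient_cycles`
#' initial cycles are discarded and `measure_cycles` full cycles analyzed;
#' the impedance is the amplitude ratio at the stimulus frequency bin of the
#' Fourier transform.
#'
#' @param cell A passive [build_cell()] result (`gbar` must be 0).
#' @param frequencies Probe frequencies (Hz).
#' @param probe Probe position on the axon (um from the junction).
#' @param amplitude Stimulus amplitude (nA).
#' @param dt Integration step (ms).
#' @param transient_cycles,measure_cycles Discarded and analyzed cycles.
#' @param min_duration Minimum analyzed stretch (ms), so high frequencies
#'   still average over a reasonable time.
#' @return An object of class `impedance_curve`: data.frame with
#'   `frequency_hz` and `impedance_mohm`, plus attribute `probe`.
#' @export
transfer_impedance_sine <- function(cell, frequencies, probe = 40,
                                    amplitude = 0.01, dt = 0.025,
                                    transient_cycles = 5,
                                    measure_cycles = 10,
                                    min_duration = 200) {
  if (cell$gbar != 0)
    stop("transfer_impedance_sine expects a passive cell (gbar = 0)")
  node <- cell$n_soma +
    which.min(abs(cell$node_positions[-seq_len(cell$n_soma)] - probe))
  z <- vapply(frequencies, function(f) {
    period <- 1000 / f
    n_cyc <- max(measure_cycles, ceiling(min_duration / period))
    n_meas <- round(n_cyc * period / dt)
    n_trans <- round(transient_cycles * period / dt)
    stim <- sinusoid(amplitude, f, 0, dt, n_trans + n_meas)
    r <- run_cell(cell, stim$samples, dt, record_nodes = node,
                  record_every = 1)
    v <- r$rec[-seq_len(n_trans + 1), 1]
    n <- length(v)
    k <- round(f * n * dt / 1000)
    vamp <- 2 * Mod(stats::fft(v - mean(v))[k + 1]) / n
    vamp / amplitude
  }, 0)
  structure(data.frame(frequency_hz = frequencies, impedance_mohm = z),
            probe = probe, class = c("impedance_curve", "data.frame"))
}

#' Transfer impedance from fluctuating (OU) input
#'
#' Injects an OU current at the soma and computes the Welch-averaged
#' cross-spectrum between input current and probe voltage divided by the
#' input power spectrum. Works on the intact (active) model -- as used for
#' the sub-threshold characterization of stimulus filtering -- or on a
#' passive cell.
#'
#' @param cell A [build_cell()] result.
#' @param ou An [ou_spec()].
#' @param probe Probe position on the axon (um).
#' @param duration Simulated time (ms).
#' @param segment Welch segment length (ms).
#' @param rec_dt Recording step (ms); must be a multiple of `ou$dt`.
#' @param f_max Upper frequency (Hz).
#' @return An `impedance_curve` data.frame.
#' @export
transfer_impedance_ou <- function(cell, ou, probe = 40, duration = 100000,
                                  segment = 4000, rec_dt = 0.25,
                                  f_max = 1000) {
  node <- cell$n_soma +
    which.min(abs(cell$node_positions[-seq_len(cell$n_soma)] - probe))
  every <- round(rec_dt / ou$dt)
  n <- round(duration / ou$dt)
  tr <- ou_generate(ou, n)
  r <- run_cell(cell, tr$samples, ou$dt, record_nodes = node,
                record_every = every)
  v <- r$rec[-1, 1]
  i_in <- tr$samples[seq(every, n, by = every)][seq_along(v)]
  nseg <- round(segment / rec_dt)
  n_use <- (length(v) %/% nseg) * nseg
  vmat <- matrix(v[seq_len(n_use)] - mean(v), nseg)
  imat <- matrix(i_in[seq_len(n_use)] - mean(i_in), nseg)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / nseg)
  fv <- stats::mvfft(vmat * win)
  fi <- stats::mvfft(imat * win)
  cross <- rowMeans(Conj(fi) * fv)
  pow <- rowMeans(Mod(fi)^2)
  f <- (seq_len(nseg) - 1) / (nseg * rec_dt / 1000)
  keep <- f > 0 & f <= f_max
  structure(data.frame(frequency_hz = f[keep],
                       impedance_mohm = Mod(cross[keep] / pow[keep])),
            probe = probe, class = c("impedance_curve", "data.frame"))
}

#' Phase plot (dV/dt versus V) of a voltage trace
#'
#' The derivative is taken by central differences at the recording
#' resolution, without smoothing. With `alignment = "local_minimum"` the
#' local minimum of dV/dt on the pre-upstroke segment (the trough between
#' resting drift and the AP upstroke) is translated to the origin, the
#' standard alignment for comparing AP initiation dynamics across model
#' variants.
#'
#' @param voltage Voltage samples (mV) containing at most one AP upstroke
#'   when alignment is requested.
#' @param dt Recording step (ms).
#' @param alignment `"none"` or `"local_minimum"`.
#' @return An object of class `phase_plot`: data.frame with `v` (mV) and
#'   `dvdt` (mV/ms); attribute `alignment_offset` = c(mV, mV/ms).
#' @export
phase_plot <- function(voltage, dt, alignment = c("none", "local_minimum")) {
  alignment <- match.arg(alignment)
  n <- length(voltage)
  stopifnot(n >= 5)
  dvdt <- (voltage[3:n] - voltage[1:(n - 2)]) / (2 * dt)
  v <- voltage[2:(n - 1)]
  offset <- c(0, 0)
  if (alignment == "local_minimum") {
    imax <- which.max(dvdt)
    if (imax < 3) stop("no pre-upstroke segment before the dV/dt maximum")
    pre <- dvdt[seq_len(imax)]
    # Last local minimum before the upstroke peak.
    cand <- which(diff(sign(diff(pre))) > 0) + 1
    imin <- if (length(cand)) cand[length(cand)] else which.min(pre)
    offset <- c(v[imin], dvdt[imin])
  }
  structure(data.frame(v = v - offset[1], dvdt = dvdt - offset[2]),
            alignment_offset = offset,
            class = c("phase_plot", "data.frame"))
}

#' Phase plot of a single AP under constant drive
#'
#' Convenience wrapper: simulates the cell under a constant current with
#' detection and forced reset, extracts the last complete inter-reset
#' segment of the recorded voltage and returns its aligned phase plot.
#'
#' @param cell A [build_cell()] result.
#' @param policy A [reset_policy()].
#' @param i_const Constant current (nA).
#' @param node Recorded node (defaults to the sodium node; use
#'   `cell$injection_node` for the somatic AP waveform).
#' @param dt Integration step (ms).
#' @param duration Simulated time (ms).
#' @param alignment Passed to [phase_plot()].
#' @return A `phase_plot` object.
#' @export
ap_phase_plot <- function(cell, policy, i_const, node = cell$na_node,
                          dt = 0.025, duration = 3000,
                          alignment = "local_minimum") {
  r <- run_cell(cell, rep(i_const, round(duration / dt)), dt,
                policy = policy, record_nodes = node, record_every = 1)
  v <- r$rec[, 1]
  dv <- diff(v)
  resets <- which(dv < -15 &
                    v[-1] <= policy$reset_voltage + 1)
  if (length(resets) < 2)
    stop("fewer than two resets; increase duration or current")
  i0 <- resets[length(resets) - 1] + 2
  i1 <- resets[length(resets)] - 1
  phase_plot(v[i0:i1], dt, alignment = alignment)
}
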