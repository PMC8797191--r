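#' Morphology specification for the ball-and-stick model
#'
#' The model is a cylindrical soma (equal length and diameter) joined to a
#' cylindrical axon. A single point sodium conductance sits on the axon at
#' distance `x_na` from the soma-axon junction. The spatial discretization
#' places nodes at segment centers, NEURON-style.
#'
#' @param soma_diameter Soma diameter (um).
#' @param soma_length Soma length (um).
#' @param axon_diameter Axon diameter (um).
#' @param axon_length Axon length (um).
#' @param x_na Distance of the sodium point conductance from the soma-axon
#'   junction (um). May be 0 (sodium at the first axon node).
#' @param dx Spatial step (um).
#' @param soma_dx Optional soma-specific spatial step (um); used for very
#'   large somata where a fine grid is unnecessary.
#' @return An object of class `morphology_spec`.
#' @export
morphology_spec <- function(soma_diameter = 50, soma_length = 50,
                            axon_diameter = 1, axon_length = 600,
                            x_na = 40, dx = 1, soma_dx = NULL) {
  if (is.null(soma_dx)) soma_dx <- dx
  stopifnot(soma_diameter > 0, soma_length > 0, axon_diameter > 0,
            axon_length > 0, dx > 0, soma_dx > 0)
  if (x_na < 0 || x_na > axon_length)
    stop("x_na must lie within the axon: 0 <= x_na <= axon_length")
  if (dx > axon_length || soma_dx > soma_length)
    stop("spatial step larger than a section")
  structure(list(soma_diameter = soma_diameter, soma_length = soma_length,
                 axon_diameter = axon_diameter, axon_length = axon_length,
                 x_na = x_na, dx = dx, soma_dx = soma_dx),
            class = "morphology_spec")
}

#' Passive membrane and axial properties
#'
#' @param axial_resistivity Intracellular resistivity R_a (Ohm cm).
#' @param specific_capacitance Membrane capacitance c_m (uF/cm^2).
#' @param specific_membrane_resistance Membrane resistance R_m (Ohm cm^2).
#' @param leak_reversal Leak reversal potential E_L (mV).
#' @param region_overrides Optional list of lists with fields `start`, `end`
#'   (axon coordinates, um), `rm_factor`, `cm_factor`; axon nodes whose center
#'   falls in `[start, end]` get `R_m * rm_factor` and `c_m * cm_factor`.
#'   Used for myelinated-axon variants.
#' @return An object of class `passive_spec`.
#' @export
passive_spec <- function(axial_resistivity = 150, specific_capacitance = 0.75,
                         specific_membrane_resistance = 30000,
                         leak_reversal = -75, region_overrides = list()) {
  stopifnot(axial_resistivity > 0, specific_capacitance > 0,
            specific_membrane_resistance > 0)
  for (ov in region_overrides) {
    stopifnot(is.list(ov), ov$rm_factor > 0, ov$cm_factor > 0,
              ov$start >= 0, ov$end >= ov$start)
  }
  structure(list(axial_resistivity = axial_resistivity,
                 specific_capacitance = specific_capacitance,
                 specific_membrane_resistance = specific_membrane_resistance,
                 leak_reversal = leak_reversal,
                 region_overrides = region_overrides),
            class = "passive_spec")
}

#' Sodium point-conductance specification
#'
#' A non-inactivating sodium conductance with Boltzmann steady-state
#' activation and a voltage-independent activation time constant, attached as
#' an absolute (non-density) point conductance at the node nearest `x_na`.
#'
#' @param peak_conductance Peak conductance (S, absolute).
#' @param reversal Sodium reversal potential (mV).
#' @param half_activation Boltzmann half-activation voltage V_1/2 (mV).
#' @param slope Boltzmann slope factor k_a (mV); smaller values mean a more
#'   voltage-sensitive activation curve.
#' @param activation_time_constant Activation/deactivation time constant (ms).
#' @return An object of class `sodium_spec`.
#' @export
sodium_spec <- function(peak_conductance = 5.23e-9, reversal = 60,
                        half_activation = -40, slope = 6,
                        activation_time_constant = 0.1) {
  stopifnot(peak_conductance >= 0, slope > 0, activation_time_constant > 0)
  structure(list(peak_conductance = peak_conductance, reversal = reversal,
                 half_activation = half_activation, slope = slope,
                 activation_time_constant = activation_time_constant),
            class = "sodium_spec")
}

#' Boltzmann steady-state activation
#'
#' `m_inf(V) = 1 / (1 + exp((V_1/2 - V) / k_a))`.
#'
#' @param v Membrane voltage (mV); vectorized.
#' @param sodium A [sodium_spec()].
#' @return Activation in (0, 1).
#' @export
m_inf <- function(v, sodium) {
  if (any(!is.finite(v))) stop("non-finite voltage")
  1 / (1 + exp((sodium$half_activation - v) / sodium$slope))
}

#' Action-potential detection and forced-reset policy
#'
#' The model has no repolarizing current, so each AP is terminated by a forced
#' global reset. The AP is detected when the axonal voltage crosses
#' `detection_threshold` (the point of maximal rate of voltage rise, see
#' [calibrate_thresholds()]); the reset fires when the axonal voltage crosses
#' `reset_threshold`, chosen so the mean detect-to-reset latency is
#' `target_delay` (2 ms by default).
#'
#' @param detection_threshold Axonal detection threshold (mV).
#' @param reset_threshold Axonal reset threshold (mV); must exceed the
#'   detection threshold.
#' @param reset_voltage Voltage all nodes are reset to (mV). The default is
#'   the leak reversal (-75 mV); sodium-conductance scans use -90 mV to
#'   preserve type 1 excitability.
#' @param gating_reset_voltage Voltage whose `m_inf` value the gating variable
#'   is reset to; defaults to `reset_voltage`.
#' @param target_delay Target mean detect-to-reset latency (ms).
#' @return An object of class `reset_policy`.
#' @export
reset_policy <- function(detection_threshold, reset_threshold,
                         reset_voltage = -75,
                         gating_reset_voltage = reset_voltage,
                         target_delay = 2) {
  stopifnot(reset_threshold > detection_threshold, target_delay > 0)
  structure(list(detection_threshold = detection_threshold,
                 reset_threshold = reset_threshold,
                 reset_voltage = reset_voltage,
                 gating_reset_voltage = gating_reset_voltage,
                 target_delay = target_delay),
            class = "reset_policy")
}

#' Spike train container
#'
#' @param spike_times Detection-threshold crossing times (ms), strictly
#'   increasing, measured from trial start (burn-in included in the time
#'   axis); all times must fall in `(burn_in, burn_in + trial_duration]`.
#' @param trial_duration Recorded duration after burn-in (ms).
#' @param burn_in Discarded initial duration (ms).
#' @param seed Integer seed that generated the trial.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spike_times, trial_duration, burn_in = 0, seed = NA) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (length(spike_times) &&
      (min(spike_times) <= burn_in ||
       max(spike_times) > burn_in + trial_duration + 1e-9))
    stop("spike times outside (burn_in, burn_in + trial_duration]")
  structure(list(spike_times = spike_times, trial_duration = trial_duration,
                 burn_in = burn_in, seed = seed),
            class = "spike_train")
}

#' Read model specifications from a YAML config file
#'
#' Keys mirror the field names of [morphology_spec()], [passive_spec()] and
#' [sodium_spec()] under top-level sections `morphology`, `passive`, `sodium`.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `morphology`, `passive`, `sodium`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    morphology = do.call(morphology_spec, cfg$morphology %||% list()),
    passive = do.call(passive_spec, cfg$passive %||% list()),
    sodium = do.call(sodium_spec, cfg$sodium %||% list())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
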