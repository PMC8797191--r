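# Shared fixtures, built once per test session and cached.
.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

# Desk-scale grid used throughout the tests (validated by the
# self-convergence test below).
desk_dx <- 2
desk_soma_dx <- 5
desk_dt <- 0.05

desk_cell <- function(x_na = 40, ...) {
  build_cell(morphology_spec(x_na = x_na, dx = desk_dx,
                             soma_dx = desk_soma_dx), ...)
}

# Threshold calibrations are moderately expensive; share them across test
# files (cache names follow "cal_x<position>" for default-kinetics cells).
desk_policy <- function() {
  cached("cal_x40", calibrate_thresholds(desk_cell(40), dt = desk_dt))
}

# OU parameters close to the 5 Hz / CV 0.85 operating point of the default
# model, used as a generic fluctuating test stimulus (tau = 5 ms).
test_mu <- 0.0166
test_sigma <- 0.0453

# Closed-form somatic input resistance of the passive two-cylinder model
# with sealed ends: the soma is split at the injection point into two
# finite cables, the distal one loaded by the sealed-end axon.
analytic_input_resistance <- function(morph = morphology_spec(),
                                      passive = passive_spec()) {
  rm <- passive$specific_membrane_resistance       # Ohm cm^2
  ra <- passive$axial_resistivity                  # Ohm cm
  seg <- function(d_um, l_um, r_load = Inf) {
    d <- d_um * 1e-4                               # cm
    l <- l_um * 1e-4
    lambda <- sqrt(rm * d / (4 * ra))              # cm
    r_i <- 4 * ra / (pi * d^2)                     # Ohm/cm
    rinf <- r_i * lambda
    t <- tanh(l / lambda)
    if (is.infinite(r_load)) return(rinf / t)      # sealed end
    rinf * (r_load + rinf * t) / (rinf + r_load * t)
  }
  r_axon <- seg(morph$axon_diameter, morph$axon_length)
  r_left <- seg(morph$soma_diameter, morph$soma_length / 2)
  r_right <- seg(morph$soma_diameter, morph$soma_length / 2, r_axon)
  (r_left * r_right) / (r_left + r_right) / 1e6    # MOhm
}
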