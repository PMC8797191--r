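---
title: "Dynamic gain analysis of a ball-and-stick neuron: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic gain analysis of a ball-and-stick neuron: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`axogain` studies how fast a population of model neurons can follow a common
input signal — its *dynamic gain function* — in the simplest morphology that
separates the spike initiation site from the soma: a cylindrical soma joined
to a thin cylindrical axon, with the entire voltage-dependent sodium
conductance concentrated at a single axonal position $x_{\mathrm{Na}}$ (an
idealized axon initial segment). This vignette documents the model, the
estimators, every tunable parameter that matters, and the design choices
made where the methods literature leaves the design open.

## The model

Both compartments obey the passive cable equation with capacitance
$c_m = 0.75\,\mu\mathrm{F/cm^2}$, membrane resistance
$R_m = 30\,\mathrm{k\Omega\,cm^2}$, axial resistivity
$R_a = 150\,\Omega\,\mathrm{cm}$ and leak reversal $E_L = -75$ mV. The soma
is a cylinder of equal diameter and length (50 μm); the axon is 1 μm thick
and 600 μm long. Boundary conditions are sealed ends and continuity of
voltage and axial current at the junction. Two point terms enter as Dirac
deltas: the stimulus current $I(t)$ at the middle of the soma, and a
non-inactivating sodium current at $x_{\mathrm{Na}}$,

$$ I_{\mathrm{Na}} = \bar g_{\mathrm{Na}}\, m\,(E_{\mathrm{Na}} - V_A),
\qquad \tau_m \dot m = m_\infty(V_A) - m, \qquad
m_\infty(V) = \frac{1}{1 + e^{(V_{1/2} - V)/k_a}}, $$

with $\bar g_{\mathrm{Na}} = 5.23$ nS (absolute, not a density),
$E_{\mathrm{Na}} = 60$ mV, $V_{1/2} = -40$ mV, slope $k_a = 6$ mV and
activation time constant $\tau_m = 0.1$ ms. Variants scale
$\bar g_{\mathrm{Na}}$ (up to 20×), steepen the activation curve
($k_a$ down to 0.1 mV), move $x_{\mathrm{Na}}$ (0–200 μm), raise $R_a$,
grow the soma (10 μm – 2 cm), or myelinate the distal axon through
`region_overrides` on the passive properties.

There is no repolarizing current and no sodium inactivation, so every action
potential (AP) is terminated by a forced global reset (below). This is a
deliberate reduction: it isolates the *initiation* dynamics, which controls
the encoding bandwidth, from AP shape repolarization details.

### Discretization and integration

`build_cell()` places nodes at segment centers (1 μm default grid; the soma
may use its own step) and assembles per-node capacitances and leak
conductances from the cylinder areas, and axial conductances
$(\pi d^2/4)/(R_a \Delta x)$ between adjacent centers, with the junction
edge the series combination of the two half-segments. All quantities are
converted once to a NEURON-like internal unit system (mV, ms, nA, μS, nF,
μm), which keeps the linear systems well scaled.

`step_cell()`/`simulate_trial()` advance the state with backward Euler: the
gating variable relaxes exactly (exponentially) toward
$m_\infty(V_A^{\mathrm{pre}})$ over the step, then the voltages solve an
implicit tridiagonal system with $\bar g_{\mathrm{Na}} m$ fixed at its
updated value and implicit in voltage. The constant passive matrix is
prefactored once; the sodium term enters as a Sherman–Morrison rank-1
correction, so each step costs two triangular sweeps. The default step is
$\Delta t = 25\,\mu$s on the 1 μm grid. Charge bookkeeping and the
equivalence of the relaxed step response with the direct stationary solve
are asserted in the test suite, and a self-convergence check
(`convergence_check()`) compares spike times of one fixed noise realization
against a simulation with $\Delta t$ and $\Delta x$ halved.

### AP detection, forced reset, and threshold calibration

An AP is detected when the axonal voltage at the sodium node crosses a
detection threshold upward (spike time linearly interpolated between
samples, which keeps phase errors at 1 kHz negligible); the reset fires when
a second, higher threshold is crossed, setting all node voltages to the
reset voltage ($E_L$ by default; −90 mV in the sodium-conductance scans, to
preserve type 1 excitability) and $m$ to $m_\infty$ of the gating reset
voltage. `calibrate_thresholds()` fixes both numbers per model variant: the
detection threshold is the axonal voltage at the maximum mean upstroke
$dV/dt$ in a constant-current pilot run near the target rate — the point
where detection timing is least corrupted by ongoing current fluctuations —
and the reset threshold is bisected until the mean detect-to-reset latency
is 2.0 ± 0.1 ms. For the −90 mV variant the gating variable is reset to
$m_\infty(-90\,\mathrm{mV})$, keeping the reset a single consistent state
reset rather than mixing reset voltages.

## Stimuli

`ou_generate()` synthesizes the fluctuating background current, an
Ornstein–Uhlenbeck process with mean $\mu$, stationary standard deviation
$\sigma$ and correlation time $\tau$ (5 ms baseline, 2–50 ms in variants),
using the exact discretization
$I_{k+1} = \mu + (I_k-\mu)e^{-\Delta t/\tau} + \sigma\sqrt{1-e^{-2\Delta
t/\tau}}\,\xi_k$, so sampled statistics carry no time-step bias; the first
sample is drawn from the stationary law. Its two-sided power spectral
density is $P(f) = 2\tau\sigma^2/(1+(2\pi\tau f)^2)$. Sinusoids, constants
and slow ramps cover the probing protocols. Per-trial seeds are derived
from a root seed with a counter mix (`mix_seed()`), so trials are
reproducible independently of execution order.

## Operating points

A dynamic gain curve is only meaningful at a stated operating point: the
pair (mean rate $\nu$, inter-spike-interval CV). All baseline comparisons
use $\nu = 5 \pm 0.25$ Hz and $\mathrm{CV} = 0.85 \pm 0.05$;
`find_operating_point()` finds $(\mu, \sigma)$ by nested one-dimensional
search — $\mu$ controls the rate at fixed $\sigma$, while the CV is
controlled almost exclusively by $\sigma$ once the rate is matched. A
polish phase re-estimates both on longer pilot runs, fitting the local
sensitivity of the CV to $\ln\sigma$ from its own evaluations (proportional
fallback 0.4 per log-unit, with a cross-term $d\mu/d\sigma \approx 0.35$ at
fixed rate), because the CV estimator has a sampling standard error of
roughly 0.016 even on 500 s of simulated activity — short pilots alone
cannot verify a ±0.05 band. The returned point is verified on a held-out
500 s run with a fresh seed, guarding against overfitting pilot noise. A
fixed-$\sigma$ mode supports the scans that fix the stimulus standard
deviation instead of the CV.

## The dynamic gain estimator

The linear response from current to population rate is estimated as

$$ L(f) = \frac{\mathcal F\,[C_{I\nu}]}{\mathcal F\,[C_{II}]}, \qquad
G(f) = |L(f)|, $$

where $C_{I\nu}$ is the input–output correlation and $C_{II}$ the input
autocorrelation. $C_{I\nu}(\tau')$ equals the firing rate times the
zero-average spike-triggered average (STA) of the current; equivalently
(and this is how the code computes it) the windowed sum of mean-subtracted
current segments around each spike divided by the total recorded time.
Spikes are aligned to the nearest sample of the 0.1 ms STA grid (currents
are block-averaged from the integration step), the window is ±400 ms — long
enough that correlations have decayed — and segments clipped by trial edges
are excluded. The denominator is the analytic OU spectrum by default; an
empirical mode (windowed mean periodogram-derived autocorrelation) exists
as a cross-check, and mid-band agreement of the two within 10% is a test.

**Denoising.** A bank of Gaussian filters is applied to the complex Fourier
components of the numerator: log-spaced centers (20 per decade from the
1.25 Hz window resolution to 1 kHz) with standard deviation $0.25 f_c$.
The filter geometry is not fixed by the methods literature; constant
*relative* width matches the log-frequency presentation of gain curves, and
both parameters are configuration fields recorded in outputs. Smoothing is
applied to the numerator rather than the ratio so the strongly colored OU
denominator (which falls as $1/f^2$) does not bias the weighted averages;
the denominator is evaluated as the same filter-bank average of the
analytic spectrum.

**Significance.** The null hypothesis (spikes independent of the input) is
realized by cyclically shifting all AP times of a trial by one random
interval in [1 s, 19 s], drawn per trial and per surrogate; 500 surrogate
gain curves are computed through the identical pipeline (via each trial's
circular spike–current cross-correlation, so the cost is one FFT per
trial), and the pointwise 95th percentile forms the significance threshold.
Downstream consumers — cutoff extraction, slope fits — mask gain values
below it.

**Confidence intervals.** Trials are pooled into 400 groups of 50 (falling
back to per-trial groups at desk scale), the grand STA is bootstrap
resampled 1000 times over groups, the gain recomputed per resample, and
pointwise 2.5/97.5 percentiles reported.

**Cutoff and decay.** The cutoff frequency is where the gain first falls to
half its reference and stays below for two further grid points
(log-linearly interpolated). The reference is the gain at the lowest
*significant* frequency; with long input correlation times the curve has a
mild resonance above its low-frequency value, which makes a peak-based
reference ambiguous between variants — the peak alternative is available
via an argument. The high-frequency decay exponent is a straight-line fit
of $\log_{10} G$ against $\log_{10} f$ over the significant 30–200 Hz band.

### Validation without the simulator

`poisson_fixture()` produces inhomogeneous-Poisson spike trains whose rate
is a known linear functional of the OU input,
$\nu(t) = \nu_0 + (h * \Delta I)(t)$, so the true dynamic gain is $|H(f)|$
by construction. The estimator must recover a first-order low-pass $H$
within its bootstrap CI, report a flat curve for a flat $H$, and stay below
the significance threshold for $H \equiv 0$ at ≥90% of frequencies. The
fixture emulates the *estimation* problem (colored input, point-process
output, realistic spike counts) but not the simulator's dynamics: passing
these tests validates the estimator's normalization and statistics, not the
biophysics — the biophysics is validated separately by the steady-state
oracles and convergence checks.

## Steady-state compartmentalization analysis

With the somatic voltage clamped (Dirichlet condition at the injection
node; the soma is electrotonically compact, so clamping the middle node is
equivalent to clamping the whole soma to within hundredths of a percent),
the passive structure seen from the sodium node reduces exactly, by two
linear solves, to an affine relation between the node's voltage and the net
non-sodium current leaving it (`lateral_current_line()`). Stationary axonal
voltages are the roots of sodium influx versus that lateral line;
`axonal_equilibria()` brackets and polishes them and classifies stability
by the sign of the net-current derivative (the one-dimensional reduction is
valid because the remaining system is linear and stable, and the gating
variable is fast).

Because the reduction is affine in the clamp voltage, the clamp value that
makes a given axonal voltage stationary is a smooth scalar function, and
three equilibria coexist exactly for clamp values between its two folds.
`bistable_clamp_window()` exploits this to find the bistable clamp window
without gridding the clamp voltage — near the onset of bistability the
window is narrower than any practical grid step, and a gridded scan
overestimates the critical distance by more than half a micrometer.
`critical_distance()` bisects $x_{\mathrm{Na}}$ (0.1 μm grid and
tolerance) for the smallest distance whose window intersects the −60…−50 mV
clamp range; for the default parameters this yields ≈27.6 μm. Note a
convention matters at the half-micrometer level here: this package's
lateral line is the *exact* Thevenin reduction, including the distal axon's
load and the path leak, because only then do the algebraic equilibria agree
with time-domain clamped relaxation (asserted to <0.1 mV). The idealized
reduction that counts only the soma-to-site axial resistance gives an onset
roughly half a micrometer lower; both are within the precision with which
"the" critical distance is usually quoted (≈27 μm).

`vclamp_sweep()` performs the quasi-static clamp sweep by time-domain
relaxation (0.25 mV steps, 500 ms budget and $|dV/dt| < 10^{-6}$ mV/ms per
step), inheriting hysteresis by carrying the state across steps; for
$x_{\mathrm{Na}} = 40$ μm the lower branch disappears near −55.9 mV, where
the sweep jumps. `cclamp_ramp()` shows the contrasting current-clamp case:
a slow ramp (quasi-static guard: somatic drift below 0.5 mV/ms) produces a
gradual axo-somatic decoupling with no jump.

## Impedance and phase-plane tools

`transfer_impedance_sine()` measures the passive soma-to-axon transfer
impedance with sinusoidal probes (≥5 transient cycles discarded, ≥10
analyzed, amplitude ratio at the stimulus frequency bin);
`transfer_impedance_ou()` estimates the same magnitude on the intact model
from Welch-averaged cross-spectra of OU input and axonal voltage. The two
agree within 5% mid-band on passive models (a test); the OU variant is the
one used on active models at the operating point, where the sinusoidal
protocol would trigger spikes. `phase_plot()` builds $dV/dt$–$V$
trajectories by central differences at recording resolution with no
smoothing, aligning the pre-upstroke local minimum of $dV/dt$ to the origin
when requested, so initiation dynamics can be compared across variants with
different baselines. When comparing *somatic* waveforms across model
variants, steepness is read out as $dV/dt$ at a fixed depolarization above
the aligned minimum rather than as the raw $dV/dt$ peak: the forced reset
is timed by the much faster axonal upstroke and truncates the somatic
upstroke at a variant-dependent point, so the raw peak conflates onset
rapidness with reset timing.

## Experiment presets and problem sizes

`run_experiment()` exposes figure-level presets (`fig1`–`fig10`) over the
other modules with full seed provenance and result caching keyed by a
configuration hash; `cutoff_surface()` maps cutoff frequencies over
two-parameter grids with per-point recalibration, flagging (not failing on)
points whose calibration or cutoff is undefined. Desk-scale defaults are
chosen so each preset runs in minutes on one CPU: 2 μm axonal and 5 μm
somatic grids with a 50 μs step (validated by the self-convergence check
for the baseline condition), 40–300 trials of 20 s, 80–500 shift
surrogates, and 120–1000 bootstrap resamples; `paper_scale = TRUE` restores
the production sizes (1 μm/25 μs, 20000 trials), which are cluster-scale
runs. The acceptance script uses 300 trials — enough that the cutoff and
the decay exponent of the baseline curve are stable, while the confidence
band is correspondingly wider than at production scale.

## Known limitations

* The forced reset makes the inter-spike-interval distribution slightly
  artificial immediately after the reset; this can shift the CV a model is
  able to reach at a given rate, but not the supra-threshold initiation
  dynamics that set the encoding bandwidth.
* At desk scale the significance threshold sits roughly an order of
  magnitude higher than at production scale (it shrinks with the square
  root of total spike count), so the usable significant band is narrower;
  slope fits are restricted to that band.
* The 0.1 ms STA grid limits phase fidelity above ~1 kHz; gain magnitudes
  up to the 1 kHz analysis limit are unaffected.
* `sigma` calibration assumes the CV increases with `sigma` at matched
  rate, which holds for all variants explored here; a pathological variant
  violating it would stall the outer search at its iteration cap (reported,
  not silent).
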