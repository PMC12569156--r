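---
title: "Models and methods behind flashkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flashkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashkin)
```

`flashkin` analyses time-resolved measurements of the oxygen-evolving
S3→S4→S0 transition of photosystem II (PSII). This vignette documents
the models, the assumptions they make, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The Kok cycle and flash-train deconvolution

A train of saturating flashes drives dark-adapted PSII through the Kok
cycle. The model assumed throughout is the classical one: a flash either
advances a centre one S-state (probability `1 - miss`) or leaves it in
place (probability `miss`), independently of the current S-state.
Double hits are neglected: with nanosecond excitation and 1 s flash
spacing a second turnover within one flash is not possible, so no
double-hit parameter is exposed. A per-state miss factor would be needed
for strongly perturbed PSII variants whose misses are S-state dependent;
the scalar default matches what flash-pattern analysis of near-native
samples supports, and such variants should not be deconvolved with this
model at all (the amplitude patterns stay interpretable; the linear
unmixing does not).

Given initial populations (default 90% S1, 10% S0 — the dark-adapted
distribution) the transition weights `W[n, j]` follow by propagation,
and the measured transient after flash `n` is modelled per channel as

```
Y(n, t) = sum_j W[n, j] x_j(t) + E_n a(t) + noise.
```

`deconvolve_flashes()` solves for the four transition signatures
`x_j(t)` by ordinary least squares independently at every time point:
no temporal smoothing or parametric time dependence is imposed at this
stage, which keeps the deconvolution a pure linear unmixing. The heat
artifact `a(t)` — flash-induced sample heating visible as a slow drift —
is an optional extra column whose amplitude scales with relative flash
energy `E_n`; the protocol's ~3× stronger final flash is what makes this
column linearly independent of the Kok columns. This energy-scaled
linear artifact model is a declared approximation; the instrument-level
correction used with reference detectors is out of scope.

The design matrix becomes rank-deficient for degenerate parameter
combinations (e.g. uniform initial populations, whose weight rows are
all equal); this raises an error naming the dependent columns rather
than returning an ill-determined solution.

`estimate_miss()` minimizes the deconvolution residual sum of squares
over `miss` in `[0, 0.5]`, with a 26-point grid followed by
golden-section refinement to an absolute tolerance of `1e-3` — the
objective is smooth and unimodal in practice, and the grid guards
against the rare shallow secondary minimum at high miss. A flat
objective (relative range below `1e-6`, e.g. flash-independent signals)
means the data carry no period-four information; the estimate is then
reported as unidentifiable rather than returning an arbitrary point.
Wild-type-like datasets typically give miss factors of 10–15%; values
far outside that band on nominally intact samples deserve suspicion.

## Global multi-exponential fitting

Transients are fitted to a sum of rising exponentials,

```
y(t) = sum_i A_i (1 - exp(-t / tau_i)) + y0,
```

with the time constants shared across channels ("global" fit) and
amplitudes/offsets free per channel. Signals are treated as post-flash
differences from the pre-flash baseline (`baseline_correct()` subtracts
the pre-flash-window mean).

The problem is separable: for fixed `tau` the amplitudes and offsets
have a closed-form linear least-squares solution. `fit_multiexp()`
exploits this (variable projection) and optimizes only the time
constants, in log space with L-BFGS-B. Numerical choices:

* The objective is normalized by the total signal power so that
  optimizer stopping rules behave identically for micro-OD IR data and
  order-one electrode signals.
* Multistart: one log-spaced base initialization between `3 * median(dt)`
  and half the fit-window length, plus `n_starts - 1` starts drawn
  log-uniformly over that range (sorted so components stay ordered),
  with a seed-controlled local RNG stream that never touches the
  caller's RNG state. Eight starts are ample for up to three
  well-separated components.
* Time constants are reported ascending; amplitude signs are free.
* Weighting is uniform across channels and time points.
* Duplicated time constants make the design rank-deficient; the linear
  solve then keeps one copy and zeroes the redundant amplitude, so a
  redundant component never degrades the fit.

Two uncertainty measures are provided: the asymptotic Gauss–Newton
covariance of all free parameters, and `subset_uncertainty()`, which
refits every leave-one-out and leave-two-out channel subset and reports
across-subset means and standard deviations. The subset route is the
appropriate one when channel-to-channel inconsistency (imperfect
deconvolution, baseline differences) rather than point noise dominates —
identical channels give exactly zero subset spread.

## The sequential intermediate scheme

The S3→S4→S0 transition is modelled as an irreversible first-order
chain A → B → C → D: A = Y_Z^ox S3⁺ before proton removal, B = Y_Z^ox S3ⁿ
before the rate-limiting oxyl-radical/O₂-formation step, C = S0⁺ after
O₂ release but before substrate-water insertion, D = the stable S0ⁿ.
Each step is assumed strongly exergonic, so backward rates are
neglected. Rates are reciprocals of measured time constants.

`scheme_populations()` evaluates the Bateman closed form. The terms are
computed as divided differences of `exp(-k t)` through `expm1`, anchored
at the smaller rate of each pair, so nearly degenerate rate constants
lose no precision and the solution is continuous across degeneracies;
only a fully confluent triple (relative spread below `1e-7`) switches to
the analytic `t^n`-weighted limit formula. The tests verify agreement
with an independent fourth-order Runge–Kutta integration to better than
`1e-8` in every population.

O₂ is assigned to the B→C step: the cumulative O₂ curve is
`P_C + P_D = 1 - P_A - P_B`, i.e. release happens when C is formed, and
water insertion (C→D) happens after. If a different assignment is ever
needed, the populations are all returned and any combination can be
formed. When the C intermediate is kinetically invisible (wild-type-like
behaviour), its decay rate is set by convention to `default_kcd()` =
`20 * k_BC`, which keeps `max P_C` below 0.05 — small enough that no
experiment at a ~5 µOD noise floor would resolve it.

## Activation thermodynamics

`arrhenius_fit()` is an unweighted ordinary least-squares regression of
`ln(1/tau)` on `1/T` (inverse-variance weights are accepted but off by
default, since the emulated experiments average several datasets per
temperature before fitting). The activation energy is the negative slope
times `k_B`, reported in meV with the 1σ slope error.

`eyring()` converts `(E_a, tau(T0))` at reference temperature
`T0 = 293.15 K` (20 °C) into

```
dH = E_a - kB T0
dG = kB T0 * ln(kB T0 * tau / h)
-T0 dS = dG - dH
```

with `k_B = 8.617333e-5 eV/K` and `h = 4.135668e-15 eV s`. ΔG‡ is
computed from the measured time constant rather than from `(E_a, ln A)`;
the two routes agree only up to regression error, and the
time-constant route is the one that reproduces published activation
tables to ≤1 meV. By construction the output satisfies the Eyring
equation exactly and `dG - dH - (-T0 dS) = 0` identically.

Error propagation (`eyring_errors()`) follows three explicit rules:
σ(ΔH‡) = σ(E_a) (a constant is subtracted); σ(ΔG‡) = k_B T0 · σ_τ/τ
(first-order, symmetric) or a directly supplied value; and
σ(−T₀ΔS‡) = σ(ΔG‡) + σ(ΔH‡) — an intentionally conservative sum rather
than a quadrature, appropriate because the two errors are strongly
correlated through the shared fit. The symmetric τ-propagation gives
~5 meV where an asymmetric range evaluation would give 6; the symmetric
form is kept as the documented convention.

## The electrode forward model

Flash-generated O₂ in a thin sample layer on a bare platinum electrode
is modelled in 1-D: concentration `c(x, t)` obeys
`dc/dt = D d²c/dx² + r(t) g(x)` with `c = 0` at the electrode (the
−0.95 V polarization makes O₂ reduction diffusion-limited, so the
surface acts as a perfect sink) and zero flux at the far boundary. The
source `r(t)` is the sequential two-step kinetic model with time
constants τ_pre (proton removal) and τ_O2 (the rate-limiting
O₂-formation step); `g(x)` deposits the O₂ uniformly over the layer
fraction adjacent to the electrode. The recorded signal is the electrode
flux passed through a first-order high-pass with `tau_filter = 0.100 s`,
emulating the drift-suppression filter of the instrument.

Defaults — layer thickness 10 µm, 200 grid points, effective
`D = 2e-9 m²/s` — are calibration constants for a plausible thylakoid
layer, not measured quantities; absolute transient shapes are therefore
not meaningful, only the kinetic recovery behaviour is. Silver-ring
geometry, electrode polarization kinetics and drift terms of full
electrode models are intentionally out of scope; a finite-rate (Robin)
electrode boundary could be added but the diffusion-limited case is the
regime the −0.95 V protocol establishes.

Numerics: Crank–Nicolson (unconditionally stable, second order in
time); per-step source amounts are taken from the closed-form cumulative
source integral, so injected O₂ is exact even when τ_pre is shorter than
the time step. The recorded flux uses the second-order one-sided
gradient, while the mass ledger uses the scheme's own first-order
boundary-loss term — the discrete update loses exactly
`D (c₂ + c₂') / (2 dx)` per step — which makes
generated = consumed + remaining hold to machine precision while the
signal converges at second order in `dx` (the two gradients differ by
O(dx), about 0.25% at the default grid).

Because the PDE is linear and time-invariant, the response to any source
is the convolution of the electrode impulse response with the per-step
source amounts. `fit_o2_transient()` exploits this: one Crank–Nicolson
solve per geometry, then each candidate `(tau_pre, tau_o2)` costs only
two FFTs. The source is symmetric in its two time constants, so the
fitted pair is sorted and the smaller reported as τ_pre, consistent with
the sub-millisecond proton-removal phase preceding the millisecond O₂
phase; fits where the two constants differ by less than 20% are flagged
as weakly identified. The signal amplitude is solved linearly;
uncertainties come from the numerical Hessian of the SSR in log-τ space.

## The synthetic-data generator

`make_ir_dataset()` emulates the statistical structure of flash-train IR
experiments: 10 flashes at 1 s spacing, 90/10 initial populations, a
configurable miss factor, four probe channels (1384, 1400, 1514,
1544 cm⁻¹), i.i.d. Gaussian noise at the 5 µOD level, and a
flash-energy-scaled heat artifact with the final flash at 3× energy.
The default transition signatures are schematic: the S3→S0 transition is
biphasic (6.5 and 75 ms) with channel-dependent amplitude ratios — slow
phase dominant at 1384 and 1514 cm⁻¹, fast phase dominant at
1544 cm⁻¹, fast phase essentially absent at 1400 cm⁻¹ — plus a
sub-millisecond negative proton-transfer phase of similar size on all
channels. These amplitude patterns mimic the qualitative behaviour of a
water-insertion-decelerated PSII variant; they are synthetic conventions
chosen once, not digitized experimental curves.

`make_temperature_series()` emulates the polarography design: eight
temperatures from 0 to 35 °C, both source time constants following
Arrhenius laws, 2% peak-relative Gaussian noise. The defaults are
`E_a = 421 meV`, `ln A = 23.0` for the O₂ step (giving τ_O2 ≈ 1.77 ms at
20 °C) and `E_a = 269 meV` for the preceding step with `ln A = 18.8`
chosen so τ_pre(20 °C) ≈ 0.3 ms. The electrode geometry is held fixed
across temperatures; real experiments would also see a weak temperature
dependence of D, which is deliberately not modelled — it affects the
transient shape, not the kinetic time constants being recovered.

What the generator does **not** emulate: correlated (1/f) detector
noise (an option exists but is off by default), QCL intensity drift,
interferogram-level artifacts, S-state-dependent misses, double hits,
acceptor-side two-flash periodicity, and electrode drift. Passing
recovery tests on these synthetics therefore demonstrates correctness of
the estimators under the stated noise model, not robustness to every
instrument pathology.

All generators are deterministic for a fixed seed, use a local RNG
stream (the caller's `.Random.seed` is untouched), and return the ground
truth needed to score any downstream estimator directly.

## Problem sizes used in the shipped studies

The test-suite and acceptance studies use: 10-flash, 4-channel trains on
a 1 ms grid over −0.1…0.9 s; 100 seeds for miss-factor and
time-constant recovery; 1000 random rate triples (4 decades overall,
per-triple ratio ≤ 100 so a fixed-step RK4 oracle stays in its accuracy
regime) for the Bateman cross-check; and polarography studies on a
0.5 ms grid with a 60-point spatial mesh — a deliberately reduced mesh
whose signal differs from the 200-point default by well under the 2%
noise level. Sub-millisecond τ_pre recovery at SNR 50 is demonstrated on
a 0.2 ms grid; at 0.5 ms sampling a 0.3 ms constant is only marginally
identified, which is a property of the design, not of the estimator.

## Known limitations

* The deconvolution assumes the scalar-miss Kok model; strongly
  S-state-dependent misses bias the unmixing and are intentionally not
  fitted.
* Whether misses leave a residual Y_Z^ox contribution in the signal is
  not modelled; the linear model attributes everything to the four
  transition signatures plus the optional artifact.
* The electrode model is a simplified one-dimensional description;
  absolute amplitudes and shapes are not transferable to real
  electrodes without calibrating geometry and D.
* Lifetime-distribution (maximum-entropy) analysis, reversible or
  branched reaction schemes, and free-energy-landscape modelling are out
  of scope.
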