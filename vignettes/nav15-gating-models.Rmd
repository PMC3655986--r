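---
title: "Two-step-inactivation Markov models of Nav1.5: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step-inactivation Markov models of Nav1.5: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navmarkov)
```

## The modeling problem

The cardiac voltage-gated sodium channel Nav1.5 carries the fast inward
current that fires the cardiac action potential. Its gating shows two
inactivation processes on very different time scales: fast inactivation
(milliseconds, entered from the open state) and slow inactivation (hundreds
of milliseconds to seconds, entered during prolonged depolarization). The
experimental signature of slow inactivation is a duration-dependent,
bi-exponential recovery: after a brief (30 ms) depolarizing prepulse the
channel recovers mono-exponentially with a time constant of a few
milliseconds at −120 mV, while after a 1 s prepulse a second, ~100-fold
slower component appears whose amplitude grows with prepulse duration.

`navmarkov` implements this biology as continuous-time Markov chains over
discrete conformational states. Two schemes are shipped:

* **Model I** — 8 states: three closed (`C1`, `C2`, `C3`), one open (`O`),
  and a fast-inactivated tier (`I11`–`I14`) paralleling the activation
  ladder. It reproduces activation, deactivation, steady-state availability
  and fast recovery.
* **Model II** — 12 states: Model I plus a slow-inactivated tier
  (`I21`–`I24`) reached from the fast tier. Occupancy leaks from `I1x` into
  `I2x` slowly during depolarization, and drains back slowly on
  repolarization, which produces both the development of slow inactivation
  and the bi-exponential recovery. This is a *two-step* architecture
  (`O → I1 → I2`): the alternative of hanging a single slow state directly
  off the open state cannot reproduce duration-dependent recovery, because
  the slow state would fill at a rate set only by open-state dwell rather
  than by accumulated fast inactivation.

Occupancies `p(t)` obey the master equation `dp/dt = p Q(V)` where the
generator matrix `Q(V)` holds the voltage-dependent transition rates
(off-diagonal, 1/ms) and rows sum to zero. The macroscopic current is
`I(t) = Gmax · P_open(t) · (V − E_rev)`, inward negative.

## Rate laws and parameters

Each transition carries one of four rate-law families (all rates in 1/ms,
voltages in mV):

* exponential, `k · exp(V/n)`; `n < 0` makes a rate grow with
  hyperpolarization; `n = Inf` is the explicit voltage-independent mode
  (used rather than a huge finite `n` so that no overflow is possible);
* sigmoid (saturating), `g / (1 + exp(−(V + a)/f))`, half-maximal at
  `V = −a`;
* scaled copies, `c^m` times another law, with `c` the single dimensionless
  tier-scaling parameter;
* derived rates, computed at generator-assembly time from microscopic
  reversibility: around any closed reaction cycle the product of rates
  traversed one way must equal the product traversed the other way, so one
  rate per independent cycle is not a free parameter. The packaged 8-state
  scheme has three independent cycles and hence exactly three derived rates
  (the open-state deactivation step `O → C3`, conventionally called the
  third backward rate of the activation ladder, plus the two backward steps
  inside the inactivated tier).

The packaged parameter set (`nav_params()`, also shipped as
`inst/extdata/params_default.txt`) holds ten exponential entries
(`alpha1–3`, `beta1–2`, `phi1–3`, `rho2–3`), one sigmoid (`rho1`) and the
scaling constant `c = 2.146`. Both models share the one set; the slow-tier
entries (`rho3`, `phi3`) are simply unused by Model I.

```{r params}
nav_params()
```

## Scheme wiring: what is declared, what was calibrated

The wiring — which named law sits on which edge — lives in YAML scheme
files (`inst/extdata/model_I.yaml`, `model_II.yaml`), not in code, so every
assignment can be inspected and revised without touching the package. The
shipped wiring is a reconstruction: it was chosen so that the model family,
with the packaged parameters, reproduces the documented kinetic
characteristics of the channel model (listed under *Reference kinetics*
below). Its logic:

* The activation ladder `C1 → C2 → C3 → O` carries `alpha1`, `alpha2`,
  `alpha3`. The first two backward steps carry `beta2` (`C2 → C1`) and
  `beta1` (`C3 → C2`); this pairing (rather than index order) is what makes
  the third closed state nearly committed at activation voltages and places
  the conductance–voltage midpoint near −34 mV with the observed steepness.
* Closed-state inactivation `Cx → I1x` is carried by powers of `c` times
  the saturating law `rho1`. The saturation matters twice: at conditioning
  voltages it sets the availability midpoint near −89 mV, and at strongly
  depolarized voltages it caps closed-state inactivation so that activation
  is not short-circuited.
* Recovery from fast inactivation exits the tier at `I11 → C1 = phi1`, the
  rate-limiting step: `1/phi1(V)` at −120…−90 mV is within a few percent of
  the measured recovery time constants, and its exponential factor
  (−13.07 mV) reproduces their voltage dependence.
* Open-state fast inactivation is `O → I14 = c^−2.5 · rho2`, with a small
  reopening rate `I14 → O = c^−1 · rho1`. The reduced entry rate keeps the
  open state in quasi-equilibrium with the closed ladder during the rising
  phase, which is required for the peak-current G–V curve to track the
  activation equilibrium (midpoint −34 mV) rather than the much shallower
  activation/inactivation race.
* The inactivated tier repeats the activation ladder scaled by `c`; its two
  backward steps and `O → C3` are the derived, cycle-balancing rates.
* Model II attaches the slow tier with uniform entry `rho3` and exit
  `phi3` on all four rungs and mirrors the fast tier's horizontal rates
  exactly, so every added cycle balances identically without further
  derived rates. The arithmetic is transparent here: at −20 mV entry and
  exit are each ≈ 3.1 × 10⁻⁴/ms, so slow inactivation develops with
  τ ≈ 1/(entry + exit) ≈ 1.6 s toward a ~50% plateau, and at −120 mV
  `phi3` ≈ 1.9 × 10⁻³/ms gives the ~0.55 s slow recovery component.

The fractional powers of `c` on the vertical steps (0.75, −0.75, 2, −2.5,
−1, −5) are calibration constants of this reconstruction, fixed once
against the reference kinetics and not revisited; they are declared in the
scheme files. `check_detailed_balance()` verifies microscopic reversibility
of every cycle at any voltage (residuals are at machine precision).

## Voltage-clamp protocols

Five builders mirror the standard whole-cell characterization (holding
potential −120 mV throughout):

| protocol | segments | sweeps |
|---|---|---|
| `activation_protocol()` | 20 ms steps | −90…+60 mV in 5 mV steps (31) |
| `deactivation_protocol()` | 0.25 ms at −10 mV, 20 ms tail | tails −100…−30 mV (8) |
| `availability_protocol()` | 500 ms conditioning, 20 ms test at −10 mV | conditioning −120…0 mV (13) |
| `recovery_protocol(P1, V)` | P1 prepulse, variable interval at `V`, 20 ms test | interval grid (log-spaced default) |
| `slow_inactivation_development_protocol()` | prepulse of variable duration at −20 mV, 30 ms interpulse at −120 mV, 20 ms test at −20 mV | duration grid |

Decisions where the protocol text leaves freedom: the recovery prepulse and
test pulses default to −20 mV (consistent with the development protocol,
exposed as `pulse_V`); the default sampling interval is 0.01 ms (100 kHz);
recovery interval grids default to 25 log-spaced points over 0.5–200 ms for
short prepulses and 0.5–5000 ms for prepulses of 300 ms and longer, covering
both exponential components; development uses 20 log-spaced durations over
0.01–10 s. Holding is realized as the exact stationary distribution of
`Q(−120 mV)` — equivalent to an infinitely long hold and much cheaper; a
finite-hold mode (`sim_config(init = "hold")`) exists for validation and
converges to the same occupancies.

## Numerical methods

Within a piecewise-constant segment the master equation has the exact
solution `p(t) = p0 · expm(Q t)`. The default propagator evaluates it
spectrally (one eigendecomposition per voltage, cached per protocol run,
then closed-form evaluation at arbitrary sample times); if the eigenvector
matrix is ill-conditioned (reciprocal condition number below 1e−10) it
falls back to scaling-and-squaring matrix exponentials over the time
increments. A fifth-order Dormand–Prince Runge–Kutta propagator (via
`deSolve`, `rtol = 1e-10`, `atol = 1e-12`) provides an independent
integration route; the two agree to better than 1e−6 in occupancy on every
protocol and both conserve total probability to better than 1e−9 per
segment (enforced, not assumed). Segments whose interior is not analyzed
(long recovery intervals, development prepulses) contribute only their end
state, so sweep cost is independent of interval length. Row-sum and
detailed-balance checks use a relative tolerance of 1e−10.

Reversal potential defaults to +67.5 mV, the Na⁺ Nernst potential for
140 mM external / 10 mM internal Na⁺ near 24 °C, and `Gmax` to 1 (arbitrary
units); every shipped analysis is normalized, so `Gmax` cancels exactly and
`E_rev` enters only through the conductance conversion of the G–V curve.

## Curve analyses

The standard reductions are implemented as deterministic least-squares
fits (Levenberg–Marquardt via `minpack.lm`, plain unweighted SSE):

* rising Boltzmann `G/Gmax = 1/(1 + exp((V50 − V)/k))` for activation,
  falling Boltzmann for availability; seeds are the interpolated
  half-maximum crossing (V50) and the quartile-crossing distance divided by
  `2·log 3` (k), so fits are reproducible and order-invariant;
* mono-exponential recovery `y = y∞ − a·exp(−t/τ)` and bi-exponential
  `y = y∞ − A1·exp(−t/τ1) − A2·exp(−t/τ2)` with components ordered
  `τ1 < τ2` and amplitude fractions `A/(A1+A2)`; seeding is a two-stage
  peel-off (log-linear regression on the late tail, then on the early
  residual). If the two components are unresolvable the fit warns
  (`τ2/τ1 < 3`) or degrades to a declared degenerate second component
  rather than reporting a spurious confident pair;
* development of slow inactivation `y = a + b·exp(−t/τ)` on remaining peak
  currents normalized to the shortest prepulse duration (the choice of
  normalization point only rescales `a` and `b`, not `τ`);
* phase time constants from single sweeps: activation fits the rise up to
  the peak, inactivation fits the decay from 110% of the time-to-peak to
  the segment end (excluding the activation shoulder), deactivation fits
  the tail from its peak; degenerate windows (peak at a segment boundary)
  are rejected with a diagnostic.

Peaks are the signed extremum of the current within a segment; at the
default 0.01 ms sampling no sub-sample interpolation is needed for ~1 ms
kinetics.

## Rate-constant estimation (PSO-GSS)

`pso_gss_fit()` estimates free rate-law fields (e.g. `alpha1.k`) from
macroscopic current families: canonical global-best particle swarm
(constriction coefficients: inertia 0.729, cognitive = social = 1.49445)
over box bounds, log10-transformed for rate magnitudes (they span five
orders of magnitude), linear for voltage factors; every `gss_every`
generations a golden-section line search refines each coordinate of the
global best. The cost is the sum over target protocols of the SSE between
simulated and target currents, each protocol normalized by its target's
squared peak magnitude (equal weighting across protocols; the conductance
scale cancels). Runs are bit-deterministic given the seed. Identifiability
is probed with one-dimensional cost profiles (`profile_parameter()`); a
parameter that no simulated protocol touches yields an exactly flat
profile. Joint estimation of all fourteen expressions at once is outside
the tested envelope — recovery is verified for problems of up to four free
parameters (within 10% on noiseless targets, 25% under 1% current noise).

## Synthetic data

`make_noisy_traces()` adds i.i.d. Gaussian noise (and optionally a linear
baseline drift) scaled to the trace family's peak current, deterministic
per seed, with the generating truth stored in the metadata sidecar. This
emulates recording noise only: it does not emulate filtering, capacitive
transients, series-resistance error, leak, or cell-to-cell variability, so
closed-loop tests built on it demonstrate correctness of the analysis
chain, not robustness to real-recording artifacts. Closed-form Boltzmann
and exponential samplers provide fixtures for the fitters.

## Reference kinetics and problem sizes

`cmd_reproduce()` (and `scripts/acceptance.R` in the source tree)
recompute the packaged models' headline characteristics end to end:
activation G–V midpoint (31 sweeps × 20 ms), availability midpoints for
both models (13 sweeps × 520 ms each), recovery time constants at
−120/−110/−100/−90 mV (25 intervals each, P1 = 30 ms), the bi-exponential
split after P1 = 1000 ms (25 intervals to 5 s), and the development time
constant (20 durations to 10 s) — all at 0.01 ms sampling, a few seconds of
compute in total. Recomputed values are compared against the reference
values at ±1 mV on Boltzmann midpoints and 10% relative on time constants
and amplitude fractions.

## Known limitations

* The wiring is a calibrated reconstruction constrained by macroscopic
  kinetics; single-channel statistics and microscopic assignments are not
  identified by these data.
* The simulated availability curve is slightly shallower (slope factor
  ≈ 7 mV) than the measured 5.5 mV, and the simulated activation slope
  (≈ 9.5 mV vs 7.2 mV) shares this bias; midpoints are reproduced within
  1 mV.
* A small reopening current (~3% of peak) persists after full fast
  inactivation; consequently the availability curve's depolarized tail has
  a floor of a few percent, and peak test currents are monotone with
  conditioning voltage only to within 0.5% of the family maximum.
* No temperature correction is applied; the parameterization is for room
  temperature (23–25 °C).
* Only ensemble-mean (macroscopic) currents are produced; there is no
  stochastic single-channel mode, and only piecewise-constant command
  voltages are supported (no ramps).
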