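---
title: "Modelling intrinsic heterogeneity and degeneracy in entorhinal stellate cells"
author: "stellate package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intrinsic heterogeneity and degeneracy in entorhinal stellate cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Layer II stellate cells (LII SCs) of the medial entorhinal cortex carry a
distinctive electrophysiological signature: a pronounced sag in response to
hyperpolarizing current, theta-band subthreshold resonance, robust
perithreshold membrane potential oscillations (MPOs), and characteristic
firing responses. A central question is whether these signatures pin down
the underlying ion-channel composition, or whether disparate channel
combinations can produce the same physiology — *degeneracy* at the cellular
scale. This package implements the computational machinery to ask that
question: a biophysical single-compartment stellate cell model, the ten
standard measurements used to validate such models against experiments, an
unbiased stochastic search over channel parameters, virtual knockouts, and
spike-triggered-average (STA) analysis of spike initiation dynamics.

## The model

The cell is a single cylindrical compartment (70 µm diameter × 75 µm
length; lateral surface only, giving an area of `pi * 70e-4 * 75e-4` cm²).
Passive properties are a specific membrane resistance `Rm` (base
40 kΩ·cm²) and capacitance `Cm` (1 µF/cm²), with the leak reversal at
−77 mV so the passive membrane rests there. Nine active conductances are
added: fast sodium (NaF, m³h), delayed rectifier potassium (KDR, n⁴),
fast and slow HCN, persistent sodium (NaP, mh), A-type potassium (KA, mh),
high- and low-voltage-activated calcium (HVA m³h, LVA m²h with
calcium-dependent inactivation s([Ca]) = 0.001/(0.001+[Ca])), M-type
potassium (KM, m), and a calcium-gated SK channel. Sodium, potassium and
HCN currents are Ohmic (E_Na = 50, E_K = −90, E_h = −20 mV); the calcium
channels use the Goldman-Hodgkin-Katz driving-force form at 34 °C, so their
"conductance" parameter scales a GHK term with units of mV and the current
reverses exactly at the calcium Nernst potential. Cytosolic calcium follows
first-order kinetics,

d[Ca]/dt = −10000 · I_Ca / (36 · dpt · F) + ([Ca]∞ − [Ca]) / τ_Ca,

with shell depth dpt = 0.1 µm, [Ca]∞ = 100 nM, and τ_Ca a free parameter
(base 78 ms). The unconventional constant 36 in the influx term (the
standard thin-shell form uses 2·F·dpt) is retained deliberately; see
*Known limitations*.

The HCN activation curves apply their fractional powers (−1.36 fast,
−58.5 slow) to the entire sigmoid bracket, which yields smooth activation
curves with effective half-activation near −78 mV (fast) and −73 mV
(slow). The KM activation slope is negative by definition, so the generic
`(V − V½)/k` sigmoid activates with depolarization without any sign
fix-ups. The NaP rate constants are interpreted on a per-second base and
converted to the millisecond time base, giving ~1 ms activation and
multi-second inactivation, the known phenomenology of the persistent
sodium current.

### The SK channel

The SK channel is a six-state Markov scheme: four sequential
calcium-binding closed states (forward rate α·[Ca] with α = 10 per µM per
second, backward β = 0.5 s⁻¹) and two open states reached from the last
two closed states (γ = 600 s⁻¹ forward, δ = 400 s⁻¹ backward). This wiring
(C1→C2→C3→C4 binding; C3↔O1, C4↔O2 opening) is one defensible reading of a
scheme whose topology is conventionally drawn rather than printed; it is
documented here rather than asserted as the original authors' intent. With
these rates the per-step binding equilibrium at resting calcium (100 nM) is
α[Ca]/β = 2, so the channel sits ~55% open at rest and saturates at
γ/(γ+δ) = 0.6: SK acts mainly as a standing potassium conductance whose
magnitude tracks slow calcium changes. Its stationary distribution is
computed from the null space of the generator and cross-checked in the
tests against long-time integration of the master equation.

### Integration

The integrator is fixed-step at dt = 25 µs: exponential Euler for the 14
gating particles (exact for the per-step linear gate ODE), forward Euler
for voltage, calcium and the SK occupancies (with renormalization to
conserve probability). Identical inputs give bitwise-identical traces. A
divergence guard aborts if |V| > 200 mV or calcium becomes nonpositive.
Halving the step changes the subthreshold measurements by well under 1%
(tested). One numerical guard is applied to the NaP inactivation time
constant: the fitted rational rate functions leave their fit range below
about −99 mV and their sum turns negative; the sum is clamped at a small
positive value so the time constant stays positive (and very large, i.e.
the gate is effectively frozen at strongly hyperpolarized voltages).

## The ten measurements

All protocols start after a 5-s settling period at zero current; the
resting potential `V_RMP` and its standard deviation `V_SD` are the mean
and SD of the sixth second. The SD criterion (< 0.01 mV) certifies both
steady state and the absence of oscillations at rest. The remaining
protocols run from the settled 6-s state:

* **Sag**: −200 pA for 1 s; ratio of steady-state to peak deflection, both
  relative to the pre-step baseline; steady state is the mean of the final
  10 ms (noise robustness at negligible bias), the peak is the signed
  extreme deflection.
* **R_in**: steady-state deflections for 1-s steps from −100 to +100 pA in
  20-pA increments; least-squares slope of the V–I relation.
* **Impedance**: a 15-s chirp sweeping 0→15 Hz at 40 pA peak-to-peak;
  Z(f) is the ratio of the Fourier transforms of response and stimulus;
  `f_R` is the argmax of |Z| over 0.5–15 Hz, `Q_R` = |Z(f_R)|/|Z(0.5)|,
  and `Phi_L` integrates the positive (inductive) region of the phase
  profile. A 1-s zero-current tail is appended after the chirp so the
  response decays inside the record; without it, the end-discontinuity
  leaks ~3% ripple into the profile (the passive model then matches the
  analytic RC curve to < 0.1%).
* **Firing**: 500-ms steps of 100 and 400 pA give `N_100` and `N_400` by
  counting upward crossings of −20 mV with a 1-ms lockout; −20 mV
  separates the low-amplitude MPO cluster (< 25 mV peak-to-peak) from full
  action potentials (> 60 mV). `V_AP` is the first spike's peak in the
  400-pA sweep minus `V_RMP`.
* **MPOs**: 5-s steps from 100 to 300 pA in 10-pA increments; the last 3 s
  of each sweep is mean-subtracted and transformed (rectangular window,
  0.33-Hz resolution; the DC bin is excluded from the peak search and a
  spectral peak below 0.01 mV is reported as non-oscillatory). `f_osc` is
  the oscillation frequency of the largest current whose *analysis window*
  contains no spikes. Restricting the spike exclusion to the analyzed
  window matters: near threshold many models fire a few onset spikes in
  the first two seconds and then settle into clean theta MPOs, which is
  exactly the perithreshold regime the measurement targets.

Each trace-level operation is also exercised on synthetic ground-truth
traces (constructed sag shapes, sinusoidal MPOs, triangular spike trains,
filtered chirps with a known transfer function), so the measurement code is
validated independently of the simulator.

## The stochastic search

Population generation is plain rejection sampling: each of the 55
parameters is drawn independently and uniformly within its range
(conductances 0.5×–2× base, time-constant scale factors 0.8×–1.2×,
half-voltages ±5 mV, slopes ±20%), the model is measured, and it is valid
iff all ten measurements fall inside their physiological bounds
(inclusive). Model *k* uses substream seed *k* derived from the global
seed, so any subset of models is reproducible independent of batch size
and an interrupted search can resume without changing the result.

Protocols run in increasing order of cost (settle → resting potential →
sag → R_in → chirp → steps → MPO scan) and abort once a criterion has
failed; this cannot change a validity decision. For desk-scale searches a
coarser screening step (0.1 ms) is used first against bounds widened by
20% of each range (±2 for the spike counts), and only screen-passing
models are confirmed at 25 µs against the exact bounds; the widening
absorbs discretization error so the coarse pass only discards models that
are clearly out of range. The test suite runs 5,000 models this way; the
full-scale study design (3 × 50,000 models) uses the same code path.

## Virtual knockouts

A knockout zeroes exactly one channel's maximal conductance (both HCN
components fall together because the fast conductance is defined as a
ratio of the slow one) and re-runs the measurements. Knockout models that
fire spontaneously at rest (any spike during the settling/resting window)
or enter depolarization-induced block (voltage above −20 mV for more than
100 ms contiguously during the 400-pA step after at least one spike) are
excluded with the reason recorded, since their subthreshold measurements
are uninterpretable. Changes are percentages of the pre-knockout value,
except `N_100`, which is a count change (its pre-knockout value is
constrained to zero). The no-change null is tested with a one-sample
Wilcoxon signed-rank test against zero (a rank-sum test against a zero
vector is available as an option; the one-sample reading is the
statistically coherent version of testing "changes against a no-change
scenario").

## Spike-triggered average

The noise SD of a zero-mean Gaussian white-noise stimulus (one independent
draw per 25-µs step) is calibrated by bisection so the model fires at
~1 Hz (±0.25 Hz on a 50-s probe), the regime in which spikes are isolated
and the pre-spike current samples are statistically independent. The STA
averages the injected current over the 300 ms preceding each spike (spikes
without a full history are excluded) and is median-filtered over a 1-ms
window before metrics are computed. The spectrum is taken after
zero-padding the 300-ms kernel to 4 s: the raw 3.3-Hz resolution can
resolve neither the 0.5-Hz reference bin of `Q_STA` nor theta-band peaks,
and padding interpolates the continuous spectrum of the finite kernel
without altering it. `T_TCDW` is the lag of the first zero crossing before
the spike (the extent of the spike-proximal positive lobe) and `T_ECDW` is
an STA-weighted width of that lobe. The literature expression for the
effective window (t²·STA in the numerator against STA² in the
denominator) is not dimensionally a time; the package's
default is the RMS width sqrt(∫t²·STA² dt / ∫STA² dt) over the lobe, and
the literal form is also reported (`T_ECDW_printed`) for auditability.

On the base model the calibrated noise is ~2.6 nA; the kernel shows the
class II/III signature (a strictly negative lobe preceding the
spike-proximal positive lobe), theta-band spectral selectivity, and an
effective coincidence-detection window in the fast-gamma range (run
`scripts/acceptance.R` to reproduce the numbers).

## Population analytics

Parameter correlations are plain Pearson coefficients across the valid
models (55 parameters → 1,485 unique pairs; 14 measurements → 91 unique
pairs); a constant column is reported as missing rather than zero.
Distances between models use either the Euclidean metric on
min-max-rescaled parameters (bounded by √55) or the Mahalanobis metric on
raw parameters with the covariance estimated from the same valid set. When
a scaled-down run has no more valid models than parameters the covariance
is singular; diagonal loading Σ + εI with ε = 10⁻⁶·tr(Σ)/55 is applied
and flagged. The Mahalanobis normalization constant is the distance
between the two synthetic vectors holding every parameter at its maximum
and minimum. Cross-set comparisons use the Kruskal-Wallis test followed by
pairwise two-sided Mann-Whitney tests, with raw p values (no
multiple-testing correction, matching how such comparisons are reported).

## Problem sizes and defaults

The packaged defaults reproduce the study conditions: dt = 25 µs,
5-s settling, the full protocol set, and uniform sampling within the
table ranges. Desk-scale analyses in the tests use 5,000-model searches
(with 0.1-ms screening and 25-µs confirmation) and 200–250-s STA runs
(> 150 spikes); the full-scale design (50,000 models per set, 1,000-s STA
runs with ~1,000 spikes) runs through the same functions with larger
arguments.

## What the synthetic fixtures do and do not show

The synthetic traces (flat rest, constructed sag shapes, pure sinusoidal
MPOs, triangular spike trains, known transfer functions) verify that each
measurement operation recovers its ground truth exactly. They do not
emulate channel noise, electrode artifacts, or the coupling between
protocols present in real recordings; passing them certifies the
measurement algebra, while the simulator-level and population-level tests
certify the dynamics.

## Known limitations

* Implementing the channel equations in their literature formulations,
  with every ambiguity resolved in the documented directions, leaves the
  hand-tuned base model slightly outside three of the ten physiological
  bounds
  (V_RMP −66.2 mV vs −65..−60; R_in 33.9 MΩ vs 35–65; N_400 20 vs 7–16);
  the other seven are inside, and all directional and dynamical
  properties (sag, theta resonance, perithreshold theta MPOs, knockout
  directionality, STA structure) hold. The largest resting outward
  current is the SK channel, which the adopted rates hold ~55% open at
  100 nM calcium; together with the calcium-influx constant (18× weaker
  than the conventional thin-shell form, so SK is barely recruited during
  spike trains) this is the most sensitive modelling choice behind those
  three measurements. No parameter was adjusted to push measurements
  toward the bounds.
* The search yield is sensitive to those same offsets, so scaled-down
  valid counts sit at the low end of the expected range.
* No stochastic channel gating, no morphology, no synapses, no resurgent
  sodium or CAN currents; dorsoventral gradients and network embedding are
  out of scope.
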