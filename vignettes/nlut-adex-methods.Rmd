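---
title: "N-LUT-ADEX: model, table design, fixed-point pipeline and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{N-LUT-ADEX: model, table design, fixed-point pipeline and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlutadex)
```

## The model

The adaptive exponential integrate-and-fire (ADEX) neuron couples a membrane
potential $V$ (mV) to an adaptation current $W$ (pA):

$$C\,\dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} + I - W,
\qquad
\tau_w\,\dot W = a (V - E_L) - W,$$

with the reset rule $V > 0 \Rightarrow V \leftarrow V_r,\; W \leftarrow W + b$.
In the unit system pF/nS/mV/pA/ms these equations are dimensionally consistent
with no conversion factors.  Eight parameter presets (`adex_preset()`)
generate the canonical firing patterns — tonic spiking, adaptation, initial
bursting, delayed accelerating, irregular spiking, and the "can", "cAD" and
"RS" regimes.

Integration is forward Euler at a fixed step, `dt = 1/128` ms by default,
which is the step a power-of-two hardware divider realizes as a shift.  No
adaptive or implicit integrators are provided: the digital pipeline being
emulated is fixed-step by construction, and the package's purpose is to
reproduce *that* computation, not to solve the ODE as accurately as possible.

Two numerical guards are applied, both configurable:

* **Exponent clamp.** The exponent argument $(V - V_T)/\Delta_T$ is capped at
  20.  Between the threshold crossing and the reset there is exactly one
  Euler step during which the exponential would otherwise overflow; the clamp
  bounds it at $e^{20} \approx 4.9\times 10^8$ without affecting subthreshold
  dynamics (the cap engages only above $V_T + 20\Delta_T$, far past the point
  where a spike is already certain).
* **Stored-apex clamp.** The recorded trace clamps $V$ at +10 mV, the top of
  the digital operating range.  The unclamped pre-reset sample reaches
  $\sim 10^5$ mV (one Euler step at the clamped exponential), which is an
  artefact of the detection convention, not a model state anyone plots; left
  in the trace it dominates every voltage-error metric.  Spike detection and
  the reset itself are unaffected — only the stored sample is bounded.

The default initial state is $(\max(E_L, v_{\min}),\, 0)$ with
$v_{\min} = -60$ mV the bottom of the operating range.  Three presets have
$E_L = -70$ mV, below the lookup table's voltage domain; starting there would
make the table model integrate a clamped boundary value for the whole initial
rise and acquire a permanent phase offset that no table size removes.
Clamping the start into the operating range is the smallest change that makes
the two models' initial conditions equivalent.

## Nyquist table design

The replaced quantity is the voltage nonlinearity
$\mathrm{ADX}(V) = -g_L (V - E_L) + g_L \Delta_T e^{(V-V_T)/\Delta_T}$
(`adx()`), everything in $\dot V$ that depends only on $V$.  The design
procedure treats $\mathrm{ADX}$ over the operating range $[-60, +10]$ mV as a
"signal" occupying one normalised second and asks for its bandwidth:

```{r bandwidth}
dense <- tabulate_objective("Tonic spiking")   # 1024 samples, saturating cap
est <- estimate_bandwidth(dense)               # DFT, cumulative power
est$base_frequency
nyquist_point_count(est)                       # max(ceil(2B), 20)
```

Two deliberate choices here:

* The dense tabulation used for the *bandwidth analysis* saturates at
  $\mathrm{ADX}(V_T + 5\Delta_T)$.  The analysis concerns the subthreshold
  shape; above that point the exponential only accelerates an
  already-certain spike, and an unbounded tabulation would be a near-delta
  function whose formal bandwidth is meaningless.
* The cumulative-power fraction defining the bandwidth is 0.95.  The
  saturating curve has a kinked onset whose spectral tail decays slowly, so
  the estimate is sensitive to this fraction (0.95 → 6 Hz-equivalents for the
  tonic objective, 0.99 → 27).  The design intent — a bandwidth of order
  10, hence at least 20 sample points — is realized at 0.95; the point count
  is additionally floored at 20 so the canonical table size does not depend
  on the estimator's last digit.

The runtime table (`build_lut()`) stores $\mathrm{ADX}$ at 20 uniform grid
points.  Reads (`lut_lookup()`) use nearest-index addressing with end
clamping — one memory access, no interpolation, matching an SRAM read.  The
runtime table's saturation ceiling defaults to the value implied by the
model's own exponent clamp, *not* the analysis cap: a low ceiling slows the
spike upstroke (a 2668 pA cap costs the tonic pattern 2.4 ms per period and
23 of its 103 spikes per second) and would make the table converge to the
wrong function as the point count grows.  With the shared clamp, the N-LUT
model's limit as $n \to \infty$ is exactly the simulated original model.

## What the 20-point table can and cannot reproduce

A piecewise-constant read perturbs $\mathrm{ADX}$ by up to half the
cell-to-cell variation (tens of pA at 20 points).  Along a limit cycle these
perturbations integrate to a net period error of order 0.1%.  Two
free-running oscillators with that period mismatch de-phase within a few
hundred milliseconds, after which pointwise voltage comparisons measure
relative phase, not waveform fidelity.  Concretely, over the default 1000 ms
protocol the tonic pair reaches a voltage MAE near 1.8 mV and a correlation
near 55% — the spike count, inter-spike interval (matched to ~0.1%), firing
pattern and phase portrait all agree, while sample-by-sample error metrics
are dominated by accumulated phase drift.  The convergence of the N-LUT
trace toward the original as the table grows is likewise oscillatory rather
than monotone at each doubling, because the period error changes sign with
the quantisation phase; the net trend across 20 → 640 points is a several-fold
error reduction (`test-lut.R` asserts the net decrease and the negative
log-log slope).  Users comparing the two models should treat spike-train
statistics, not pointwise voltage error over long windows, as the meaningful
fidelity measure.

## Fixed-point multiplierless pipeline

`digital_preset()` stores each model constant as a signed sum of powers of
two, verbatim from the reference design — including its deliberate
approximations (the tonic $\tau_w$ realized as $16+8+4 = 28$ against the
continuous 30) and one sign correction: the "can" row's printed capacitance
is negative, which is unphysical, so the default flips it to +56 (the printed
form stays available behind `printed_can_C = TRUE`).
`digital_divergence_report()` enumerates every departure from the continuous
presets instead of hiding them; three entries exceed 10% (the "cAD" leak
conductance and the "RS" slope factor and adaptation conductance).

`csd_decompose()` is the independent greedy utility: nearest signed power of
two to the residual, ties to the larger exponent, at most three terms.  It
is value-exact for every integer parameter in the tables, though its term
*forms* can differ from the stored ones (200 = $2^8 - 2^6 + 2^3$ for the
greedy versus the stored $2^7 + 2^6 + 2^3$) — both multiply with two adds.

`simulate_fixed()` emulates the datapath bit-exactly: two's-complement
state, a table read per step, and the three coefficient scalings ($dt/C$,
$dt/\tau_w$, $a$) pre-decomposed to signed powers with exponents down to $-25$ and applied as arithmetic shift/add chains
(`shift_add_scale()`).  The division the continuous equations appear to
require is absorbed into those constant decompositions — the only reading
consistent with a zero-divider datapath.  Every operation is tallied in an
`op_trace`; multiply, divide and exponential counts are structurally zero,
which the suite asserts over full one-second runs of all eight patterns.
Overflow saturates (and is counted) rather than wrapping, as DSP hardware
does, and the run continues.

Word sizing: `bit_width_analysis()` reproduces the published 28-bit
membrane-voltage path (6 integer + 20 fraction + 1 guard + 1 sign for
$[-60, +10]$ mV).  The *table-value* path is wider — the stored
$\mathrm{ADX}$ values exceed any 28-bit word — so the emulator's default
format is a 44-bit word with the same 20 fraction bits; the published
analysis is a statement about the voltage datapath, not the whole pipeline.
The scheduling of the four architecture units (table read, pipelining,
control, output) is emulated functionally — one "step" is one Euler update —
not cycle-accurately.

## Phase-plane diagnostics

`adex_nullclines()` returns $W = \mathrm{ADX}(V) + I$ (piecewise constant for
the table model) and $W = a(V - E_L)$; their intersections are fixed points,
verified in the suite against vanishing Euler increments.
`adex_jacobian()` gives the analytic partials — for the original model
$A_1 = (g_L/C)(e^{(V-V_T)/\Delta_T} - 1)$, $B_1 = -1/C$, $C_1 = a/\tau_w$,
$D_1 = -1/\tau_w$; for the table model $A_1 = 0$, since a piecewise-constant
read has zero slope almost everywhere.  A `paper_table` mode reproduces the
reference table's entries verbatim, including its proposed-row $B_1 = -1$,
which is dimensionally inconsistent with the state equation (the coefficient
is $-1/C$); both behaviours are exposed so neither reading is silently
discarded.

## The population experiment

`network_config()` / `build_network()` / `simulate_population()` realize a
2000-neuron random directed network, 80% excitatory / 20% inhibitory
(the 4:1 split), connection probability 0.1.  The synapse model is the
minimal standard construction: delta pulses, i.e. the weights of neurons
that spiked on the previous step are summed into the postsynaptic stimulus
current for one step, plus per-step Gaussian noise.  Everything is seeded:
a fixed seed reproduces the network, the noise and both rasters exactly.

The defaults were chosen once, by calibration against the single-neuron
model, to realize a slow collective rhythm:

* **Baseline drive 223 pA.**  The tonic cell's rheobase is ≈ 220 pA; at
  223 pA an isolated neuron fires at 5.9 Hz.  The population then operates
  in the few-hertz regime where a common rhythm at the cellular rate is the
  expected collective state.
* **Drive jitter s.d. 1 pA.**  Heterogeneity enters through the stimulus
  current only — so one lookup table serves the whole population — and is
  kept small enough that the spread of intrinsic rates stays within one
  spectral bin of the 1-second analysis window.
* **Weights up to 250 pA (excitatory) / 1000 pA (inhibitory) per step.**
  With four times as many excitatory sources, the mean recurrent drive is
  zero; the coupling is strong enough to share the rhythm, weak enough not
  to advance it.
* **Noise s.d. 100 pA per step** desynchronises the initial transient.

`rhythm_frequency()` bins all spikes at 1 ms, removes the mean and reports
the largest non-DC spectral peak; over a 1000 ms window the resolution is
1 Hz.  Under the defaults both models' population histograms peak at 6 Hz.
`mre()` implements the paired spike-time statistic: i-th spikes of each
neuron paired within the window, $\sum |\Delta t_i| / |t_{s,i}| / N \times
100$ with $t_{s,i}$ the original model's spike time (the reference reading
of an ambiguous denominator) and surplus unpaired spikes excluded from $N$
but counted.  Because the population sits near rheobase, where table
quantisation shifts effective drive by more than the suprathreshold margin,
the N-LUT population's mean rate is ~20% below the original's and the
network-level MRE lands near 14% — an honest property of a 20-point table
near rheobase; the statistic's own correctness is pinned by exact
constructed cases (the two-spike 1% example) instead.

What the generator does *not* emulate: conductance-based or delayed
synapses, distance-dependent topology, per-parameter cellular heterogeneity,
and any slow adaptation-driven collective dynamics.  Passing network tests
therefore certify the pipeline and the statistics, not biological realism of
the rhythm mechanism.

## Problem sizes and runtime

Unit tests run the single-neuron protocols at 60–300 ms, where every
qualitative property (pattern class, ISI regularity, convergence trend,
multiplierless contract) is already decided; the full-protocol runs
(1000 ms, all eight patterns, the 2000-neuron network) live in the
validation suite and the acceptance script.  One full network simulation
integrates 2000 neurons × 128 000 steps in a few seconds of compiled code.

## Known limitations

* Pointwise voltage error over long free-running windows measures phase
  drift, not fidelity (see above); tabulated error metrics of that kind are
  not reproducible from the disclosed protocol and the suite documents the
  measured values instead.
* The functional-unit census reports the reference design's accounting from
  stored per-model inventories; the original-model row does not follow from
  any single consistent operator count of the update equations.
* The fixed-point emulator's address computation (voltage → table index) is
  treated as memory addressing, outside the arithmetic tally.
* No HDL emission, timing, or device-resource estimation: those are
  hardware-dependent and out of scope.
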