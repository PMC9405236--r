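# nlutadex

Lookup-table approximation and multiplierless fixed-point emulation of the
adaptive exponential integrate-and-fire (ADEX) neuron.

## The problem

The ADEX neuron is a two-variable spiking model — membrane potential *V* and
adaptation current *W*:

    C dV/dt = -gL (V - EL) + gL ΔT exp((V - VT)/ΔT) + I - W
    τw dW/dt = a (V - EL) - W,      if V > 0: V ← Vr, W ← W + b

Its exponential spike-initiation term is the expensive part of any digital
(FPGA-style) realization: exponentials, multipliers and dividers are the
units that dominate area and limit clock frequency.  The N-LUT-ADEX approach
removes them by treating the voltage nonlinearity
`ADX(V) = -gL (V - EL) + gL ΔT exp((V - VT)/ΔT)` as a band-limited signal
over the operating voltage range, sampling it at the Nyquist rate
(`fs > 2B`, at least 20 points), and replacing the function with a 20-entry
lookup table read by nearest-index addressing.  The remaining constant
coefficients are written as signed sums of powers of two (canonical signed
digits), so one Euler update needs only table reads, shifts, adds and
subtracts.

The package is for computational neuroscientists and neuromorphic-hardware
designers who want to study this approximation in software: design the
table, quantify what it preserves (firing patterns, phase-plane geometry,
population behaviour) and what it costs (voltage error, spike-time drift),
and emulate the digital datapath bit-exactly before committing to hardware.

## What is in the package

* `adex_preset()`, `simulate_adex()` — the eight canonical firing-pattern
  parameter sets and the forward-Euler reference model (`dt = 1/128` ms).
* `tabulate_objective()`, `estimate_bandwidth()`, `nyquist_point_count()`,
  `build_lut()`, `simulate_nlut()` — the Nyquist table design chain and the
  table-based neuron.
* `csd_decompose()`, `digital_preset()`, `to_fixed()`, `shift_add_scale()`,
  `bit_width_analysis()`, `simulate_fixed()`, `resource_census()`,
  `export_fixed_lut()` — the multiplierless fixed-point pipeline with a
  per-operation tally proving the absence of multipliers, dividers and
  exponentials, plus memory-file export (hex / COE dialects).
* `trace_mae()`, `trace_correlation()`, `trace_errp()`, `compare_models()`,
  `adex_nullclines()`, `adex_jacobian()`, `phase_portrait()` — model
  comparison metrics and phase-plane diagnostics.
* `network_config()`, `build_network()`, `simulate_population()`,
  `rhythm_frequency()`, `mre()` — the 2000-neuron, 4:1
  excitatory:inhibitory random-network experiment with raster, population
  rhythm and paired spike-time error.
* A command line (`inst/scripts/nlutadex`, or `nlutadex_main()`) with
  subcommands `simulate`, `build-lut`, `validate`, `network`, `export-lut`,
  `fixtures`.

## Worked example

```r
library(nlutadex)
p   <- adex_preset("Tonic spiking")$params
lut <- build_lut(p)                 # 20 points over [-60, +10] mV
lut
#> lut_spec: 20 points over [-60, 10] mV (dv = 3.684), values in [-176.7, 9.703e+09] pA

orig <- simulate_adex(p)            # exact exponential, 1000 ms
prop <- simulate_nlut(p, lut)       # table reads instead
orig
#> voltage_trace: 128001 samples, dt = 0.0078125 ms, 104 spikes, V in [-60.00, 10.00] mV
length(prop$spike_times)
#> [1] 104

trace_mae(orig, prop)               # 1.78 mV
trace_correlation(orig, prop)       # 54.9 %
```

Both models fire 104 spikes with inter-spike intervals matched to ~0.1%; the
pointwise MAE/correlation numbers are dominated by slow spike-phase drift
between two free-running oscillators, not by waveform error — see the
vignette for why that distinction matters when reading tabulated error
metrics.

The fixed-point pipeline certifies multiplierless execution while
reproducing the spiking pattern:

```r
fx <- simulate_fixed("Tonic spiking")
fx
#> fixed-point pipeline run:
#>   voltage_trace: 128001 samples, dt = 0.0078125 ms, 118 spikes, V in [-60.00, 10.00] mV
#>   ops: shift=896000 add=896118 sub=384000 mul=0 div=0 exp=0 lut_read=128000; saturations: 0
```

(The spike count differs from the continuous model because the digitised
parameter set itself differs — e.g. τw realized as 28 ms against the
continuous 30; `digital_divergence_report()` lists every such departure.)

The population experiment:

```r
net <- build_network(network_config(seed = 1))   # 2000 neurons, 4:1 E:I
r   <- simulate_population(net, "nlut")
rhythm_frequency(r)
#> [1] 6
```

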