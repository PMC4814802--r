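# paingate

A seeded, testable simulator of the spinal **gate control** circuit for pain,
built from two rate-code neurons and two interacting plasticity rules.

## The model

The circuit is the classical dorsal-horn gate with one modification: *all*
afferent terminals are excitatory. A substantia gelatinosa (SG) interneuron
and a central transmission (CT) neuron both receive the mechanoreceptor
(sensory, `I1`) and nociceptive (`I2`) afferents through four plastic
excitatory synapses `w1..w4`; the SG neuron inhibits the CT neuron through a
fixed synapse of magnitude 1. The CT output is the pain signal relayed to the
brain:

    Net1 = w1*I1 + w3*I2            O1 = f(Net1; s1)
    Net2 = w2*I1 + w4*I2 - O1       O2 = f(Net2; s2)

with the near-step activation `f(net; s) = 1 / (1 + exp(-k*(net + 0.5 - 2s)))`
(`k = 50`), whose shift `s` defines the firing threshold `t = 2s - 0.5`.
Two rules adapt the circuit:

* **synaptic plasticity** — each weight is the conditional probability
  `w = P(o | i) = n(o & i) / n(i)` of a postsynaptic spike given a
  presynaptic spike, estimated from sampled binary spikes with (optionally
  decayed) event counters;
* **intrinsic plasticity** — each shift relaxes towards the neuron's output
  rate, `s_t = (v*O_{t-1} + s_{t-1}) / (v + 1)`, so chronically active
  neurons raise their threshold and silenced neurons become hyperexcitable.

Weights driven by output correlations alone saturate; thresholds alone cannot
reshape the mapping. Together, under a standard stimulation regime (the four
input combinations at sensory 0.6, nociceptive 0.3), every random
initialization converges to the setpoint `w = (1, 0, 0.5, 0.5)`,
`t = (0.51, 0.02)` at which the gate computes its textbook behaviour — pain
is relayed only for a pure nociceptive stimulus, and concurrent touch closes
the gate. Non-standard regimes drive the same circuit to setpoints that
reproduce pathological pain: phantom limb pain, dysesthesia/allodynia under
demyelination, wind-up, wind-down and breakthrough pain.

## Worked example

```r
library(paingate)
tr <- run_scenario(scenario_standard(5000), seed = 42)
tr$circuit
#> <gate_circuit>
#>   weights  w1..w4: 1.000, 0.000, 0.528, 0.472
#>   SG: s1 = 0.504 (t1 = +0.508)   CT: s2 = 0.273 (t2 = +0.047)
truth_table(tr$circuit)
#>    I1  I2 net1      o1     net2      o2 pain
#> 1 0.0 0.0 0.00 9.3e-12 -9.3e-12 8.9e-02    0
#> 2 0.6 0.0 0.60 9.9e-01 -9.9e-01 3.1e-23    0
#> 3 0.0 0.3 0.16 2.6e-08  1.4e-01 9.9e-01    1
#> 4 0.6 0.3 0.76 1.0e+00 -8.6e-01 2.2e-20    0
classify_condition(tr)
#> [1] "normal"
```

From a uniform-random start the weights settle at `(1, 0, ~0.5, ~0.5)` and
the thresholds at `(~0.51, ~0.05)`: pain (`O2 ~ 1`) appears only in the
nociceptive-only row, touch alone or combined input is gated, and the
zero-input response is ~0.1 (the sigmoid's resting value at the converged
CT threshold). A pathological regime reprograms the same circuit:

```r
ph <- run_scenario(scenario_phantom(), seed = 2)
thresholds(ph$circuit)
#>     t1     t2
#>  0.089 -0.035
classify_condition(ph)
#> [1] "phantom"
```

After amputation (null inputs) followed by weak neuroma discharge, the CT
threshold turns negative — the neuron fires with *no* input at all, the
model's account of phantom pain.

Scenario scripts for all modelled conditions are built in
(`scenario_phantom()`, `scenario_demyelinating()`, `scenario_breakthrough()`,
`scenario_wind_down()`, `scenario_wind_up()`, `scenario_dual_intense()`), and
`phase_sweep()` maps the condition reached for each combination of input
intensities. A thin CLI lives at `inst/scripts/paingate`
(`run` / `report` / `sweep`).

## Acceptance script

`scripts/acceptance.R` recomputes, from a fresh run of the installed package,
the model's reference quantities: the deterministic forward arithmetic of the
standard truth table, the converged standard setpoint (weights, shifts,
thresholds and the zero-input CT output) from a 5000-iteration training run,
and the CT firing threshold at phantom-pain setpoints across 24 phantom runs.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Not modelled

Spiking/conductance-based dynamics, inhibitory-synapse plasticity,
descending (cortical) modulation, and continuous non-epoch stimulation
streams are out of scope; see the methods vignette
(`vignettes/gate-circuit-model.Rmd`) for assumptions, parameter choices and
known limitations.
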