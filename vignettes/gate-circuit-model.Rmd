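---
title: "The gate circuit model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The gate circuit model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paingate)
```

## The model

`paingate` simulates a minimal spinal gate circuit: a substantia gelatinosa
(SG) interneuron and a central transmission (CT) neuron, both excited by the
mechanoreceptor afferent `I1` and the nociceptive afferent `I2` through four
plastic synapses, with a fixed inhibitory projection of magnitude 1 from SG
to CT. All quantities are dimensionless rates in `[0, 1]`: inputs are firing
probabilities, outputs are sigmoid responses

$$O = \frac{1}{1 + e^{-k(\mathrm{net} + 0.5 - 2s)}},$$

and the firing threshold — the net input at which the neuron fires with
probability one half — is `t = 2s - 0.5`. The exponent above is the unique
reading of the activation rule consistent with its two stated limit cases
(`s = 0`: output 1 at zero input; `s = 1`: output 0 at input 1) and with the
threshold definition; the unit tests pin all three properties.

Two adaptation rules are coupled:

* **Synaptic (presynaptic-rule) plasticity.** Each weight is the conditional
  probability $w = P(o \mid i) = n(o \cap i)/n(i)$ of a postsynaptic spike
  given a presynaptic spike. Because the neurons are rate-coded, fictitious
  binary spikes are sampled per presentation (`i ~ Bernoulli(I)`,
  `o ~ Bernoulli(O)`) and tallied. A presentation without a presynaptic
  spike leaves the weight untouched: the estimator conditions on `i = 1`,
  so silent afferents freeze.
* **Intrinsic plasticity.** Each shift relaxes towards the neuron's output
  rate, $s_t = (\upsilon O_{t-1} + s_{t-1})/(\upsilon + 1)$, a convex
  combination that keeps `s` in `[0, 1]`, has the unique fixed point
  `s* = O` for constant output, and converges geometrically with ratio
  $1/(1+\upsilon)$.

The interplay is the point: the conditional-probability rule is
self-reinforcing (correlated pairs grow their weight, which correlates them
further, pushing `w` to saturation), while threshold adaptation moves the
sigmoid's steep region over the neuron's mean net input and removes the
runaway. The test suite demonstrates both halves on a one-neuron closed
loop: without intrinsic plasticity the weight saturates above 0.95; with it,
weight and shift co-stabilize at an interior value.

## Iteration semantics and randomness

An *epoch* is an ordered set of `(I1, I2)` pairs; an *iteration* presents
every pair once. Per presentation the order of operations is: compute both
rates (the CT net input subtracts the SG *rate*, see below), sample the four
spikes in the fixed order `i1, i2, o1, o2`, update the four weights (one
presynaptic spike per afferent, one postsynaptic spike per neuron, shared
across that neuron's synapses), then update both shifts with this
presentation's rates. The four random draws are consumed whether or not
plasticity is enabled, so frozen test phases leave the stream aligned with
an unfrozen run. A run is fully determined by `(scenario, seed, parameters)`
and the trajectory log is bit-reproducible.

The inhibitory term in the CT net input is the SG output rate `O1`, not a
sampled spike. This matches the published truth-table arithmetic (where the
near-step sigmoid makes `O1` effectively binary) and, empirically, it is the
variant that reproduces the phantom-pain threshold (~ −0.05) and the wind-up
outcome; we also implemented and rejected a spike-sampled inhibition variant,
which raises the frequency of the wind-down outcome but destroys phantom and
wind-up behaviour (the full-strength `−1` inhibition events suppress the CT
neuron's graded resting response during weak-input phases).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 50 | sigmoid slope; 50 makes `f` a near-step function, so rates are saturated except within ~0.1 of threshold |
| `upsilon` | 0.02 | intrinsic-plasticity rate; relaxation time `1/upsilon` = 50 presentations |
| `decay` | 0.99 | forgetting factor of the spike counters; `decay = 1` is the literal lifetime conditional probability |

**Why `upsilon = 0.02`.** The rate is stated only as "small and arbitrary"
in the source model, so it is a genuine design choice. We match the
intrinsic-plasticity relaxation time to the 50-iteration phases of the
scenario scripts: at 0.02 a single-stimulus phase moves the threshold most
of the way to its new equilibrium while the transient is still visible at
the phase boundary. Faster rates (e.g. 0.05, relaxation time 20) make the
CT threshold overshoot during the wind-down script's intense phase — the
early "pain" period is forgotten and the frozen test shows rest-state
hyperexcitability instead of the reduced responsiveness the scenario is
meant to produce. At 0.02 the standard 5000-iteration run converges to
`s = (0.504, 0.273)`, matching the reference setpoint `(0.5, 0.27)` more
closely than faster rates do.

**Why `decay = 0.99`.** With lifetime counts the estimator's gain decays as
`1/n`, so after the 50-iteration standard opening phase a pathological
regime would re-program the circuit ever more slowly. A forgetting factor of
0.99 gives the counters an effective memory of roughly 100 presentations:
old evidence fades on the same timescale on which the scenarios change
regime. The cost is a residual jitter of the weights around the attractor
(standard error ~ `sqrt(w(1-w)/n_eff)`), which is why converged setpoints
are reported as trailing-window means. `decay = 1` reproduces the exact
counting rule and is used in the unit tests against a brute-force tally.

## Scenarios: the stated world

The stimulation protocols are the data-generating world; there is no
external data. The standard epoch presents the four presence/absence
combinations at sensory 0.6 and nociceptive 0.3 (stronger myelinated touch,
weaker unmyelinated nociception), in the fixed order 00, S0, 0N, SN; a
shuffled order is available and converges to the same setpoint. The verbal
intensity scale (very weak 0.1 ... very intense 0.9) supplies the
pathological intensities: phantom (null inputs, then 0.1 combinations),
demyelination (sensory weakened to 0.3, later nociception raised to 0.5),
breakthrough (nociceptive 0.7 in the combination epoch), wind-down (lone
nociceptive 1.0), wind-up (lone sensory 0.1), dual-intense (both 0.9). The
phantom third phase presents all four combinations at 0.1 — the script
leaves open exactly which weak combinations neuromas produce, and all four
is the symmetric reading. Wind-up/wind-down/dual-intense end with a
frozen-plasticity probe phase so the response can be read without moving the
setpoint.

What a green scenario test does establish: the qualitative response pattern
of the converged/probed circuit under the scripted intensities, across
seeds. What it does not establish: anything about continuous (non-epoch)
stimulation, stimulus timing, multi-neuron populations, descending
modulation, or biological parameter values — the model is phenomenological
and its iteration clock has no physical unit.

Several pathological regimes are multi-stable. Phantom runs reach setpoints
that fire at rest in most but not all seeds; wind-down reaches the
all-responses-reduced basin in roughly a third of seeds (other seeds land in
rest-hyperexcitable basins); the tests therefore assert that the described
outcome *occurs among seeds*, not that it is the only outcome.

## Numerical and design choices

* **Convergence detection** uses the trailing-window range of all six
  parameters against a tolerance, with the window mean as the setpoint
  estimate — attractor-agnostic, so novel pathological setpoints are
  detected the same way as the standard one. With decayed counters the raw
  range never reaches the deterministic default tolerance (`1e-3`); settled
  runs are instead judged by agreement of successive window means at the
  jitter scale (0.05), which is how the acceptance tests operationalize
  "converged".
* **Binarization** of a truth table uses the cut 0.5, the sigmoid midpoint,
  consistent with the threshold definition. `truth_table(style = "printed")`
  reproduces the published-table arithmetic, where the SG output is
  binarized by threshold comparison before entering the CT net input.
* **Degenerate inputs** need no special-casing: with `O1` saturated at 1 and
  `w2 = w4 = 0` the CT net input is simply −1, well inside the sigmoid's
  domain; a silent afferent freezes its weights through the conditioning on
  `i = 1` rather than through a division-by-zero guard.
* **Initialization** is uniform on `[0, 1]` for all four weights and both
  shifts, drawn from the run's seeded stream; counters start at zero, so a
  weight keeps its initialization until its afferent first spikes.

## Known limitations

* The dual-intense script does not reproduce an "intense response only to
  the combined intense stimulus" probe pattern in our simulations; across
  seeds the frozen probe shows the inverse (responses to everything except
  the combined pair). The mechanism is structural: from the standard
  setpoint the SG neuron necessarily fires for a `(0.9, 0.9)` input (its net
  input ~1.35 is far above any reachable threshold, which `s <= 1` caps at
  1.5), so the CT neuron is tonically inhibited throughout the intense
  phase, its weights and threshold collapse, and homeostasis leaves it
  hyperexcitable at rest. The corresponding acceptance expectation is left
  failing rather than redefined; the region is acknowledged to be
  unpredictable in the source material.
* The intensity phase chart produced by `phase_sweep()` is a qualitative
  classification under one training duration and one seed per grid point;
  basin boundaries shift with both, and near the diagonal the symmetric
  circuit's outcome is intrinsically seed-dependent.
* A "more realistic" activation with `f(0) = 0` (zero output at zero input)
  is sometimes suggested for this class of models; it is not defined
  precisely enough to implement, so the resting response at a converged
  setpoint remains the sigmoid's value at zero net input (~0.1 at the
  standard setpoint).
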