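Package: paingate
Title: A Plastic Gate-Control Circuit Model of Pain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded simulator of a two-neuron spinal gate-control circuit for
    pain with strictly excitatory plastic afferents. Synaptic weights follow a
    probabilistic presynaptic (conditional-probability) Hebbian rule and the
    neurons' firing thresholds adapt by intrinsic plasticity. Includes the
    standard stimulation protocol on which the circuit converges to the
    conventional gate behaviour (touch closes the gate on concurrent pain),
    scenario scripts for pathological pain conditions (phantom limb pain,
    demyelinating syndromes, breakthrough, wind-up and wind-down pain),
    trajectory logging, convergence detection, truth-table evaluation,
    multi-initialization studies and an input-intensity phase sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
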