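# Shared fixtures for the test suite. Everything is built in code.

# Circuit frozen at the standard converged setpoint as printed: weights
# (1, 0, 0.5, 0.5) and thresholds exactly (0.51, 0.02), i.e. shifts
# (0.505, 0.26).
reference_circuit <- function(...) {
  gate_circuit(weights = c(1, 0, 0.5, 0.5), shifts = c(0.505, 0.26), ...)
}

# Epoch with the rows of the published truth table, in its printed order
# (00, 0N, S0, SN).
table3_epoch <- function() {
  epoch(sensory = c(0, 0, 0.6, 0.6), nociceptive = c(0, 0.3, 0, 0.3))
}

# Binary pain pattern of a circuit over the standard combinations,
# as a compact string in epoch order (00, S0, 0N, SN).
pain_pattern <- function(circuit, epoch = standard_epoch(), cut = 0.5) {
  paste(truth_table(circuit, epoch)$o2 > cut, collapse = "")
}

# The standard (conventional gate) pattern in epoch order: pain only for
# the nociceptive-only row.
standard_pattern <- paste(c(FALSE, FALSE, TRUE, FALSE), collapse = "")

# Brute-force conditional-probability tally: the independent oracle for the
# presynaptic rule with decay 1.
brute_conditional <- function(i_bits, o_bits) {
  if (sum(i_bits) == 0) return(NA_real_)
  sum(i_bits & o_bits) / sum(i_bits)
}
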