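# The two adaptation rules: probabilistic presynaptic (conditional
# probability) synaptic plasticity and intrinsic plasticity of the
# activation-function shift.

#' Construct the state of one plastic excitatory synapse
#'
#' The weight of an NMDA-type synapse is modelled as the conditional
#' probability `w = P(o | i) = n(o & i) / n(i)` of a postsynaptic spike `o`
#' given a presynaptic spike `i`, estimated from sampled binary spikes. The
#' two counters are tallies of presynaptic events and of pre/post
#' coincidences; with `decay = 1` they are exact lifetime counts (the literal
#' conditional-probability rule), while `decay < 1` discounts old events so
#' the weight can re-adapt after a change of stimulation regime.
#'
#' @param weight Initial weight in `[0, 1]`; kept unchanged until the first
#'   presynaptic spike arrives (the conditional probability is undefined when
#'   `n(i) = 0`).
#' @param decay Forgetting factor in `(0, 1]` applied to both counters at
#'   every update (default 0.99).
#' @param plastic Logical; a non-plastic synapse ignores updates.
#' @return An object of class `synapse_state` with fields `weight`,
#'   `joint_count`, `pre_count`, `decay`, `plastic`.
#' @seealso [update_weight()]
#' @export
synapse_state <- function(weight = 0.5, decay = 0.99, plastic = TRUE) {
  stopifnot(length(weight) == 1L, length(decay) == 1L)
  if (weight < 0 || weight > 1) {
    stop("'weight' must lie in [0, 1]", call. = FALSE)
  }
  if (decay <= 0 || decay > 1) {
    stop("'decay' must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(weight = weight, joint_count = 0, pre_count = 0,
         decay = decay, plastic = isTRUE(plastic)),
    class = "synapse_state"
  )
}

#' @export
print.synapse_state <- function(x, ...) {
  cat(sprintf(
    "<synapse_state> w = %.4f (n(o&i) = %.2f / n(i) = %.2f, decay = %g%s)\n",
    x$weight, x$joint_count, x$pre_count, x$decay,
    if (x$plastic) "" else ", frozen"))
  invisible(x)
}

#' Presynaptic-rule weight update
#'
#' One update of the conditional-probability estimate from a sampled
#' presynaptic/postsynaptic spike pair: both counters are decayed, the
#' presynaptic tally is incremented by `pre_bit`, the coincidence tally by
#' `pre_bit * post_bit`, and the weight becomes their ratio. Presentations
#' without a presynaptic spike leave the weight unchanged -- the rule
#' conditions on `i = 1` -- so silent afferents keep their weights frozen.
#'
#' @param state A [synapse_state()].
#' @param pre_bit,post_bit Binary spikes in `{0, 1}`.
#' @return The updated `synapse_state`.
#' @examples
#' s <- synapse_state(weight = 0, decay = 1)
#' for (t in 1:4) s <- update_weight(s, c(1, 1, 0, 1)[t], c(1, 0, 0, 1)[t])
#' s$weight  # 2/3: two coincidences out of three presynaptic spikes
#' @export
update_weight <- function(state, pre_bit, post_bit) {
  stopifnot(inherits(state, "synapse_state"))
  if (!pre_bit %in% c(0, 1) || !post_bit %in% c(0, 1)) {
    stop("spike bits must be 0 or 1", call. = FALSE)
  }
  if (!state$plastic) {
    return(state)
  }
  state$joint_count <- state$decay * state$joint_count + pre_bit * post_bit
  state$pre_count <- state$decay * state$pre_count + pre_bit
  if (state$pre_count > 0) {
    state$weight <- state$joint_count / state$pre_count
  }
  state
}

#' Intrinsic-plasticity shift update
#'
#' The activation-function shift relaxes towards the neuron's previous output
#' rate: `s_t = (v * O_{t-1} + s_{t-1}) / (v + 1)`. The update is a convex
#' combination, so the shift stays in `[0, 1]` whenever the output does, and
#' for a constant output `O` the shift converges monotonically and
#' geometrically (ratio `1 / (1 + v)`) to the unique fixed point `s* = O`.
#' Through `t = 2 s - 0.5` this is homeostasis: a chronically active neuron
#' raises its threshold, a silenced one becomes hyperexcitable.
#'
#' @param shift Current shift `s` in `[0, 1]`.
#' @param prev_output Output rate `O` of the previous presentation, in
#'   `[0, 1]`.
#' @param rate Small positive adaptation factor `v` (default
#'   `gate_defaults()$upsilon`).
#' @return The updated shift, strictly between `shift` and `prev_output`
#'   (or equal to both when they coincide).
#' @examples
#' update_shift(0.5, 1, rate = 0.1)  # 0.6/1.1
#' @export
update_shift <- function(shift, prev_output, rate = gate_defaults()$upsilon) {
  if (any(prev_output < 0 | prev_output > 1)) {
    stop("'prev_output' must lie in [0, 1]", call. = FALSE)
  }
  if (any(shift < 0 | shift > 1)) {
    stop("'shift' must lie in [0, 1]", call. = FALSE)
  }
  if (rate <= 0) {
    stop("'rate' must be positive", call. = FALSE)
  }
  (rate * prev_output + shift) / (rate + 1)
}

#' Default simulation parameters
#'
#' * `k = 50`: slope factor of the near-step sigmoid.
#' * `upsilon = 0.02`: intrinsic-plasticity rate. Its relaxation time
#'   `1/upsilon = 50` presentations matches the 50-iteration single-stimulus
#'   phases of the pathological scenarios, so threshold adaptation during a
#'   regime change is neither instantaneous nor negligible -- see the methods
#'   vignette for why faster rates erase the wind-down transient before it
#'   can be tested.
#' * `decay = 0.99`: synaptic counter forgetting factor; `decay = 1` is the
#'   literal lifetime conditional probability.
#'
#' @return Named list with elements `k`, `upsilon`, `decay`.
#' @export
gate_defaults <- function() {
  list(k = 50, upsilon = 0.02, decay = 0.99)
}
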