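# Rate-code neuron: net input, shifted sigmoid, threshold bookkeeping and
# stochastic binarization of rates.

#' Construct the state of one rate-code neuron
#'
#' A neuron is described by the shift `s` of its sigmoidal activation function
#' and the slope (curve-compressing) factor `k`. The shift determines the
#' firing threshold through `t = 2 s - 0.5`: with `s = 0` the sigmoid is fully
#' shifted leftwards (output 1 at zero net input), with `s = 1` fully
#' rightwards (output 0 at net input 1).
#'
#' @param shift Shift parameter `s`, in `[0, 1]`.
#' @param slope_factor Positive slope factor `k` of the sigmoid (default 50,
#'   which makes the activation close to a step function).
#' @param label Identifier, conventionally `"SG"` or `"CT"`.
#' @return An object of class `neuron_state` with fields `shift`,
#'   `slope_factor`, `label` and the derived `threshold`.
#' @seealso [activate()], [threshold_from_shift()]
#' @examples
#' n <- neuron_state(0.27, label = "CT")
#' n$threshold  # 2 * 0.27 - 0.5
#' @export
neuron_state <- function(shift, slope_factor = 50, label = "neuron") {
  stopifnot(is.numeric(shift), length(shift) == 1L)
  if (shift < 0 || shift > 1) {
    stop("'shift' must lie in [0, 1], got ", shift, call. = FALSE)
  }
  if (!is.numeric(slope_factor) || length(slope_factor) != 1L ||
      slope_factor <= 0) {
    stop("'slope_factor' must be a positive scalar", call. = FALSE)
  }
  structure(
    list(shift = shift, slope_factor = slope_factor, label = label,
         threshold = threshold_from_shift(shift)),
    class = "neuron_state"
  )
}

#' @export
print.neuron_state <- function(x, ...) {
  cat(sprintf("<neuron_state '%s'> shift = %.4f, threshold = %.4f, k = %g\n",
              x$label, x$shift, x$threshold, x$slope_factor))
  invisible(x)
}

#' Net input of a neuron
#'
#' Sums the excitatory postsynaptic potentials `w_j * I_j` and subtracts an
#' optional inhibitory term. In the gate circuit the SG neuron has no
#' inhibitory input and the CT neuron receives the SG output through a fixed
#' inhibitory synapse of magnitude 1, so its net input is
#' `w2 I1 + w4 I2 - O1`.
#'
#' @param weights Numeric vector of synaptic weights in `[0, 1]`.
#' @param inputs Numeric vector of presynaptic firing probabilities in
#'   `[0, 1]`; must match `weights` in length.
#' @param inhibitory_term Non-negative inhibitory contribution (default 0).
#' @return The scalar net input; negative values can arise only through the
#'   inhibitory term.
#' @examples
#' net_input(c(1, 0.5), c(0.6, 0.3))      # 0.75
#' net_input(c(0, 0.5), c(0.6, 0.3), 1)   # -0.85
#' @export
net_input <- function(weights, inputs, inhibitory_term = 0) {
  if (length(weights) != length(inputs)) {
    stop("'weights' and 'inputs' must have the same length", call. = FALSE)
  }
  if (any(weights < 0 | weights > 1)) {
    stop("all weights must lie in [0, 1]", call. = FALSE)
  }
  if (any(inputs < 0 | inputs > 1)) {
    stop("all inputs must lie in [0, 1]", call. = FALSE)
  }
  if (length(inhibitory_term) != 1L || inhibitory_term < 0) {
    stop("'inhibitory_term' must be a non-negative scalar", call. = FALSE)
  }
  sum(weights * inputs) - inhibitory_term
}

#' Sigmoidal activation with shift
#'
#' Computes the firing probability `O = 1 / (1 + exp(-k (net + 0.5 - 2 s)))`.
#' The exponent is the unique reading consistent with both stated limit
#' cases of the near-step sigmoid -- `s = 0` gives `O = 1` at `net = 0`, and
#' `s = 1` gives `O = 0` at `net = 1` -- and with the threshold definition
#' `t = 2 s - 0.5`: the output is exactly 0.5 when `net` equals the
#' threshold.
#'
#' @param net Net input (any real value; the inhibitory term can make it
#'   negative).
#' @param shift Shift parameter `s` in `[0, 1]`, or a [neuron_state()].
#' @param k Slope factor (ignored when `shift` is a `neuron_state`).
#' @return Firing probability strictly between 0 and 1; strictly increasing
#'   in `net` and strictly decreasing in `shift`.
#' @examples
#' activate(0, 0)            # ~1: fully left-shifted sigmoid
#' activate(1, 1)            # ~0: fully right-shifted sigmoid
#' activate(0.04, 0.27)      # 0.5: net input at threshold
#' @export
activate <- function(net, shift, k = 50) {
  if (inherits(shift, "neuron_state")) {
    k <- shift$slope_factor
    shift <- shift$shift
  }
  stopifnot(is.numeric(net), is.numeric(shift), is.numeric(k))
  if (any(shift < 0 | shift > 1)) {
    stop("'shift' must lie in [0, 1]", call. = FALSE)
  }
  1 / (1 + exp(-k * (net + 0.5 - 2 * shift)))
}

#' Firing threshold derived from the activation shift
#'
#' The threshold is the net input at which the neuron fires with probability
#' 0.5: `t = 2 s - 0.5`, so thresholds range over `[-0.5, 1.5]`. Negative
#' thresholds describe hyperexcitable neurons that fire with no input at all,
#' the signature of phantom-pain setpoints.
#'
#' @param shift Shift parameter(s) in `[0, 1]`.
#' @return Threshold value(s) `2 * shift - 0.5`.
#' @examples
#' threshold_from_shift(c(0, 0.5, 1))  # -0.5, 0.5, 1.5
#' @export
threshold_from_shift <- function(shift) {
  if (any(shift < 0 | shift > 1)) {
    stop("'shift' must lie in [0, 1]", call. = FALSE)
  }
  2 * shift - 0.5
}

#' Sample a binary spike from a firing probability
#'
#' Draws a Bernoulli bit from the current R random stream. Rates are kept as
#' probabilities throughout the model; binarization is needed only where the
#' conditional-probability weight rule counts spike coincidences.
#'
#' @param probability Firing probability/probabilities in `[0, 1]`.
#' @return Integer bit(s) in `{0, 1}`.
#' @examples
#' set.seed(1)
#' sample_spike(rep(0.3, 5))
#' @export
sample_spike <- function(probability) {
  if (any(probability < 0 | probability > 1) || any(!is.finite(probability))) {
    stop("'probability' must lie in [0, 1]", call. = FALSE)
  }
  as.integer(runif(length(probability)) < probability)
}
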