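# The gate circuit: wiring, forward evaluation and the plasticity-coupled
# simulation step.

#' Construct a gate circuit
#'
#' Wires the two-neuron gate: sensory (`I1`) and nociceptive (`I2`) afferents
#' project excitatory plastic synapses onto both the substantia gelatinosa
#' (SG) neuron and the central transmission (CT) neuron, and the SG neuron
#' inhibits the CT neuron through a fixed non-plastic synapse of magnitude 1.
#' Weight indices follow the circuit diagram: `w1` sensory-to-SG, `w2`
#' sensory-to-CT, `w3` nociceptive-to-SG, `w4` nociceptive-to-CT.
#'
#' When `weights` or `shifts` are `NULL` they are drawn uniformly on
#' `[0, 1]` from the current random stream, the initialization used by the
#' multi-start convergence studies.
#'
#' @param weights Numeric vector `c(w1, w2, w3, w4)` in `[0, 1]`, or `NULL`
#'   for a random initialization.
#' @param shifts Numeric vector `c(s1, s2)` (SG, CT) in `[0, 1]`, or `NULL`.
#' @param k Sigmoid slope factor.
#' @param upsilon Intrinsic-plasticity rate.
#' @param decay Synaptic counter forgetting factor in `(0, 1]`.
#' @param synaptic_plasticity,intrinsic_plasticity Logical flags; a disabled
#'   rule leaves its parameters untouched during [gate_step()].
#' @return An object of class `gate_circuit`.
#' @examples
#' circ <- gate_circuit(weights = c(1, 0, 0.5, 0.5), shifts = c(0.505, 0.26))
#' thresholds(circ)  # the standard converged thresholds (0.51, 0.02)
#' @export
gate_circuit <- function(weights = NULL, shifts = NULL,
                         k = gate_defaults()$k,
                         upsilon = gate_defaults()$upsilon,
                         decay = gate_defaults()$decay,
                         synaptic_plasticity = TRUE,
                         intrinsic_plasticity = TRUE) {
  if (is.null(weights)) weights <- runif(4)
  if (is.null(shifts)) shifts <- runif(2)
  stopifnot(length(weights) == 4L, length(shifts) == 2L)
  if (any(weights < 0 | weights > 1)) {
    stop("all weights must lie in [0, 1]", call. = FALSE)
  }
  if (any(shifts < 0 | shifts > 1)) {
    stop("both shifts must lie in [0, 1]", call. = FALSE)
  }
  if (decay <= 0 || decay > 1) stop("'decay' must lie in (0, 1]", call. = FALSE)
  if (upsilon <= 0) stop("'upsilon' must be positive", call. = FALSE)
  structure(
    list(
      w = as.numeric(weights),
      joint = numeric(4),
      pre = numeric(4),
      shift = as.numeric(shifts),
      k = k, upsilon = upsilon, decay = decay,
      synaptic = isTRUE(synaptic_plasticity),
      intrinsic = isTRUE(intrinsic_plasticity)
    ),
    class = "gate_circuit"
  )
}

#' @export
print.gate_circuit <- function(x, ...) {
  t12 <- threshold_from_shift(x$shift)
  cat("<gate_circuit>\n")
  cat(sprintf("  weights  w1..w4: %s\n",
              paste(sprintf("%.3f", x$w), collapse = ", ")))
  cat(sprintf("  SG: s1 = %.3f (t1 = %+.3f)   CT: s2 = %.3f (t2 = %+.3f)\n",
              x$shift[1], t12[1], x$shift[2], t12[2]))
  cat(sprintf("  k = %g, upsilon = %g, decay = %g; plasticity: synaptic %s, intrinsic %s\n",
              x$k, x$upsilon, x$decay,
              if (x$synaptic) "on" else "off",
              if (x$intrinsic) "on" else "off"))
  invisible(x)
}

#' Circuit accessors
#'
#' @param object,circuit A [gate_circuit()].
#' @param ... Unused.
#' @return `weights()` returns the named weight vector `w1..w4`; `shifts()`
#'   the named shift vector `s1, s2`; `thresholds()` the named firing
#'   thresholds `t1, t2`.
#' @importFrom stats weights
#' @export
weights.gate_circuit <- function(object, ...) {
  setNames(object$w, c("w1", "w2", "w3", "w4"))
}

#' @rdname weights.gate_circuit
#' @export
shifts <- function(circuit) {
  stopifnot(inherits(circuit, "gate_circuit"))
  setNames(circuit$shift, c("s1", "s2"))
}

#' @rdname weights.gate_circuit
#' @export
thresholds <- function(circuit) {
  stopifnot(inherits(circuit, "gate_circuit"))
  setNames(threshold_from_shift(circuit$shift), c("t1", "t2"))
}

#' Forward evaluation of the gate circuit
#'
#' Pure (state-preserving) evaluation of one input pair:
#' `Net1 = w1 I1 + w3 I2`, `O1 = f(Net1; s1)`,
#' `Net2 = w2 I1 + w4 I2 - O1`, `O2 = f(Net2; s2)`, with `f` the shifted
#' sigmoid of [activate()]. The inhibitory term is the SG output *rate*; with
#' the default near-step sigmoid it is saturated at 0 or 1 for almost all
#' inputs, which is why truth tables printed with binary `O1` produce the
#' same arithmetic.
#'
#' @param circuit A [gate_circuit()].
#' @param sensory,nociceptive Firing probabilities `I1`, `I2` in `[0, 1]`.
#' @return A list with elements `net1`, `o1`, `net2`, `o2`.
#' @examples
#' circ <- gate_circuit(weights = c(1, 0, 0.5, 0.5), shifts = c(0.505, 0.26))
#' gate_forward(circ, 0.6, 0.3)  # pain gated: o2 ~ 0
#' gate_forward(circ, 0, 0.3)    # pain relayed: o2 ~ 1
#' @export
gate_forward <- function(circuit, sensory, nociceptive) {
  stopifnot(inherits(circuit, "gate_circuit"))
  if (sensory < 0 || sensory > 1 || nociceptive < 0 || nociceptive > 1) {
    stop("inputs must lie in [0, 1]", call. = FALSE)
  }
  net1 <- circuit$w[1] * sensory + circuit$w[3] * nociceptive
  o1 <- activate(net1, circuit$shift[1], circuit$k)
  net2 <- circuit$w[2] * sensory + circuit$w[4] * nociceptive - o1
  o2 <- activate(net2, circuit$shift[2], circuit$k)
  list(net1 = net1, o1 = o1, net2 = net2, o2 = o2)
}

# One presentation on the raw state list. Kept free of S3 dispatch so the
# scenario runner can call it in a tight loop; gate_step() wraps it.
# Random draws per call, in fixed order: i1, i2, o1, o2 (always consumed,
# plasticity flags notwithstanding, so frozen phases keep the stream aligned).
step_core <- function(st, I1, I2, syn, intr) {
  net1 <- st$w[1] * I1 + st$w[3] * I2
  O1 <- 1 / (1 + exp(-st$k * (net1 + 0.5 - 2 * st$shift[1])))
  net2 <- st$w[2] * I1 + st$w[4] * I2 - O1
  O2 <- 1 / (1 + exp(-st$k * (net2 + 0.5 - 2 * st$shift[2])))
  r <- runif(4)
  if (syn) {
    i1 <- r[1] < I1
    i2 <- r[2] < I2
    o1 <- r[3] < O1
    o2 <- r[4] < O2
    pre <- c(i1, i1, i2, i2)
    post <- c(o1, o2, o1, o2)
    st$joint <- st$decay * st$joint + pre * post
    st$pre <- st$decay * st$pre + pre
    upd <- st$pre > 0
    st$w[upd] <- st$joint[upd] / st$pre[upd]
  }
  if (intr) {
    st$shift <- (st$upsilon * c(O1, O2) + st$shift) / (st$upsilon + 1)
  }
  st
}

#' One plasticity-coupled simulation step
#'
#' Runs [gate_forward()] on the pair, samples the input spikes `i1`, `i2` and
#' the output spikes `o1`, `o2` (in that fixed order, consuming four draws
#' from the random stream whether or not plasticity is enabled), then -- if
#' synaptic plasticity is on -- applies [update_weight()] to the four
#' synapses (`w1`: `i1,o1`; `w2`: `i1,o2`; `w3`: `i2,o1`; `w4`: `i2,o2`),
#' and -- if intrinsic plasticity is on -- relaxes both shifts towards this
#' presentation's output rates. A presentation with no presynaptic spike
#' leaves the corresponding weights untouched while the shifts still adapt.
#'
#' @inheritParams gate_forward
#' @return The updated `gate_circuit`.
#' @export
gate_step <- function(circuit, sensory, nociceptive) {
  stopifnot(inherits(circuit, "gate_circuit"))
  if (sensory < 0 || sensory > 1 || nociceptive < 0 || nociceptive > 1) {
    stop("inputs must lie in [0, 1]", call. = FALSE)
  }
  step_core(circuit, sensory, nociceptive, circuit$synaptic, circuit$intrinsic)
}

#' Present one epoch to the circuit
#'
#' Applies [gate_step()] once per input pair of the epoch. One call is one
#' "iteration" of the simulation clock: all combinations of an epoch are
#' processed inside an iteration.
#'
#' @param circuit A [gate_circuit()].
#' @param epoch A [epoch()] (ordered set of input pairs).
#' @param order `"fixed"` presents the pairs in epoch order, `"shuffled"`
#'   in a fresh random permutation (one extra draw block from the stream).
#' @return The updated `gate_circuit`.
#' @export
run_epoch <- function(circuit, epoch, order = c("fixed", "shuffled")) {
  stopifnot(inherits(circuit, "gate_circuit"))
  epoch <- as_epoch(epoch)
  if (nrow(epoch) == 0L) stop("epoch must contain at least one pair", call. = FALSE)
  order <- match.arg(order)
  idx <- seq_len(nrow(epoch))
  if (order == "shuffled") idx <- sample(idx)
  for (p in idx) {
    circuit <- gate_step(circuit, epoch$sensory[p], epoch$nociceptive[p])
  }
  circuit
}
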