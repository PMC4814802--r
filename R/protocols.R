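# Stimulation protocols: epochs, the verbal intensity scale and the scenario
# scripts for the pathological pain conditions.

#' Construct a stimulation epoch
#'
#' An epoch is an ordered set of `(sensory, nociceptive)` firing-probability
#' pairs presented within one iteration. The standard epoch contains the four
#' presence/absence combinations of the two afferents at the standard
#' intensities (sensory 0.6, nociceptive 0.3): mechanoreceptor stimuli are
#' more intense than nociceptive ones because their axons are myelinated.
#'
#' @param sensory,nociceptive Numeric vectors of equal length with firing
#'   probabilities in `[0, 1]`.
#' @return A data frame of class `gate_epoch` with columns `sensory` and
#'   `nociceptive`.
#' @examples
#' standard_epoch()
#' epoch(0, 1)  # the wind-down stimulus: a lone intense nociceptive input
#' @export
epoch <- function(sensory, nociceptive) {
  if (length(sensory) != length(nociceptive)) {
    stop("'sensory' and 'nociceptive' must have the same length", call. = FALSE)
  }
  if (length(sensory) == 0L) {
    stop("an epoch needs at least one input pair", call. = FALSE)
  }
  if (any(sensory < 0 | sensory > 1) || any(nociceptive < 0 | nociceptive > 1)) {
    stop("firing probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    data.frame(sensory = as.numeric(sensory),
               nociceptive = as.numeric(nociceptive)),
    class = c("gate_epoch", "data.frame")
  )
}

as_epoch <- function(x) {
  if (inherits(x, "gate_epoch")) return(x)
  if (is.data.frame(x) && all(c("sensory", "nociceptive") %in% names(x))) {
    return(epoch(x$sensory, x$nociceptive))
  }
  stop("cannot interpret object as an epoch", call. = FALSE)
}

#' @rdname epoch
#' @export
standard_epoch <- function() {
  combination_epoch(0.6, 0.3)
}

#' The four presence/absence combinations at given intensities
#'
#' Builds the epoch `(0,0), (S,0), (0,N), (S,N)` -- absent/present
#' combinations of the sensory intensity `S` and nociceptive intensity `N`,
#' in the fixed presentation order 00, 10, 01, 11 (sensory bit first).
#'
#' @param sensory,nociceptive Intensities (firing probabilities) of the
#'   present stimuli.
#' @return A `gate_epoch` with four rows.
#' @export
combination_epoch <- function(sensory = 0.6, nociceptive = 0.3) {
  epoch(sensory = c(0, sensory, 0, sensory),
        nociceptive = c(0, 0, nociceptive, nociceptive))
}

#' Verbal intensity scale
#'
#' Translates the verbal description of a stimulus intensity into a firing
#' probability. Intervals: very intense `(0.8, 1]`, intense `(0.6, 0.8]`,
#' medium `(0.4, 0.6]`, weak `(0.25, 0.4]`, very weak `[0, 0.20]`. The
#' representative defaults are 0.9, 0.7, 0.5, 0.3 and 0.1; note that "weak"
#' maps to 0.3, the standard nociceptive intensity.
#'
#' @param label One of `"very intense"`, `"intense"`, `"medium"`, `"weak"`,
#'   `"very weak"` (case-insensitive; underscores allowed).
#' @return The representative firing probability for `label`.
#' @examples
#' intensity("weak")          # 0.3
#' intensity("very intense")  # 0.9
#' @export
intensity <- function(label) {
  scale <- intensity_scale()
  key <- tolower(gsub("_", " ", label))
  if (!key %in% scale$label) {
    stop("unknown intensity label: '", label, "'", call. = FALSE)
  }
  scale$value[match(key, scale$label)]
}

#' @rdname intensity
#' @return `intensity_scale()` returns the full table: verbal label,
#'   interval bounds `lower` (exclusive except for "very weak") and `upper`
#'   (inclusive), and the representative `value`.
#' @export
intensity_scale <- function() {
  data.frame(
    label = c("very intense", "intense", "medium", "weak", "very weak"),
    lower = c(0.8, 0.6, 0.4, 0.25, 0),
    upper = c(1, 0.8, 0.6, 0.4, 0.20),
    value = c(0.9, 0.7, 0.5, 0.3, 0.1)
  )
}

#' Scenario phases
#'
#' A phase is one stimulation regime: an epoch presented for a number of
#' iterations with each plasticity rule on or off. A scenario is a named
#' ordered list of phases; every scenario ships with a standard opening phase
#' (50 iterations of the standard epoch) that programs the circuit into the
#' conventional gate setpoint before the pathological regime begins.
#'
#' @param epoch A [epoch()].
#' @param iterations Number of iterations (epoch presentations) of the phase.
#' @param synaptic,intrinsic Plasticity flags for the phase; test phases of
#'   the wind-up/wind-down scripts freeze both to probe the circuit without
#'   altering its parameters.
#' @return `scenario_phase()` returns a `gate_phase`; `scenario()` a
#'   `gate_scenario`.
#' @export
scenario_phase <- function(epoch, iterations, synaptic = TRUE, intrinsic = TRUE) {
  epoch <- as_epoch(epoch)
  if (iterations < 1) stop("'iterations' must be >= 1", call. = FALSE)
  structure(
    list(epoch = epoch, iterations = as.integer(iterations),
         synaptic = isTRUE(synaptic), intrinsic = isTRUE(intrinsic)),
    class = "gate_phase"
  )
}

#' @rdname scenario_phase
#' @param name Scenario name.
#' @param phases List of `gate_phase` objects.
#' @export
scenario <- function(name, phases) {
  if (!length(phases) || !all(vapply(phases, inherits, TRUE, "gate_phase"))) {
    stop("'phases' must be a non-empty list of scenario_phase() objects",
         call. = FALSE)
  }
  structure(list(name = name, phases = phases), class = "gate_scenario")
}

#' @export
print.gate_scenario <- function(x, ...) {
  cat(sprintf("<gate_scenario '%s'> %d phase(s)\n", x$name, length(x$phases)))
  for (i in seq_along(x$phases)) {
    ph <- x$phases[[i]]
    cat(sprintf("  %d. %3d iterations x %d pair(s)%s\n", i, ph$iterations,
                nrow(ph$epoch),
                if (!ph$synaptic && !ph$intrinsic) " [plasticity frozen]"
                else if (!ph$synaptic) " [synaptic off]"
                else if (!ph$intrinsic) " [intrinsic off]" else ""))
  }
  invisible(x)
}

standard_phase <- function(iterations = 50) {
  scenario_phase(standard_epoch(), iterations)
}

#' Scenario scripts
#'
#' Ready-made stimulation scripts for the pain conditions studied with the
#' model. All pathological scenarios open with 50 standard iterations so the
#' circuit first settles into the conventional gate setpoint; the abnormal
#' regime starts at iteration 51.
#'
#' * `scenario_standard(n)`: the standard epoch throughout.
#' * `scenario_phantom()`: amputation -- 50 null-input iterations -- followed
#'   by 50 iterations of very weak (0.1) input combinations emulating neuroma
#'   discharge at the stump.
#' * `scenario_demyelinating()`: sensory intensity drops to 0.3 (demyelinated
#'   mechanoreceptor axons), then a concomitant rise of the nociceptive
#'   intensity from 0.3 to 0.5 triggers dysesthesia.
#' * `scenario_breakthrough()`: 100 iterations with an intense (0.7)
#'   nociceptive component in the combination epoch.
#' * `scenario_wind_down()`: 50 iterations of a lone maximal (1.0)
#'   nociceptive stimulus, then a frozen-plasticity test phase with the
#'   standard combinations.
#' * `scenario_wind_up()`: 50 iterations of a lone weak (0.1) sensory
#'   stimulus, then a frozen test phase.
#' * `scenario_dual_intense()`: both inputs very intense (0.9) for 50
#'   iterations, then a frozen test phase with the very intense combinations.
#'
#' Intensities are overridable; the defaults follow the verbal intensity
#' scale of [intensity()].
#'
#' @param n,iterations Iteration counts.
#' @return A `gate_scenario`.
#' @seealso [run_scenario()], [classify_condition()]
#' @export
scenario_standard <- function(n = 150) {
  scenario("standard", list(standard_phase(n)))
}

#' @rdname scenario_standard
#' @param weak Intensity of the post-amputation neuroma inputs.
#' @export
scenario_phantom <- function(weak = 0.1) {
  scenario("phantom", list(
    standard_phase(),
    scenario_phase(epoch(rep(0, 4), rep(0, 4)), 50),
    scenario_phase(combination_epoch(weak, weak), 50)
  ))
}

#' @rdname scenario_standard
#' @param sensory Weakened sensory intensity after demyelination.
#' @param nociceptive_late Raised nociceptive intensity of the third phase.
#' @export
scenario_demyelinating <- function(sensory = 0.3, nociceptive_late = 0.5) {
  scenario("demyelinating", list(
    standard_phase(),
    scenario_phase(combination_epoch(sensory, 0.3), 50),
    scenario_phase(combination_epoch(sensory, nociceptive_late), 50)
  ))
}

#' @rdname scenario_standard
#' @param nociceptive Intense nociceptive intensity.
#' @export
scenario_breakthrough <- function(nociceptive = intensity("intense")) {
  scenario("breakthrough", list(
    standard_phase(),
    scenario_phase(combination_epoch(0.6, nociceptive), 100)
  ))
}

#' @rdname scenario_standard
#' @export
scenario_wind_down <- function() {
  scenario("wind_down", list(
    standard_phase(),
    scenario_phase(epoch(0, 1), 50),
    scenario_phase(standard_epoch(), 50, synaptic = FALSE, intrinsic = FALSE)
  ))
}

#' @rdname scenario_standard
#' @param sensory Weak repetitive sensory intensity.
#' @export
scenario_wind_up <- function(sensory = 0.1) {
  scenario("wind_up", list(
    standard_phase(),
    scenario_phase(epoch(sensory, 0), 50),
    scenario_phase(standard_epoch(), 50, synaptic = FALSE, intrinsic = FALSE)
  ))
}

#' @rdname scenario_standard
#' @param level Very intense input level for both afferents.
#' @export
scenario_dual_intense <- function(level = intensity("very intense")) {
  scenario("dual_intense", list(
    standard_phase(),
    scenario_phase(epoch(level, level), 50),
    scenario_phase(combination_epoch(level, level), 50,
                   synaptic = FALSE, intrinsic = FALSE)
  ))
}

#' Serialize scenarios to and from JSON
#'
#' The on-disk schema is a JSON object with keys `name` and `phases`, each
#' phase holding `sensory`, `nociceptive` (the epoch columns), `iterations`,
#' `synaptic_plasticity` and `intrinsic_plasticity`.
#'
#' @param scenario A `gate_scenario`.
#' @param path File path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   the reconstructed `gate_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "gate_scenario"))
  obj <- list(
    name = scenario$name,
    phases = lapply(scenario$phases, function(ph) {
      list(sensory = ph$epoch$sensory,
           nociceptive = ph$epoch$nociceptive,
           iterations = ph$iterations,
           synaptic_plasticity = ph$synaptic,
           intrinsic_plasticity = ph$intrinsic)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  phases <- lapply(obj$phases, function(ph) {
    scenario_phase(epoch(unlist(ph$sensory), unlist(ph$nociceptive)),
                   iterations = ph$iterations,
                   synaptic = isTRUE(ph$synaptic_plasticity),
                   intrinsic = isTRUE(ph$intrinsic_plasticity))
  })
  scenario(obj$name, phases)
}
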