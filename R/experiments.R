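# Simulation runner, trajectory logging, convergence detection, truth
# tables, multi-initialization studies, condition classification and the
# input-intensity phase sweep.

#' Run a stimulation scenario
#'
#' Executes the phases of a scenario on one circuit, honouring each phase's
#' plasticity flags, and logs one record per iteration: the four weights,
#' both shifts, the derived thresholds and the pure forward CT output for
#' every pair of the phase's epoch (columns `o2_1..o2_4`, `NA`-padded for
#' epochs with fewer than four pairs). Given the same scenario, seed and
#' parameters the trajectory is bit-identical.
#'
#' @param scenario A `gate_scenario` (see [scenario_standard()] and friends).
#' @param seed Integer seed for the run's random stream, or `NULL` to
#'   continue the current stream.
#' @param circuit Optional starting [gate_circuit()]; by default a fresh
#'   circuit with uniform-random weights and shifts is drawn (after seeding),
#'   the initialization of the convergence studies.
#' @param k,upsilon,decay Simulation parameters for the default circuit;
#'   ignored when `circuit` is supplied.
#' @param order Pair presentation order within an iteration, see
#'   [run_epoch()].
#' @return An object of class `gate_trajectory`: a list with `log` (data
#'   frame, one row per iteration), `circuit` (final state), `scenario`,
#'   `seed` and `params`.
#' @examples
#' traj <- run_scenario(scenario_standard(150), seed = 1)
#' tail(traj$log[, c("iteration", "w1", "w2", "w3", "w4")], 1)
#' @export
run_scenario <- function(scenario, seed = NULL, circuit = NULL,
                         k = gate_defaults()$k,
                         upsilon = gate_defaults()$upsilon,
                         decay = gate_defaults()$decay,
                         order = c("fixed", "shuffled")) {
  stopifnot(inherits(scenario, "gate_scenario"))
  order <- match.arg(order)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(circuit)) {
    circuit <- gate_circuit(k = k, upsilon = upsilon, decay = decay)
  }
  stopifnot(inherits(circuit, "gate_circuit"))

  n_total <- sum(vapply(scenario$phases, function(p) p$iterations, 1L))
  log <- matrix(NA_real_, nrow = n_total, ncol = 13L)
  colnames(log) <- c("iteration", "w1", "w2", "w3", "w4", "s1", "s2",
                     "t1", "t2", "o2_1", "o2_2", "o2_3", "o2_4")
  phase_id <- integer(n_total)
  row <- 0L
  for (pi in seq_along(scenario$phases)) {
    ph <- scenario$phases[[pi]]
    pairs <- as.matrix(ph$epoch)
    np <- nrow(pairs)
    for (it in seq_len(ph$iterations)) {
      idx <- if (order == "shuffled") sample.int(np) else seq_len(np)
      for (p in idx) {
        circuit <- step_core(circuit, pairs[p, 1L], pairs[p, 2L],
                             ph$synaptic, ph$intrinsic)
      }
      row <- row + 1L
      o2 <- rep(NA_real_, 4L)
      for (p in seq_len(min(np, 4L))) {
        o2[p] <- gate_forward(circuit, pairs[p, 1L], pairs[p, 2L])$o2
      }
      log[row, ] <- c(row, circuit$w, circuit$shift,
                      threshold_from_shift(circuit$shift), o2)
      phase_id[row] <- pi
    }
  }
  log <- as.data.frame(log)
  log$phase <- phase_id
  structure(
    list(log = log, circuit = circuit, scenario = scenario$name,
         seed = seed,
         params = list(k = circuit$k, upsilon = circuit$upsilon,
                       decay = circuit$decay)),
    class = "gate_trajectory"
  )
}

#' @export
print.gate_trajectory <- function(x, ...) {
  cat(sprintf("<gate_trajectory '%s'> %d iterations (seed %s)\n",
              x$scenario, nrow(x$log),
              if (is.null(x$seed)) "none" else x$seed))
  print(x$circuit)
  invisible(x)
}

#' Detect convergence of a trajectory
#'
#' The circuit is considered converged when, over the trailing `window`
#' iterations, the range (max minus min) of every tracked parameter
#' (`w1..w4`, `s1`, `s2`) is below `tol`. The setpoint estimate is the
#' trailing-window mean, which is also the right summary for runs with
#' decayed spike counters (`decay < 1`), whose weights keep jittering around
#' the attractor with a spread set by the effective sample size of the
#' counters; for those runs use a `tol` commensurate with the jitter.
#'
#' @param trajectory A `gate_trajectory` (or its `log` data frame).
#' @param window Trailing window length in iterations.
#' @param tol Convergence tolerance on the per-parameter range.
#' @return A list with `converged` (logical), `setpoint` (named
#'   trailing-window means of `w1..w4`, `s1`, `s2`, `t1`, `t2`) and
#'   `max_change` (largest per-parameter range observed in the window).
#' @export
detect_convergence <- function(trajectory, window = 100, tol = 1e-3) {
  log <- if (inherits(trajectory, "gate_trajectory")) trajectory$log else trajectory
  if (nrow(log) <= window) {
    stop("trajectory must be longer than 'window'", call. = FALSE)
  }
  tail_log <- log[(nrow(log) - window + 1L):nrow(log),
                  c("w1", "w2", "w3", "w4", "s1", "s2"), drop = FALSE]
  ranges <- vapply(tail_log, function(col) diff(range(col)), numeric(1))
  means <- vapply(tail_log, mean, numeric(1))
  setpoint <- c(means, t1 = unname(2 * means["s1"] - 0.5),
                t2 = unname(2 * means["s2"] - 0.5))
  list(converged = all(ranges < tol), setpoint = setpoint,
       max_change = max(ranges))
}

#' Truth table of a circuit
#'
#' Pure forward evaluation of the circuit on every pair of an epoch:
#' `Net1`, `O1`, `Net2` and `O2` per row, plus the binarized pain verdict
#' `pain` (`O2 > cut`). With the near-step sigmoid the rates are saturated
#' for almost all inputs, so the table matches the printed truth-table
#' arithmetic in which `O1` is compared against `t1` directly.
#'
#' @param circuit A [gate_circuit()].
#' @param epoch The probe [epoch()] (default: the standard epoch).
#' @param cut Binarization cut for the pain column (default 0.5, the sigmoid
#'   midpoint).
#' @param style `"rate"` (default) evaluates the sigmoid outputs;
#'   `"printed"` follows the arithmetic of the published table instead:
#'   `O1 = 1` iff `Net1 > t1` (binary), `Net2` uses that binary `O1`, and
#'   `O2 = 1` iff `Net2 > t2`. With the near-step sigmoid the two styles
#'   agree away from the thresholds.
#' @return A data frame of class `gate_truth_table` with columns `I1`, `I2`,
#'   `net1`, `o1`, `net2`, `o2`, `pain`.
#' @examples
#' circ <- gate_circuit(weights = c(1, 0, 0.5, 0.5), shifts = c(0.505, 0.26))
#' truth_table(circ)
#' @export
truth_table <- function(circuit, epoch = standard_epoch(), cut = 0.5,
                        style = c("rate", "printed")) {
  stopifnot(inherits(circuit, "gate_circuit"))
  style <- match.arg(style)
  epoch <- as_epoch(epoch)
  thr <- threshold_from_shift(circuit$shift)
  rows <- lapply(seq_len(nrow(epoch)), function(p) {
    I1 <- epoch$sensory[p]
    I2 <- epoch$nociceptive[p]
    if (style == "rate") {
      fw <- gate_forward(circuit, I1, I2)
      data.frame(I1 = I1, I2 = I2, net1 = fw$net1, o1 = fw$o1,
                 net2 = fw$net2, o2 = fw$o2)
    } else {
      net1 <- circuit$w[1] * I1 + circuit$w[3] * I2
      o1 <- as.numeric(net1 > thr[1])
      net2 <- circuit$w[2] * I1 + circuit$w[4] * I2 - o1
      o2 <- as.numeric(net2 > thr[2])
      data.frame(I1 = I1, I2 = I2, net1 = net1, o1 = o1,
                 net2 = net2, o2 = o2)
    }
  })
  out <- do.call(rbind, rows)
  out$pain <- as.integer(out$o2 > cut)
  class(out) <- c("gate_truth_table", "data.frame")
  out
}

#' Multi-initialization convergence study
#'
#' Repeats a scenario from independent uniform-random initializations and
#' summarizes the dispersion of the final setpoints. With both plasticity
#' rules enabled and standard stimulation, all runs converge to one common
#' setpoint; with either rule alone they do not, and the standard
#' truth-table pattern is generally lost.
#'
#' @param scenario A `gate_scenario`.
#' @param n_runs Number of runs (>= 2).
#' @param seeds Integer seeds, one per run (default `1:n_runs`).
#' @param window Trailing window for the setpoint estimate.
#' @param ... Passed on to [run_scenario()] (e.g. `upsilon`, `decay`, or a
#'   `circuit` factory through `k`).
#' @return A list with `trajectories`, `setpoints` (matrix, one row per
#'   run), `max_pairwise_distance` (Euclidean, over `w1..w4, s1, s2`) and
#'   `truth_tables` (list of final standard-epoch truth tables).
#' @export
multi_init_study <- function(scenario, n_runs = 5, seeds = seq_len(n_runs),
                             window = 100, ...) {
  if (n_runs < 2) stop("'n_runs' must be >= 2", call. = FALSE)
  stopifnot(length(seeds) == n_runs)
  trajectories <- lapply(seeds, function(s) run_scenario(scenario, seed = s, ...))
  setpoints <- t(vapply(trajectories, function(tr) {
    detect_convergence(tr, window = window, tol = Inf)$setpoint[1:6]
  }, numeric(6)))
  rownames(setpoints) <- paste0("run", seq_len(n_runs))
  tables <- lapply(trajectories, function(tr) truth_table(tr$circuit))
  list(trajectories = trajectories,
       setpoints = setpoints,
       max_pairwise_distance = max(dist(setpoints)),
       truth_tables = tables)
}

#' Classify the pain condition of a converged circuit
#'
#' Rule-based labelling of the final truth table over the four
#' presence/absence combinations (rows in the order 00, S0, 0N, SN):
#'
#' * `"normal"`: pain exactly and only for the nociceptive-only input -- the
#'   conventional gate.
#' * `"wind_down"`: no response above the cut for any combination.
#' * `"phantom"`: pain for the null input and for nothing else.
#' * `"wind_up"`: pain for the null input alongside other responses
#'   (phantom pain is the extreme case of this class).
#' * `"allodynia"`: pain for the sensory-only input (dysesthesia) without
#'   null-input pain.
#' * `"mixed"`: any other pattern.
#'
#' @param x A `gate_trajectory`, a [gate_circuit()] or a
#'   `gate_truth_table` over a four-combination epoch.
#' @param cut Pain binarization cut.
#' @return A single classification label.
#' @export
classify_condition <- function(x, cut = 0.5) {
  tab <- if (inherits(x, "gate_trajectory")) truth_table(x$circuit, cut = cut)
  else if (inherits(x, "gate_circuit")) truth_table(x, cut = cut)
  else if (inherits(x, "gate_truth_table")) x
  else stop("cannot classify object of class ", class(x)[1L], call. = FALSE)
  if (nrow(tab) != 4L) {
    stop("classification needs a four-combination truth table", call. = FALSE)
  }
  pain <- tab$o2 > cut  # order: 00, S0, 0N, SN
  if (!any(pain)) return("wind_down")
  if (identical(pain, c(FALSE, FALSE, TRUE, FALSE))) return("normal")
  if (pain[1L]) {
    return(if (sum(pain) == 1L) "phantom" else "wind_up")
  }
  if (pain[2L]) return("allodynia")
  "mixed"
}

#' Phase sweep over input intensities
#'
#' Trains a fresh random circuit per grid point on the four presence/absence
#' combinations at the given sensory (x) and nociceptive (y) intensities,
#' then classifies the resulting condition with [classify_condition()]
#' evaluated on the training combinations. Below the diagonal (sensory more
#' intense than nociceptive) standard gate behaviour is expected; above it,
#' the symmetric circuit treats touch as pain (dysesthesia/allodynia); very
#' weak or very intense corners drift into the wind-up and wind-down
#' classes. Near the diagonal the two inputs are indistinguishable and
#' outcomes become seed-dependent.
#'
#' @param sensory_grid,nociceptive_grid Intensity grids in `[0, 1]`.
#' @param iterations Training iterations per grid point.
#' @param seed Base seed; point `(i, j)` uses `seed + (j-1)*length(sensory
#'   grid) + (i-1)`.
#' @param ... Passed to [run_scenario()].
#' @return A character matrix of labels with sensory intensities as rows
#'   and nociceptive intensities as columns.
#' @export
phase_sweep <- function(sensory_grid, nociceptive_grid, iterations = 150,
                        seed = 1, ...) {
  if (any(sensory_grid < 0 | sensory_grid > 1) ||
      any(nociceptive_grid < 0 | nociceptive_grid > 1)) {
    stop("grids must lie in [0, 1]", call. = FALSE)
  }
  out <- matrix(NA_character_, length(sensory_grid), length(nociceptive_grid),
                dimnames = list(sensory = format(sensory_grid),
                                nociceptive = format(nociceptive_grid)))
  for (j in seq_along(nociceptive_grid)) {
    for (i in seq_along(sensory_grid)) {
      sc <- scenario(
        sprintf("sweep_%g_%g", sensory_grid[i], nociceptive_grid[j]),
        list(scenario_phase(
          combination_epoch(sensory_grid[i], nociceptive_grid[j]),
          iterations))
      )
      pt_seed <- seed + (j - 1L) * length(sensory_grid) + (i - 1L)
      tr <- run_scenario(sc, seed = pt_seed, ...)
      tab <- truth_table(tr$circuit,
                         combination_epoch(sensory_grid[i], nociceptive_grid[j]))
      out[i, j] <- classify_condition(tab)
    }
  }
  out
}

#' Write and read trajectory files
#'
#' The iteration log is written as plain CSV (one row per iteration) and the
#' run metadata (scenario name, seed, parameters) as a JSON sidecar next to
#' it (`<path>.json`).
#'
#' @param trajectory A `gate_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   a list with `log` and `meta`.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "gate_trajectory"))
  write.csv(trajectory$log, path, row.names = FALSE)
  meta <- list(scenario = trajectory$scenario, seed = trajectory$seed,
               params = trajectory$params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  log <- read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  }
  list(log = log, meta = meta)
}

#' Plot a trajectory
#'
#' Two-panel base-graphics view: parameter evolution (weights and shifts)
#' and the CT output ribbons (one line per epoch pair) along iterations.
#'
#' @param x A `gate_trajectory`.
#' @param ... Unused.
#' @export
plot.gate_trajectory <- function(x, ...) {
  log <- x$log
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(log$iteration, log[, c("w1", "w2", "w3", "w4", "s1", "s2")],
                    type = "l", lty = c(1, 1, 1, 1, 2, 2),
                    col = c(1, 2, 3, 4, 1, 2),
                    xlab = "iteration", ylab = "parameter",
                    main = sprintf("'%s': weights (solid) and shifts (dashed)",
                                   x$scenario))
  graphics::matplot(log$iteration, log[, c("o2_1", "o2_2", "o2_3", "o2_4")],
                    type = "l", lty = 1, col = c("darkblue", "cyan3",
                                                 "gold2", "darkred"),
                    ylim = c(0, 1), xlab = "iteration", ylab = "CT output O2",
                    main = "CT response per epoch pair")
  invisible(x)
}
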