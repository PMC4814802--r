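test_that("scenario runs are deterministic given a seed", {
  a <- run_scenario(scenario_standard(60), seed = 123)
  b <- run_scenario(scenario_standard(60), seed = 123)
  expect_identical(a$log, b$log)
  expect_identical(unclass(a$circuit), unclass(b$circuit))

  c <- run_scenario(scenario_standard(60), seed = 124)
  expect_false(identical(a$log, c$log))

  # one record per iteration, monotone index, phase bookkeeping
  tr <- run_scenario(scenario_wind_down(), seed = 1)
  expect_equal(nrow(tr$log), 150)
  expect_equal(tr$log$iteration, 1:150)
  expect_equal(as.vector(table(tr$log$phase)), c(50L, 50L, 50L))
  # single-pair phase logs one ribbon, NA elsewhere
  expect_true(all(is.na(tr$log$o2_2[tr$log$phase == 2])))
  expect_true(all(!is.na(tr$log$o2_4[tr$log$phase == 1])))
})

test_that("truth tables are pure and reproduce the printed arithmetic", {
  circ <- reference_circuit()
  t1 <- truth_table(circ, table3_epoch())
  t2 <- truth_table(circ, table3_epoch())
  expect_identical(t1, t2)

  # printed style: binary O1 compared against t1, then Net2 against t2
  tp <- truth_table(circ, table3_epoch(), style = "printed")
  expect_equal(tp$net1, c(0, 0.15, 0.6, 0.75))
  expect_equal(tp$o1, c(0, 0, 1, 1))
  expect_equal(tp$net2, c(0, 0.15, -1, -0.85))
  expect_equal(tp$o2, c(0, 1, 0, 0))
  # rate style agrees after binarization at the 0.5 cut
  expect_equal(t1$pain, tp$pain)
})

test_that("convergence detection distinguishes settled from oscillating", {
  make_log <- function(w3) {
    n <- length(w3)
    data.frame(iteration = 1:n, w1 = 1, w2 = 0, w3 = w3, w4 = 0.5,
               s1 = 0.5, s2 = 0.27, t1 = 0.5, t2 = 0.04,
               o2_1 = 0.1, o2_2 = 0, o2_3 = 1, o2_4 = 0)
  }
  # constant trajectory: converged, setpoint equals the constant
  res <- detect_convergence(make_log(rep(0.5, 200)), window = 100, tol = 1e-3)
  expect_true(res$converged)
  expect_equal(unname(res$setpoint["w3"]), 0.5)
  expect_equal(unname(res$setpoint["t2"]), 2 * 0.27 - 0.5)

  # square wave of amplitude 0.1: not converged
  res <- detect_convergence(make_log(0.5 + 0.05 * rep_len(c(-1, 1), 200)),
                            window = 100, tol = 1e-3)
  expect_false(res$converged)
  expect_gte(res$max_change, 0.1)

  expect_error(detect_convergence(make_log(rep(0.5, 50)), window = 100),
               "longer than")
})

test_that("condition classification follows the truth-table rules", {
  fake_table <- function(o2) {
    structure(
      data.frame(I1 = c(0, 0.6, 0, 0.6), I2 = c(0, 0, 0.3, 0.3),
                 net1 = NA, o1 = NA, net2 = NA, o2 = o2,
                 pain = as.integer(o2 > 0.5)),
      class = c("gate_truth_table", "data.frame"))
  }
  expect_equal(classify_condition(fake_table(c(0.1, 0, 1, 0))), "normal")
  expect_equal(classify_condition(fake_table(c(0.1, 0.2, 0.3, 0.1))), "wind_down")
  expect_equal(classify_condition(fake_table(c(0.9, 0, 0, 0))), "phantom")
  expect_equal(classify_condition(fake_table(c(0.9, 0, 0.8, 0))), "wind_up")
  expect_equal(classify_condition(fake_table(c(0.1, 0.9, 0.2, 0.1))), "allodynia")
  expect_equal(classify_condition(fake_table(c(0, 0, 0, 0.9))), "mixed")
  # the reference converged circuit is the conventional gate
  expect_equal(classify_condition(reference_circuit()), "normal")
})

test_that("multi-initialization studies summarize setpoint dispersion", {
  st <- multi_init_study(scenario_standard(200), n_runs = 3, seeds = 11:13,
                         window = 50)
  expect_length(st$trajectories, 3)
  expect_equal(dim(st$setpoints), c(3L, 6L))
  expect_length(st$truth_tables, 3)
  expect_gte(st$max_pairwise_distance, 0)
})

test_that("trajectories round-trip through CSV with a JSON sidecar", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  tr <- run_scenario(scenario_standard(30), seed = 9)
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$log, tr$log, tolerance = 1e-12)
  expect_equal(back$meta$scenario, "standard")
  expect_equal(back$meta$seed, 9)
  expect_equal(back$meta$params$upsilon, tr$params$upsilon)
})

test_that("the intensity sweep labels regimes on both sides of the diagonal", {
  # standard-regime point: sensory stronger than nociceptive -> normal gate
  grid <- phase_sweep(0.6, 0.3, iterations = 300, seed = 2)
  expect_equal(unname(grid[1, 1]), "normal")
  # mirrored point above the diagonal: touch is treated as pain
  grid2 <- phase_sweep(0.3, 0.6, iterations = 300, seed = 2)
  expect_equal(unname(grid2[1, 1]), "allodynia")
  # shape and labels of a small grid
  g <- phase_sweep(c(0.2, 0.6), c(0.3, 0.8), iterations = 40, seed = 3)
  expect_equal(dim(g), c(2L, 2L))
  expect_true(all(g %in% c("normal", "allodynia", "wind_up", "wind_down",
                           "phantom", "mixed")))
})
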