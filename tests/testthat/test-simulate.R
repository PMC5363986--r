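test_that("scenario construction validates events and initial states", {
  p <- crypt_params()
  g <- cell_graph(c("c1", "c2"), cbind("c1", "c2"))
  init <- standard_state(p, 1)
  expect_error(crypt_scenario(g, rbind(c1 = init, c2 = -init)),
               "non-negative")
  bad_ev <- data.frame(time_h = 60, cell = "c1", field = "W", value = 2)
  expect_error(crypt_scenario(g, rbind(c1 = init, c2 = init), hours = 48,
                              events = bad_ev), "within")
  bad_ev2 <- data.frame(time_h = 12, cell = "c1", field = "X", value = 2)
  expect_error(crypt_scenario(g, rbind(c1 = init, c2 = init), hours = 48,
                              events = bad_ev2), "field")
})

test_that("deterministic run reports the requested grid and stays finite", {
  p <- crypt_params()
  sc <- build_scenario("healthy_pair", p, hours = 2)
  tr <- run_deterministic(sc, p)
  expect_s3_class(tr, "crypt_trajectory")
  expect_equal(tr$times, seq(0, 120, by = 1))
  expect_true(all(is.finite(tr$conc)))
  expect_true(all(tr$conc >= 0))
  expect_equal(dim(tr$conc), c(121, 2, 12))
})

test_that("events switch the environment with continuous concentrations", {
  p <- crypt_params()
  sc <- build_scenario("wnt_hyper_pair", p, hours = 14)
  tr <- run_deterministic(sc, p)
  i <- which(tr$times == 12 * 60)
  # continuity across the W switch at 12 h
  expect_lt(abs(tr$conc[i, "cell2", "B"] - tr$conc[i - 1, "cell2", "B"]),
            0.05)
  # beta-catenin rises in the switched cell afterwards, not in the other
  expect_gt(tr$conc[i + 60, "cell2", "B"], tr$conc[i, "cell2", "B"] + 0.5)
  expect_lt(abs(tr$conc[i + 60, "cell1", "B"] - tr$conc[i, "cell1", "B"]),
            0.5)
})

test_that("GSK pool is conserved along deterministic trajectories", {
  p <- crypt_params()
  sc <- build_scenario("apc_mutant_pair", p, hours = 30)
  tr <- run_deterministic(sc, p)
  pool <- tr$conc[, , "G"] + tr$conc[, , "C"] + tr$conc[, , "I2"]
  expect_equal(max(abs(pool - 50)), 0, tolerance = 1e-5)
})

test_that("sigma = 0 stochastic matches deterministic on the same grid", {
  p <- crypt_params()
  sc <- build_scenario("healthy_pair", p, hours = 3)
  det <- run_deterministic(sc, p)
  sto <- run_stochastic(sc, p, sigma = 0, dt = 0.02, n_runs = 1, seed = 7)
  expect_equal(sto[[1]]$conc, det$conc, tolerance = 5e-3)
})

test_that("stochastic runs are seed-reproducible and seed-sensitive", {
  p <- crypt_params()
  sc <- build_scenario("healthy_pair", p, hours = 1)
  a <- run_stochastic(sc, p, sigma = 1, dt = 0.1, n_runs = 2, seed = 11)
  b <- run_stochastic(sc, p, sigma = 1, dt = 0.1, n_runs = 2, seed = 11)
  c <- run_stochastic(sc, p, sigma = 1, dt = 0.1, n_runs = 2, seed = 12)
  expect_identical(a[[1]]$conc, b[[1]]$conc)
  expect_identical(a[[2]]$conc, b[[2]]$conc)
  expect_false(identical(a[[1]]$conc, c[[1]]$conc))
})

test_that("noise enters Hes1 only and scales per mode", {
  p <- crypt_params()
  sc <- build_scenario("healthy_pair", p, hours = 1)
  det <- run_deterministic(sc, p)
  sto <- run_stochastic(sc, p, sigma = 1, dt = 0.1, n_runs = 1, seed = 3,
                        mode = "literal")[[1]]
  # Non-H1 species deviate only via dynamics driven by the noisy H1, so
  # at very early times their deviation is far smaller than H1's.
  i <- which(sto$times == 5)
  dev <- abs(sto$conc[i, "cell1", ] - det$conc[det$times == 5, "cell1", ])
  expect_gt(dev[["H1"]], 10 * dev[["N"]])
  # wiener mode at the same sigma/dt has larger increments than literal
  w <- run_stochastic(sc, p, sigma = 1, dt = 0.1, n_runs = 1, seed = 3,
                      mode = "wiener")[[1]]
  expect_gt(stats::sd(diff(w$conc[, "cell1", "H1"])),
            stats::sd(diff(sto$conc[, "cell1", "H1"])))
})

test_that("small-sigma ensemble mean tracks the deterministic trajectory", {
  p <- crypt_params()
  sc <- build_scenario("healthy_pair", p, hours = 2)
  det <- run_deterministic(sc, p)
  runs <- run_stochastic(sc, p, sigma = 0.01, dt = 0.1, n_runs = 200,
                         seed = 5)
  h1 <- sapply(runs, function(tr) tr$conc[, "cell1", "H1"])
  expect_equal(rowMeans(h1), det$conc[, "cell1", "H1"], tolerance = 0.01)
})

test_that("invalid stochastic inputs error", {
  p <- crypt_params()
  sc <- build_scenario("healthy_pair", p, hours = 1)
  expect_error(run_stochastic(sc, p, sigma = -1), "sigma")
  expect_error(run_stochastic(sc, p, dt = 0), "dt")
})

test_that("trajectory CSV export is tidy and round-readable", {
  p <- crypt_params()
  sc <- build_scenario("healthy_pair", p, hours = 1)
  tr <- run_deterministic(sc, p)
  f <- tempfile(fileext = ".csv"); m <- tempfile(fileext = ".json")
  write_trajectory(tr, f, m)
  tab <- utils::read.csv(f)
  expect_equal(names(tab), c("time_min", "cell", "species", "value"))
  expect_equal(nrow(tab), length(tr$times) * 2 * 12)
  man <- jsonlite::fromJSON(m)
  expect_true(all(c("params", "kind", "cells", "solver") %in% names(man)))
  unlink(c(f, m))
})
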