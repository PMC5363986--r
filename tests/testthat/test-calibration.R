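test_that("sensitivity_index on analytic outputs", {
  p <- crypt_params()
  s0 <- sensitivity_index(function(pp) 42, p, "kappa7")
  expect_equal(s0$S_k, 0)
  expect_equal(s0$NS_k, 0)
  expect_true(s0$ns_defined)
  # linear output X = 2 k: S = 2, NS = 1
  s1 <- sensitivity_index(function(pp) 2 * pp$kappa7, p, "kappa7")
  expect_equal(s1$S_k, 2, tolerance = 1e-10)
  expect_equal(s1$NS_k, 1, tolerance = 1e-10)
  # power law X = c k^2: NS ~ 2, independent of the scale c
  for (c0 in c(0.1, 7)) {
    s2 <- sensitivity_index(function(pp) c0 * pp$kappa7^2, p, "kappa7",
                            delta_frac = 1e-6)
    expect_equal(s2$NS_k, 2, tolerance = 1e-4)
  }
  # zero baseline output: NS undefined and flagged
  sz <- sensitivity_index(function(pp) pp$kappa7 - p$kappa7, p, "kappa7")
  expect_false(sz$ns_defined)
  expect_true(is.na(sz$NS_k))
  expect_error(sensitivity_index(function(pp) 1, p, "kappa7", 0),
               "positive")
  expect_error(sensitivity_index(function(pp) 1, p, "nope"), "unknown")
})

test_that("sensitivity_report ranks by |NS| and returns a permutation", {
  p <- crypt_params()
  nm <- c("alpha3", "alpha4", "mu_B", "kappa_A")
  rep1 <- sensitivity_report(function(pp) output_bstar(pp, 1), p, nm)
  expect_setequal(attr(rep1, "ranking"), nm)
  expect_equal(order(-abs(rep1$NS_k)), seq_len(nrow(rep1)))
  # alpha4 dominates the beta-catenin steady state at W = 1
  expect_equal(rep1$parameter[1], "alpha4")
})

test_that("mse matches hand-computed examples", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(1, 2, 3) + 0.5, c(1, 2, 3)), 0.25)
  expect_equal(mse(c(1, 2, 3), c(1, 1, 5)), 5 / 3)
  expect_error(mse(1:3, 1:4), "equal length")
  expect_error(mse(numeric(0), numeric(0)), "non-empty")
})

test_that("synthetic targets are exact at zero noise and seeded otherwise", {
  p <- crypt_params()
  sc <- build_scenario("healthy_pair", p, hours = 4)
  times <- c(0, 60, 120, 180, 240)
  tgt <- generate_synthetic_target(p, sc, "H1", times, noise_sd = 0)
  tr <- run_deterministic(sc, p)
  expect_equal(tgt$value,
               species_series(tr, "H1")[match(times, tr$times)])
  a <- generate_synthetic_target(p, sc, "H1", times, noise_sd = 0.3,
                                 seed = 4)
  b <- generate_synthetic_target(p, sc, "H1", times, noise_sd = 0.3,
                                 seed = 4)
  c <- generate_synthetic_target(p, sc, "H1", times, noise_sd = 0.3,
                                 seed = 5)
  expect_identical(a$value, b$value)
  expect_false(identical(a$value, c$value))
  # noise amplitude matches the requested SD over a dense sample
  all_t <- seq(0, 240, by = 1)
  dense <- generate_synthetic_target(p, sc, "H1", all_t, noise_sd = 0.5,
                                     seed = 8)
  resid <- dense$value - species_series(tr, "H1")
  expect_equal(stats::sd(resid), 0.5, tolerance = 0.15)
  expect_error(generate_synthetic_target(p, sc, "H1", c(0, 1e6)),
               "horizon")
})

test_that("sequential_fit minimises a convex quadratic within half a step", {
  p <- crypt_params()
  obj <- function(pp) (pp$kappa7 - 7)^2
  fit <- sequential_fit(obj, p, "kappa7", grid_points = 101,
                        tolerance_frac = 1, target_tol = 1e-2)
  spacing <- 2 * p$kappa7 / 100
  expect_lt(abs(fit$values[["kappa7"]] - 7), spacing / 2 + 1e-12)
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
  expect_equal(fit$termination, "converged")
  expect_error(sequential_fit(obj, p, "nope"), "unknown")
  expect_error(sequential_fit(function(pp) stop("boom"), p, "kappa7"),
               "starting")
  # finite at the start, non-finite at every grid evaluation
  calls <- 0
  bad <- function(pp) {
    calls <<- calls + 1
    if (calls == 1) 1 else NA_real_
  }
  expect_error(sequential_fit(bad, p, "kappa7", grid_points = 5,
                              max_loops = 1), "whole grid")
})

test_that("fit_production_rates inverts the decoupled steady state", {
  p <- crypt_params()
  b0 <- bstar_decoupled(p, 0); b1 <- bstar_decoupled(p, 1)
  rec <- fit_production_rates(p, c(0, 1), c(b0, b1))
  expect_equal(rec$alpha3, p$alpha3, tolerance = 1e-8)
  expect_equal(rec$alpha4, p$alpha4, tolerance = 1e-8)
  expect_error(fit_production_rates(p, c(1, 1), c(b0, b1)), "distinct")
  expect_error(fit_production_rates(p, c(0, 1), c(25, 3)), "non-positive")
})

test_that("steady-state objective recovers alpha4 within one grid step", {
  truth <- crypt_params()
  target <- output_bstar(truth, 1)
  start <- truth
  start$alpha4 <- truth$alpha4 * 1.5
  fit <- sequential_fit(function(pp) (output_bstar(pp, 1) - target)^2,
                        start, "alpha4", grid_points = 201,
                        tolerance_frac = 1)
  spacing <- 2 * start$alpha4 / 200
  expect_lt(abs(fit$values[["alpha4"]] - truth$alpha4), spacing)
})

test_that("6-point timecourse MSE objective recovers alpha4", {
  truth <- crypt_params()
  sc <- build_scenario("wnt_hyper_pair", truth, hours = 24)
  times <- c(4, 8, 12, 16, 20, 24) * 60
  tgt <- generate_synthetic_target(truth, sc, "B", times, noise_sd = 0,
                                   cell = "cell2")
  start <- truth
  start$alpha4 <- truth$alpha4 * 1.5
  obj <- function(pp) {
    tr <- run_deterministic(sc, pp)
    mse(species_series(tr, "B", "cell2")[match(times, tr$times)],
        tgt$value)
  }
  fit <- sequential_fit(obj, start, "alpha4", grid_points = 21,
                        tolerance_frac = 1, max_loops = 1)
  spacing <- 2 * start$alpha4 / 20
  expect_lt(abs(fit$values[["alpha4"]] - truth$alpha4), spacing)
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
})

test_that("period objective recovers a perturbed Notch parameter", {
  truth <- crypt_params()
  target <- output_period(truth)
  expect_false(is.na(target))
  start <- truth
  start$kappa5 <- truth$kappa5 * 1.5
  obj <- function(pp) {
    v <- output_period(pp)
    if (is.na(v)) 1e3 else (v - target)^2
  }
  fit <- sequential_fit(obj, start, "kappa5", grid_points = 21,
                        tolerance_frac = 1, max_loops = 1)
  spacing <- 2 * start$kappa5 / 20
  expect_lt(abs(fit$values[["kappa5"]] - truth$kappa5), spacing)
})
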