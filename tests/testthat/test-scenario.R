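# Counterfactual savings scenarios.

fit_stub <- function(b_prev = 0.104, b_cons = 0.113, V = NULL) {
  nm <- c("ln_prev_l1", "ln_cons_l1")
  if (is.null(V)) V <- matrix(0, 2, 2)
  dimnames(V) <- list(nm, nm)
  list(coefficients = stats::setNames(c(b_prev, b_cons), nm), vcov = V)
}

test_that("reduction paths compound multiplicatively", {
  expect_equal(scenario_path(0, 5), rep(1, 5))
  expect_equal(scenario_path(0.05, 1), 0.95)
  expect_equal(scenario_path(0.05, 5)[5], 0.95^5)
  expect_error(scenario_path(1, 5))
})

test_that("derived absolute reductions match the published magnitudes", {
  r <- derived_reductions(17.47, 325, 0.05)
  expect_equal(unname(r["prev_pp"]), 0.8735)
  expect_equal(round(unname(r["prev_pp"]), 2), 0.87)
  expect_equal(unname(r["cons_packs"]), 16.25)
  expect_equal(round(unname(r["cons_packs"])), 16)
  expect_equal(unname(derived_reductions(20, 400, 0.1)), c(2, 40))
  expect_equal(unname(derived_reductions(9, 9, 0)), c(0, 0))
})

test_that("zero reductions produce exactly zero savings with degenerate intervals", {
  sr <- simulate_savings(fit_stub(), scenario_spec(r_prev = 0, r_cons = 0,
                                                   n_trials = 1000, seed = 1),
                         9057)
  expect_true(all(sr$table$saving == 0))
  expect_true(all(sr$table$low == 0 & sr$table$high == 0))
})

test_that("with zero coefficient covariance the simulation is the plug-in value", {
  sr <- simulate_savings(fit_stub(), scenario_spec(n_trials = 1000, seed = 2),
                         9057)
  expect_equal(sr$table$saving, unname(sr$plugin), tolerance = 1e-12)
  expect_equal(sr$table$saving[1], 9057 * (1 - exp(0.217 * log(0.95))),
               tolerance = 1e-12)
  # near-linear accumulation over the five years
  expect_equal(sr$table$saving[5] / sr$table$saving[1], 4.89, tolerance = 0.01)
})

test_that("the Monte-Carlo mean converges to the closed form under uncertainty", {
  V <- matrix(c(0.0323^2, 0.0002, 0.0002, 0.0326^2), 2, 2)
  sr <- simulate_savings(fit_stub(V = V),
                         scenario_spec(n_trials = 50000, seed = 3), 9057)
  # the savings transform is nearly linear in the coefficients at these
  # scales, so the simulated mean sits within Monte-Carlo error of the
  # plug-in value
  draws_sd <- 9057 * 0.22 * sqrt(V[1, 1] + V[2, 2]) * log(0.95) * 5
  mc_se <- abs(draws_sd) / sqrt(50000)
  expect_lt(abs(sr$table$saving[1] - sr$plugin[1]), 30 * mc_se)
  expect_true(all(sr$table$low < sr$table$saving),
              all(sr$table$saving < sr$table$high))
  # interval width shrinks as the covariance is scaled toward zero
  sr_small <- simulate_savings(fit_stub(V = V * 0.01),
                               scenario_spec(n_trials = 50000, seed = 3), 9057)
  expect_lt(sr_small$table$high[1] - sr_small$table$low[1],
            (sr$table$high[1] - sr$table$low[1]) / 5)
})

test_that("savings are monotone in horizon and symmetric in the two levers", {
  sr <- simulate_savings(fit_stub(), scenario_spec(n_trials = 1000, seed = 4),
                         9057)
  expect_true(all(diff(sr$table$saving) > 0))
  a <- simulate_savings(fit_stub(0.104, 0.113),
                        scenario_spec(r_prev = 0.08, r_cons = 0.02,
                                      n_trials = 1000, seed = 5), 9057)
  b <- simulate_savings(fit_stub(0.113, 0.104),
                        scenario_spec(r_prev = 0.02, r_cons = 0.08,
                                      n_trials = 1000, seed = 5), 9057)
  expect_equal(a$table$saving, b$table$saving, tolerance = 1e-10)
})

test_that("a fixed seed reproduces the scenario result exactly", {
  V <- diag(c(0.001, 0.001))
  s1 <- simulate_savings(fit_stub(V = V), scenario_spec(n_trials = 2000,
                                                        seed = 9), 9057)
  s2 <- simulate_savings(fit_stub(V = V), scenario_spec(n_trials = 2000,
                                                        seed = 9), 9057)
  expect_identical(s1$table, s2$table)
})

test_that("national aggregation is per-capita times population", {
  expect_equal(aggregate_national(99, 318.2e6) / 1e9, 31.5, tolerance = 0.002)
  expect_equal(aggregate_national(c(low = 44, high = 154), 318.2e6) / 1e9,
               c(low = 14.0, high = 49.0), tolerance = 0.01)
  expect_equal(aggregate_national(0, 1e6), 0)
  expect_error(aggregate_national(10, -5))
})

test_that("the cross-sectional prevalence trend opts into the shock", {
  nm <- c("ln_prev_l1", "ln_cons_l1", "ln_avg_prev_l1")
  fit <- list(coefficients = stats::setNames(c(0.104, 0.113, 0.104), nm),
              vcov = matrix(0, 3, 3, dimnames = list(nm, nm)))
  base <- simulate_savings(fit, scenario_spec(r_cons = 0, n_trials = 1000,
                                              seed = 1), 9057)
  amp <- simulate_savings(fit, scenario_spec(r_cons = 0, n_trials = 1000,
                                             seed = 1,
                                             include_cs_trend = TRUE), 9057)
  # doubling the prevalence-side elasticity about doubles the saving
  expect_equal(amp$table$saving[1] / base$table$saving[1], 2, tolerance = 0.01)
})
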