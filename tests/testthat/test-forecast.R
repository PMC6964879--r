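# Recursive estimation and out-of-sample forecast evaluation.

test_that("recursive fitting adds one year of all states at a time", {
  p <- generate_panel(noiseless_cfg(31))$latent
  spec <- model_spec(bridge_mode = "none")
  rf1 <- recursive_fit(p, spec, base_end = 2006)
  expect_length(rf1$fits, 1L)
  single <- fe2sls(design_window(build_design(p, spec), 2006))
  expect_equal(coef(rf1$fits[[1]]), coef(single), tolerance = 1e-12)

  rf <- recursive_fit(p, spec, base_end = 2006, final_end = 2013)
  expect_length(rf$fits, 8L)
  ns <- vapply(rf$fits, nobs, numeric(1))
  expect_true(all(diff(ns) == 51))
})

test_that("noiseless data gives flat coefficient paths and zero forecast errors", {
  p <- generate_panel(noiseless_cfg(32))$latent
  spec <- model_spec(bridge_mode = "none")
  rf <- recursive_fit(p, spec, base_end = 2006, final_end = 2013)
  paths <- sapply(rf$fits, function(f) coef(f)[["ln_prev_l1"]])
  expect_lt(max(abs(paths - 0.104)), 1e-8)
  fs <- one_step_forecasts(rf)
  expect_equal(nrow(fs), 51L * 8L)
  expect_lt(max(abs(fs$yhat_log - fs$y_obs_log)), 1e-8)
  ms <- multi_step_forecasts(rf$fits[[1]], rf$design, horizon = 8)
  expect_lt(max(abs(ms$yhat_log - ms$y_obs_log)), 1e-8)
  # horizon 1 multi-step is the one-step forecast from the same origin
  m1 <- ms[ms$horizon == 1, ]
  f1 <- fs[fs$origin == 2006, ]
  expect_equal(m1$yhat_log, f1$yhat_log, tolerance = 1e-12)
})

test_that("one-step forecasts match a refit-from-scratch oracle on a toy panel", {
  p <- toy_panel(ns = 3, seed = 33, start = 2000, end = 2012)
  spec <- spec_min(instruments = list())
  rf <- recursive_fit(p, spec, base_end = 2008, final_end = 2010,
                      method = "ols")
  fs <- one_step_forecasts(rf)
  d <- build_design(p, spec)
  df <- data.frame(y = d$y, d$X, state = d$state, year = d$year,
                   check.names = FALSE)
  for (origin in 2008:2010) {
    fit <- stats::lm(stats::reformulate(c("state", colnames(d$X)), "y"),
                     data = df[df$year <= origin, ])
    pred <- stats::predict(fit, newdata = df[df$year == origin + 1, ])
    got <- fs$yhat_log[fs$origin == origin]
    expect_equal(unname(got), unname(pred), tolerance = 1e-8)
  }
})

test_that("forecasts use no information dated after the origin", {
  p <- generate_panel(small_cfg(34))$measured
  spec <- model_spec(bridge_mode = "none")
  rf <- recursive_fit(p, spec, base_end = 2008, final_end = 2008)
  fs <- one_step_forecasts(rf)
  # perturb the response in years strictly after the forecast target
  p2 <- as.data.frame(p)
  sel <- p2$year >= 2011
  p2$hexp[sel] <- p2$hexp[sel] * 1.5
  p2 <- state_panel(p2)
  rf2 <- recursive_fit(p2, spec, base_end = 2008, final_end = 2008)
  fs2 <- one_step_forecasts(rf2)
  expect_equal(fs$yhat_log, fs2$yhat_log, tolerance = 1e-12)
})

test_that("multi-step forecasts are no more accurate than one-step on average", {
  res <- vapply(1:5, function(i) {
    pm <- generate_panel(small_cfg(800 + i,
                                   break_mean = numeric(0),
                                   break_sd = numeric(0)))$measured
    spec <- model_spec(bridge_mode = "none")
    rf <- recursive_fit(pm, spec, base_end = 2007, final_end = 2011)
    one <- one_step_forecasts(rf)
    multi <- multi_step_forecasts(rf$fits[[1]], rf$design, horizon = 5)
    keep <- intersect(unique(one$target), unique(multi$target))
    r1 <- sqrt(mean((one$yhat_log - one$y_obs_log)[one$target %in% keep]^2))
    rm_ <- sqrt(mean((multi$yhat_log - multi$y_obs_log)[multi$target %in% keep]^2))
    rm_ - r1
  }, numeric(1))
  expect_gte(mean(res), 0)
})

test_that("forecast metrics follow their definitions", {
  fs <- data.frame(state = c("A", "B"), origin = 2000, target = 2001,
                   horizon = 1L,
                   yhat_log = c(log(110), log(95)), se_log = 0,
                   y_obs_log = c(log(100), log(100)),
                   yhat_level = c(110, 95), fallback = FALSE)
  class(fs) <- c("forecast_set", "data.frame")
  m <- forecast_metrics(fs)
  expect_equal(m$bias_pct, 2.5)    # mean of +10% and -5%
  expect_equal(m$rmsfe, sqrt(mean(c(log(1.1)^2, log(0.95)^2))))
  # perfect forecasts
  fs2 <- fs
  fs2$yhat_log <- fs2$y_obs_log
  fs2$yhat_level <- exp(fs2$y_obs_log)
  m2 <- forecast_metrics(fs2)
  expect_equal(m2$rmsfe, 0)
  expect_equal(m2$bias_pct, 0)
  expect_equal(m2$correlation, 1)
  # rmsfe of log errors +/- 0.01 is 0.01
  fs3 <- fs
  fs3$yhat_log <- fs3$y_obs_log + c(0.01, -0.01)
  expect_equal(forecast_metrics(fs3)$rmsfe, 0.01)
  expect_error(forecast_metrics(fs[0, ]), "no forecasts")
})

test_that("the lognormal back-transform is exact and monotone", {
  expect_equal(back_transform(0, 0), 1)
  expect_equal(back_transform(log(100), 0.0009), 100 * exp(0.00045))
  expect_lt(back_transform(1, 0.1), back_transform(1.2, 0.1))
  expect_lt(back_transform(1, 0.1), back_transform(1, 0.2))
  expect_error(back_transform(1, -0.1), "var_log")
  # matches the mean of exp(normal draws)
  set.seed(77)
  draws <- exp(rnorm(2e5, 3, 0.3))
  mc_se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(back_transform(3, 0.09) - mean(draws)), 3 * mc_se)
})
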