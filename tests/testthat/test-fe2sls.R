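test_that("within transform demeans by state and is idempotent", {
  p <- toy_panel(ns = 2, seed = 2, start = 2000, end = 2007)
  spec <- spec_min(instruments = list())
  d <- build_design(p, spec)
  wt <- within_transform(d)
  # group means are zero after demeaning
  expect_lt(max(abs(rowsum(wt$X, d$group))), 1e-10)
  expect_lt(max(abs(rowsum(wt$y, d$group))), 1e-10)
  # hand case: values (1,2,3) within one state demean to (-1,0,1)
  d2 <- list(y = rep(0, 6), X = cbind(v = c(1, 2, 3, 5, 7, 9)),
             Z = matrix(numeric(0), 6, 0),
             state = rep(c("A", "B"), each = 3),
             group = rep(c("A", "B"), each = 3))
  w2 <- within_transform(d2)
  expect_equal(unname(w2$X[, "v"]), c(-1, 0, 1, -2, 0, 2))
  # idempotence
  d3 <- d
  d3$X <- wt$X
  d3$y <- wt$y
  w3 <- within_transform(d3)
  expect_equal(w3$X, wt$X, tolerance = 1e-12)
})

test_that("state-constant columns are absorbed and reported, not silently dropped", {
  p <- toy_panel(ns = 3, seed = 5)
  spec <- spec_min(instruments = list())
  d <- build_design(p, spec)
  d$X <- cbind(d$X, state_dummy = as.numeric(d$state == d$state[1]))
  f <- fe2sls(d, method = "ols")
  expect_true("state_dummy" %in% f$absorbed)
  expect_false("state_dummy" %in% names(coef(f)))
})

test_that("2SLS with the endogenous column as its own instrument is OLS", {
  p <- toy_panel(ns = 4, seed = 6)
  spec <- spec_min(instruments = list())
  d <- build_design(p, spec)
  d$Z <- d$X[, "ln_cons_l1", drop = FALSE]
  colnames(d$Z) <- "iv_self"
  f_iv <- fe2sls(d)
  f_ols <- fe2sls(d, method = "ols")
  expect_equal(coef(f_iv), coef(f_ols), tolerance = 1e-10)
  expect_equal(f_iv$sigma, f_ols$sigma, tolerance = 1e-10)
})

test_that("2SLS equals an explicit two-stage regression oracle", {
  p <- toy_panel(ns = 3, seed = 8)
  spec <- spec_min()
  d <- build_design(p, spec)
  f <- fe2sls(d)
  # oracle: literal two stages with state dummies via lm()
  df <- data.frame(y = d$y, d$X, d$Z, state = d$state, check.names = FALSE)
  exog <- setdiff(colnames(d$X), "ln_cons_l1")
  fs <- stats::lm(stats::reformulate(c("state", exog, colnames(d$Z)),
                                     response = "ln_cons_l1"), data = df)
  df$cons_hat <- stats::fitted(fs)
  ss <- stats::lm(stats::reformulate(c("state", exog, "cons_hat"),
                                     response = "y"), data = df)
  oracle <- stats::coef(ss)[c(exog, "cons_hat")]
  names(oracle) <- c(exog, "ln_cons_l1")
  expect_equal(coef(f)[names(oracle)], oracle, tolerance = 1e-8)
})

test_that("estimates are invariant to shifting one state's level", {
  p <- toy_panel(ns = 4, seed = 12)
  spec <- spec_min()
  d <- build_design(p, spec)
  f1 <- fe2sls(d)
  d2 <- d
  d2$y[d$state == d$state[1]] <- d$y[d$state == d$state[1]] + 0.7
  f2 <- fe2sls(d2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  s1 <- unique(d$state)[1]
  expect_equal(unname(f2$fixed_effects[s1] - f1$fixed_effects[s1]), 0.7,
               tolerance = 1e-10)
})

test_that("cluster sandwich matches hand summation on a 2-cluster instance", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  u <- c(0.5, -0.2, 0.3, 0.1)
  cl <- factor(c("a", "a", "b", "b"))
  V <- smokecast:::sandwich_vcov(X, u, cl, small = TRUE)
  bread <- 1 / 30
  meat <- (1 * 0.5 + 2 * (-0.2))^2 + (3 * 0.3 + 4 * 0.1)^2
  corr <- (2 / 1) * (3 / 3)
  expect_equal(V[1, 1], corr * bread * meat * bread, tolerance = 1e-12)
  # zero residuals give a zero matrix
  V0 <- smokecast:::sandwich_vcov(X, rep(0, 4), cl)
  expect_equal(V0[1, 1], 0)
})

test_that("one observation per cluster reproduces the HC1 sandwich", {
  skip_if_not_installed("sandwich")
  set.seed(4)
  n <- 40
  X <- cbind(x1 = rnorm(n), x2 = runif(n))
  y <- drop(X %*% c(1, -2)) + rnorm(n)
  fit <- stats::lm(y ~ X - 1)
  u <- stats::residuals(fit)
  ours <- smokecast:::sandwich_vcov(X, u, factor(seq_len(n)), small = TRUE)
  hc1 <- sandwich::vcovHC(fit, type = "HC1")
  expect_equal(unname(ours), unname(hc1), tolerance = 1e-8)
})

test_that("normal 95% intervals reproduce the published arithmetic", {
  expect_equal(signif(ci_normal(0.104, 0.0323)[, "low"], 3), c(low = 0.0407))
  expect_equal(signif(ci_normal(0.104, 0.0323)[, "high"], 3), c(high = 0.167))
  expect_equal(signif(ci_normal(0.259, 0.0679)[, "high"], 3), c(high = 0.392))
  expect_equal(unname(ci_normal(5, 0)[1, ]), c(5, 5))
  expect_error(ci_normal(1, -0.1), "se")
})

test_that("panel R2 statistics behave at the analytic extremes", {
  g <- generate_panel(noiseless_cfg(21))
  d <- build_design(g$latent, model_spec(bridge_mode = "none"))
  # exact fit with identical intercepts across states: all R2 are 1
  b <- coef(fe2sls(d, method = "ols"))
  d$y <- drop(d$X[, names(b)] %*% b) + 2
  f <- fe2sls(d, method = "ols")
  r2 <- panel_r2(f)
  expect_equal(r2$within, 1, tolerance = 1e-6)
  expect_equal(r2$between, 1, tolerance = 1e-6)
  expect_equal(r2$total, 1, tolerance = 1e-6)
  expect_true(all(unlist(r2[c("within", "between", "total")]) <= 1 + 1e-9))
  # zero fixed-effect dispersion and positive error variance: rho = 0
  f$sigma <- 0.1
  expect_equal(panel_r2(f)$rho, 0)
})

test_that("panel R2 matches a spreadsheet-style computation on a small case", {
  p <- toy_panel(ns = 3, seed = 30)
  spec <- spec_min(instruments = list())
  d <- build_design(p, spec)
  f <- fe2sls(d, method = "ols")
  r2 <- panel_r2(f)
  xb <- drop(d$X[, names(coef(f))] %*% coef(f))
  dm <- function(v, g) v - ave(v, g)
  expect_equal(r2$within, cor(dm(xb, d$state), dm(d$y, d$state))^2,
               tolerance = 1e-10)
  mb <- function(v, g) tapply(v, g, mean)
  expect_equal(r2$between, cor(mb(xb, d$state), mb(d$y, d$state))^2,
               tolerance = 1e-10)
  expect_equal(r2$total, cor(xb, d$y)^2, tolerance = 1e-10)
  expect_equal(r2$corr_u_xb,
               cor(f$fixed_effects[sort(unique(d$state))],
                   as.numeric(mb(xb, d$state))), tolerance = 1e-10)
})

test_that("order condition and cluster prerequisites are enforced", {
  p <- toy_panel(ns = 3, seed = 14)
  spec <- spec_min(instruments = list(prev = 2))
  d <- build_design(p, spec)
  d$Z <- d$Z[, 0, drop = FALSE]   # no instruments but one endogenous column
  d$endogenous <- "ln_cons_l1"
  expect_error(fe2sls(d), "order condition")
})
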