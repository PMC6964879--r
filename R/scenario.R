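#' Cumulative multipliers of permanent annual relative reductions
#'
#' A permanent annual relative reduction `r` compounds multiplicatively:
#' the multiplier on the affected variable at forecast year t is
#' `(1 - r)^t` (5% a year for 5 years leaves 0.95^5 of the baseline).
#'
#' @param r Annual relative reduction, in `[0, 1)`.
#' @param horizon Number of years.
#' @return Numeric vector of multipliers for years 1..horizon.
#' @export
scenario_path <- function(r, horizon) {
  stopifnot(r >= 0, r < 1, horizon >= 1)
  (1 - r)^seq_len(horizon)
}

#' Absolute reductions implied by a relative reduction
#'
#' Converts a relative reduction into the absolute first-year changes the
#' scenario implies: percentage points of smoking prevalence and packs per
#' year of mean consumption (a 5% reduction from 17.47% prevalence is
#' about 0.87 percentage points; from 325 packs/year about 16 packs).
#'
#' @param national_prev National adult smoking prevalence, percent.
#' @param national_cons National mean consumption, packs/year.
#' @param r Relative reduction fraction.
#' @return Named vector: `prev_pp`, `cons_packs`.
#' @export
derived_reductions <- function(national_prev, national_cons, r) {
  stopifnot(national_prev > 0, national_cons > 0, r >= 0)
  c(prev_pp = r * national_prev, cons_packs = r * national_cons)
}

#' Scenario specification for counterfactual savings
#'
#' @param r_prev,r_cons Annual relative reductions in smoking prevalence
#'   and mean consumption (fractions; default 0.05 each).
#' @param horizon Forecast years (default 5).
#' @param n_trials Monte-Carlo trials (default 50000, >= 1000).
#' @param seed Seed for the coefficient draws.
#' @param baseline_year Label for the baseline year (metadata).
#' @param include_cs_trend Add the cross-sectional prevalence-trend
#'   elasticity to the prevalence shock (off by default: the trend
#'   correlation is not causal for new policy).
#' @param population Persons for national aggregation (default 318.2
#'   million).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(r_prev = 0.05, r_cons = 0.05, horizon = 5L,
                          n_trials = 50000L, seed = NULL,
                          baseline_year = 2014L, include_cs_trend = FALSE,
                          population = 318.2e6) {
  stopifnot(r_prev >= 0, r_prev < 1, r_cons >= 0, r_cons < 1,
            horizon >= 1, n_trials >= 1000, population > 0)
  structure(list(r_prev = r_prev, r_cons = r_cons, horizon = as.integer(horizon),
                 n_trials = as.integer(n_trials), seed = seed,
                 baseline_year = baseline_year,
                 include_cs_trend = isTRUE(include_cs_trend),
                 population = population),
            class = "scenario_spec")
}

#' Closed-form plug-in saving
#'
#' The deterministic counterpart of the Monte-Carlo simulation: with the
#' coefficients held at `beta`, the log-scale effect in year t is
#' `t * (b_prev * log(1 - r_prev) + b_cons * log(1 - r_cons))` and the
#' per-capita saving is `baseline * (1 - exp(effect))`. Used as the oracle
#' the simulated mean must converge to.
#'
#' @param b_prev,b_cons Elasticities of prevalence and consumption.
#' @param r_prev,r_cons Annual relative reductions.
#' @param baseline Per-capita baseline expenditure, dollars.
#' @param horizon Years.
#' @return Numeric vector of per-capita savings for years 1..horizon.
#' @export
plugin_saving <- function(b_prev, b_cons, r_prev, r_cons, baseline,
                          horizon = 5L) {
  t <- seq_len(horizon)
  eff <- t * (b_prev * log(1 - r_prev) + b_cons * log(1 - r_cons))
  baseline * (1 - exp(eff))
}

#' Monte-Carlo counterfactual expenditure savings
#'
#' Draws the elasticity vector from a multivariate normal centered at the
#' point estimates with the cluster-robust covariance (via its Cholesky
#' factor), propagates each draw through the compounded log-scale
#' reduction path, and reports, per forecast year, the mean per-capita
#' saving with 2.5/97.5 percentile prediction bounds, the saving as a
#' percent of baseline expenditure, and national totals. The regression-
#' error back-transformation applies identically to the factual and
#' counterfactual arm, so it cancels from the savings difference and is
#' not simulated.
#'
#' @param fit An [fe2sls()] fit (or a list with `coefficients` and `vcov`)
#'   providing the prevalence/consumption elasticities and covariance.
#' @param scen A [scenario_spec()].
#' @param baseline_expenditure Per-capita baseline expenditure in dollars
#'   (the study's 2014 national value is $9,057).
#' @param prev_col,cons_col,cs_prev_col Coefficient names; defaults match
#'   [build_design()] at lag 1.
#' @return A `scenario_result` with a per-year table and settings.
#' @export
simulate_savings <- function(fit, scen, baseline_expenditure,
                             prev_col = "ln_prev_l1", cons_col = "ln_cons_l1",
                             cs_prev_col = "ln_avg_prev_l1") {
  stopifnot(inherits(scen, "scenario_spec"), baseline_expenditure > 0)
  beta <- fit$coefficients
  V <- fit$vcov
  sel <- c(prev_col, cons_col)
  if (scen$include_cs_trend) {
    if (!cs_prev_col %in% names(beta)) {
      stop_sc("cross-sectional prevalence trend '%s' not in the fitted model",
              cs_prev_col)
    }
    sel <- c(sel, cs_prev_col)
  }
  missing_sel <- setdiff(sel, names(beta))
  if (length(missing_sel)) {
    stop_sc("coefficient(s) not in fit: %s", paste(missing_sel, collapse = ", "))
  }
  b <- beta[sel]
  Vb <- V[sel, sel, drop = FALSE]
  ev <- eigen((Vb + t(Vb)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1e-12)) {
    stop_sc("coefficient covariance is not positive semidefinite")
  }

  draws <- with_seed(scen$seed, {
    Z <- matrix(stats::rnorm(scen$n_trials * length(b)), scen$n_trials)
    R <- tryCatch(chol(Vb), error = function(e) {
      # PSD but singular: shift by a tiny ridge on the diagonal scale
      chol(Vb + diag(1e-12 * max(diag(Vb), 1e-300), nrow(Vb)))
    })
    sweep(Z %*% R, 2, b, "+")
  })
  colnames(draws) <- sel

  lp <- log(1 - scen$r_prev)
  lc <- log(1 - scen$r_cons)
  b_prev_eff <- draws[, prev_col] +
    if (scen$include_cs_trend) draws[, cs_prev_col] else 0
  slope <- b_prev_eff * lp + draws[, cons_col] * lc   # per-year log effect

  years <- seq_len(scen$horizon)
  tab <- do.call(rbind, lapply(years, function(t) {
    sav <- baseline_expenditure * (1 - exp(t * slope))
    qs <- stats::quantile(sav, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(year = t,
               saving = mean(sav), low = qs[1], high = qs[2],
               saving_pct = 100 * mean(sav) / baseline_expenditure,
               national = mean(sav) * scen$population,
               national_low = qs[1] * scen$population,
               national_high = qs[2] * scen$population)
  }))
  if (scen$r_prev == 0 && scen$r_cons == 0) {
    tab[, c("saving", "low", "high", "saving_pct",
            "national", "national_low", "national_high")] <- 0
  }
  structure(
    list(table = tab, baseline = baseline_expenditure,
         trials = scen$n_trials, seed = scen$seed, scenario = scen,
         plugin = plugin_saving(b[prev_col] +
                                  if (scen$include_cs_trend) b[cs_prev_col] else 0,
                                b[cons_col], scen$r_prev, scen$r_cons,
                                baseline_expenditure, scen$horizon)),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Expenditure savings, %d%%/yr prevalence and %d%%/yr consumption reduction (%s trials)\n",
              round(100 * x$scenario$r_prev), round(100 * x$scenario$r_cons),
              format(x$trials, big.mark = ",")))
  tab <- x$table
  tab$national <- tab$national / 1e9
  tab$national_low <- tab$national_low / 1e9
  tab$national_high <- tab$national_high / 1e9
  names(tab) <- c("year", "saving_$", "low95", "high95", "pct_of_baseline",
                  "national_$B", "nat_low95", "nat_high95")
  print(round(tab, 2), row.names = FALSE)
  invisible(x)
}

#' Aggregate per-capita savings to national totals
#'
#' @param per_capita Named or unnamed numeric vector (e.g. mean, low,
#'   high) of per-capita savings in dollars.
#' @param population Persons (> 0).
#' @return The vector multiplied by population (dollars).
#' @export
aggregate_national <- function(per_capita, population) {
  stopifnot(population > 0)
  per_capita * population
}
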