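#' Configuration for the synthetic state-panel generator
#'
#' The generator emulates the statistical structure the estimator assumes:
#' 51 states observed annually over 1992-2014; a cointegrating log-log
#' relation in which log real per capita healthcare expenditure responds to
#' the one-year-lagged logs of the state variables, to lagged logged
#' cross-sectional national averages, and to region-specific log tax terms,
#' around state fixed effects, with a stationary AR(1) error; common
#' national stochastic trends (random walks with drift) in the logs of the
#' seven averaged variables; mean-reverting state deviations from those
#' trends; classical measurement error on log consumption plus a component
#' proportional to the interstate tax differential (untaxed cross-border
#' sales make high-tax states under-measure consumption); and an additive
#' post-2011 level shift in the survey-measured variables (prevalence,
#' consumption, percent Black, percent Hispanic).
#'
#' Default elasticities are the model's 2014 estimates; the error process
#' targets serial correlation 0.56 and a stationary standard deviation of
#' 0.0301.
#'
#' @param n_states Number of states (51 = 50 states + DC).
#' @param start_year,end_year Panel years (1992-2014).
#' @param regions Optional character vector of length `n_states` assigning
#'   each state a BEA region; default round-robin over the eight regions.
#' @param true_beta Named elasticities of the six state regressors.
#' @param true_gamma Named elasticities of the cross-sectional averages
#'   entering the generating equation.
#' @param true_tau Named region-specific tax elasticities.
#' @param fixed_effect_sd Cross-state sd of the state constants (log scale).
#' @param error_ar1,error_sd AR(1) coefficient and *stationary* sd of the
#'   regression error.
#' @param trend_drift,trend_sd Drift and innovation sd of the national
#'   random-walk trends for the logs of each variable (incl. tax).
#' @param state_ar1,state_sd AR(1) coefficient and innovation sd of each
#'   state's log deviation from its national trend.
#' @param init_level,init_sd Initial national level of each variable and
#'   the cross-state sd of initial log deviations.
#' @param trend_cor Pairwise correlation of the national trend innovations
#'   (a shared macro factor; the cross-sectional averages are highly
#'   mutually correlated in the data the generator emulates).
#' @param prev_cons_cor Correlation between state-level prevalence and
#'   consumption innovations.
#' @param cons_meas_sd Sd of classical iid noise on measured log consumption.
#' @param cons_meas_tax Loading of measured log consumption on the state
#'   tax differential (dollars over the national mean); negative so high-tax
#'   states under-measure consumption.
#' @param break_year First survey year affected by the BRFSS redesign.
#' @param break_mean,break_sd Mean and cross-state sd of the additive
#'   post-break level shifts on the survey variables (percentage points for
#'   prevalence/Black/Hispanic, packs/year for consumption). Zero length
#'   disables the break.
#' @param population_log_mean,population_log_sd,population_growth Resident
#'   population levels (lognormal across states) and annual growth.
#' @param seed Integer seed; the same seed reproduces the panel exactly.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_states = 51L,
                         start_year = 1992L, end_year = 2014L,
                         regions = NULL,
                         true_beta = c(prev = 0.104, cons = 0.113,
                                       income = 0.259, elderly = 0.493,
                                       black = 0.00935, hispanic = 0.0121),
                         true_gamma = c(elderly = -0.521, hispanic = 0.0478,
                                        hexp = 0.784),
                         true_tau = c(NE = 0.0802, ME = 0.0167, GL = -0.00722,
                                      PL = 0.0196, SE = -0.00381, SW = 0.0113,
                                      RM = -0.00301, FW = 0.0277),
                         fixed_effect_sd = 0.124,
                         error_ar1 = 0.56,
                         error_sd = 0.0301,
                         trend_drift = c(prev = -0.02, cons = -0.02,
                                         income = 0.025, elderly = 0.008,
                                         black = 0.002, hispanic = 0.03,
                                         tax = 0.04),
                         trend_sd = c(prev = 0.015, cons = 0.02,
                                      income = 0.012, elderly = 0.004,
                                      black = 0.004, hispanic = 0.008,
                                      tax = 0.03),
                         state_ar1 = 0.85,
                         state_sd = c(prev = 0.02, cons = 0.02,
                                      income = 0.008, elderly = 0.006,
                                      black = 0.012, hispanic = 0.015,
                                      tax = 0.05),
                         init_level = c(hexp = 4800, prev = 23, cons = 400,
                                        income = 35000, elderly = 12.5,
                                        black = 10, hispanic = 8, tax = 0.8),
                         init_sd = c(prev = 0.12, cons = 0.12, income = 0.15,
                                     elderly = 0.10, black = 0.8,
                                     hispanic = 0.9, tax = 0.30),
                         trend_cor = 0.6,
                         prev_cons_cor = 0.5,
                         cons_meas_sd = 0.02,
                         cons_meas_tax = -0.05,
                         break_year = 2011L,
                         break_mean = c(prev = 1.5, cons = -15,
                                        black = 0.3, hispanic = 0.4),
                         break_sd = c(prev = 1.2, cons = 18,
                                      black = 0.3, hispanic = 0.5),
                         population_log_mean = log(5e6),
                         population_log_sd = 1,
                         population_growth = 0.009,
                         seed = NULL) {
  if (abs(error_ar1) >= 1) stop_sc("error_ar1 must lie in (-1, 1)")
  sds <- c(fixed_effect_sd, error_sd, trend_sd, state_sd, init_sd,
           cons_meas_sd, break_sd, population_log_sd)
  if (any(sds < 0)) stop_sc("all standard deviations must be >= 0")
  if (end_year - start_year < 5) stop_sc("panel horizon too short for lag structure")
  if (is.null(regions)) {
    regions <- rep(bea_regions(), length.out = n_states)
  }
  if (length(regions) != n_states) stop_sc("regions must have length n_states")
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic state panel
#'
#' Returns both the latent panel (true values, the ones the structural
#' equation uses) and the measured panel (consumption carrying measurement
#' error, survey variables carrying the post-break level shift), plus a
#' generation report with the realized error serial correlation, the
#' realized fixed-effect dispersion, and the realized break shifts.
#'
#' @param cfg A [synth_config()].
#' @return List with elements `latent` ([state_panel()]), `measured`
#'   ([state_panel()]) and `report`.
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, generate_panel_impl(cfg))
}

generate_panel_impl <- function(cfg) {
  ns <- cfg$n_states
  states <- sprintf("S%02d", seq_len(ns))
  xvars <- c("prev", "cons", "income", "elderly", "black", "hispanic", "tax")
  # x paths start two years before the panel: one for the regressor lag of
  # the first expenditure year, one for calibration of the state constants.
  yrs_x <- (cfg$start_year - 2L):cfg$end_year
  Tx <- length(yrs_x)

  # national log trends: random walks with drift whose innovations share a
  # common macro factor (the cross-sectional averages move together, which
  # is what makes separating them hard)
  cc <- cfg$trend_cor
  factor_t <- stats::rnorm(Tx - 1)
  trend <- sapply(xvars, function(v) {
    z <- stats::rnorm(Tx - 1)
    innov <- cfg$trend_drift[[v]] + cfg$trend_sd[[v]] *
      (sqrt(cc) * factor_t + sqrt(1 - cc) * z)
    log(cfg$init_level[[v]]) + c(0, cumsum(innov))
  })

  # state log deviations from trend: AR(1), initialized with dispersion
  offsets <- list()
  for (v in xvars) {
    o <- matrix(0, ns, Tx)
    o[, 1] <- stats::rnorm(ns, 0, cfg$init_sd[[v]])
    innov <- matrix(stats::rnorm(ns * (Tx - 1), 0, cfg$state_sd[[v]]), ns, Tx - 1)
    if (v == "cons" && cfg$prev_cons_cor != 0) {
      r <- cfg$prev_cons_cor
      innov <- r * attr(offsets[["prev"]], "innov") *
        (cfg$state_sd[["cons"]] / max(cfg$state_sd[["prev"]], 1e-12)) +
        sqrt(1 - r^2) * innov
    }
    for (t in 2:Tx) o[, t] <- cfg$state_ar1 * o[, t - 1] + innov[, t - 1]
    attr(o, "innov") <- innov
    offsets[[v]] <- o
  }

  lnx <- lapply(xvars, function(v) sweep(offsets[[v]], 2, trend[, v], "+"))
  names(lnx) <- xvars

  # regression error: AR(1) with stationary sd error_sd, one burn-in year
  yrs_h <- (cfg$start_year - 1L):cfg$end_year   # expenditure years
  Th <- length(yrs_h)
  rho <- cfg$error_ar1
  innov_sd <- cfg$error_sd * sqrt(1 - rho^2)
  eps <- matrix(0, ns, Th)
  eps[, 1] <- stats::rnorm(ns, 0, cfg$error_sd)
  for (t in 2:Th) eps[, t] <- rho * eps[, t - 1] + stats::rnorm(ns, 0, innov_sd)

  beta <- cfg$true_beta
  gamma <- cfg$true_gamma
  tau <- cfg$true_tau[cfg$regions]

  xb <- function(tix) {
    # tix indexes yrs_x; structural score at regressor date yrs_x[tix]
    s <- rep(0, ns)
    for (v in names(beta)) s <- s + beta[[v]] * lnx[[v]][, tix]
    for (v in setdiff(names(gamma), "hexp")) {
      s <- s + gamma[[v]] * log(mean(exp(lnx[[v]][, tix])))
    }
    s + tau * lnx[["tax"]][, tix]
  }

  # calibrate state constants so the process starts near equilibrium at
  # init_level hexp, with fixed-effect dispersion fixed_effect_sd
  fe_dev <- stats::rnorm(ns, 0, cfg$fixed_effect_sd)
  g_h <- if ("hexp" %in% names(gamma)) gamma[["hexp"]] else 0
  lnh0 <- log(cfg$init_level[["hexp"]]) + fe_dev + eps[, 1]
  alpha <- (lnh0 - eps[, 1]) - xb(1L) - g_h * log(cfg$init_level[["hexp"]])

  lnh <- matrix(NA_real_, ns, Th)
  lnh[, 1] <- lnh0
  for (t in 2:Th) {
    tix <- t  # yrs_h[t] - 1 == yrs_x[t]; regressors dated one year earlier
    avg_h <- log(mean(exp(lnh[, t - 1])))
    lnh[, t] <- alpha + xb(tix) + g_h * avg_h + eps[, t]
  }

  pop0 <- exp(stats::rnorm(ns, cfg$population_log_mean, cfg$population_log_sd))
  keep_x <- match(cfg$start_year:cfg$end_year, yrs_x)
  keep_h <- match(cfg$start_year:cfg$end_year, yrs_h)
  ny <- length(keep_h)
  years <- rep(cfg$start_year:cfg$end_year, each = ns)

  base <- data.frame(
    state = rep(states, times = ny),
    year = years,
    region = rep(cfg$regions, times = ny),
    hexp = as.vector(exp(lnh[, keep_h])),
    prev = as.vector(exp(lnx$prev[, keep_x])),
    cons = as.vector(exp(lnx$cons[, keep_x])),
    income = as.vector(exp(lnx$income[, keep_x])),
    elderly = as.vector(exp(lnx$elderly[, keep_x])),
    black = as.vector(exp(lnx$black[, keep_x])),
    hispanic = as.vector(exp(lnx$hispanic[, keep_x])),
    tax = as.vector(exp(lnx$tax[, keep_x])),
    population = as.vector(outer(pop0, (1 + cfg$population_growth)^(0:(ny - 1)))),
    stringsAsFactors = FALSE
  )
  latent <- state_panel(base)

  # measurement error on consumption: classical noise plus a loading on the
  # interstate tax differential (dollars over the cross-state mean)
  measured <- base
  if (cfg$cons_meas_sd > 0 || cfg$cons_meas_tax != 0) {
    tax_lvl <- measured$tax
    tax_mean <- stats::ave(tax_lvl, measured$year, FUN = mean)
    noise <- stats::rnorm(nrow(measured), 0, cfg$cons_meas_sd)
    measured$cons <- measured$cons *
      exp(noise + cfg$cons_meas_tax * (tax_lvl - tax_mean))
  }

  # post-break additive level shifts on the survey-measured variables
  shifts <- NULL
  if (length(cfg$break_mean)) {
    shifts <- lapply(stats::setNames(names(cfg$break_mean), names(cfg$break_mean)),
                     function(v) {
                       stats::setNames(
                         stats::rnorm(ns, cfg$break_mean[[v]], cfg$break_sd[[v]]),
                         states)
                     })
    measured <- as.data.frame(
      apply_break(state_panel(measured), cfg$break_year, shifts))
  }
  measured <- state_panel(measured)

  eps_panel <- eps[, keep_h]
  # AR(1) fitted without intercept (the error process has known mean zero)
  ar1 <- apply(eps_panel, 1, function(e) {
    if (stats::sd(e) == 0) return(NA_real_)
    sum(e[-1] * e[-length(e)]) / sum(e[-length(e)]^2)
  })
  report <- list(
    residual_ar1_mean = mean(ar1, na.rm = TRUE),
    fixed_effect_sd = stats::sd(alpha),
    fixed_effect_dev_sd = stats::sd(fe_dev),
    break_shift_means = if (is.null(shifts)) NULL else
      vapply(shifts, mean, numeric(1)),
    seed = cfg$seed
  )

  list(latent = latent, measured = measured, report = report)
}

#' Apply an additive survey-break level shift to a panel
#'
#' Shifts the named variables by per-state constants for all years at or
#' after `break_year`, emulating a survey-methodology change that moves
#' reported levels without changing time paths.
#'
#' @param panel A [state_panel()].
#' @param break_year First shifted year.
#' @param shifts Named list (by variable) of either a single number or a
#'   named per-state vector of additive shifts on the level scale.
#' @return The shifted [state_panel()].
#' @export
apply_break <- function(panel, break_year, shifts) {
  stopifnot(inherits(panel, "state_panel"))
  if (break_year < min(panel$year) || break_year > max(panel$year)) {
    stop_sc("break year %d outside panel range", break_year)
  }
  df <- as.data.frame(panel)
  post <- df$year >= break_year
  for (v in names(shifts)) {
    s <- shifts[[v]]
    add <- if (length(s) == 1L && is.null(names(s))) {
      rep(as.numeric(s), nrow(df))
    } else {
      as.numeric(s[df$state])
    }
    newv <- df[[v]] + ifelse(post, add, 0)
    bad <- which(!is.na(newv) & newv <= 0 & v %in% log_fields())
    if (length(bad)) {
      stop_sc("break shift drives '%s' non-positive at state %s, year %d",
              v, df$state[bad[1]], df$year[bad[1]])
    }
    df[[v]] <- newv
  }
  state_panel(df)
}
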