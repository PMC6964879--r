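#' Declare one regression specification
#'
#' A model spec describes a single candidate regression: which state-level
#' regressors enter, which cross-sectional national averages control for
#' common trends, whether region-specific tax elasticities are included,
#' which regressors are treated as mismeasured and instrumented by deeper
#' lags, how the 2011 survey break is bridged, and the sample window.
#'
#' @param state_vars Ordered names of the state-specific regressors; the
#'   default is the model's six: prevalence, mean consumption, income,
#'   percent elderly, percent African-American, percent Hispanic.
#' @param cs_averages Subset of [cs_average_candidates()] whose lagged
#'   equally-weighted cross-state averages enter as common-trend controls.
#' @param tax_by_region Logical; include the eight region-specific
#'   `region x log real tax` terms.
#' @param endogenous Regressors treated as mismeasured and instrumented
#'   (default mean consumption).
#' @param instruments Named list mapping a variable name to the lag depths
#'   used as excluded instruments; default prevalence at lags 2 and 3 plus
#'   consumption at lag 3. All lags must be strictly deeper than `lag`.
#' @param lag Regression lag of the explanatory variables (default 1).
#' @param bridge_mode How the survey break is bridged: `"none"`,
#'   `"intercept_shift"` (a second state-specific constant for post-break
#'   observations), `"slope_shift"` (common post-break slope interactions on
#'   the survey-measured variables), or `"both"`.
#' @param break_align Whether the post-break era of a row is indexed on the
#'   regressor date `t - lag` (the date at which the survey-measured
#'   regressors actually break; the default) or on the observation
#'   (response) year.
#' @param break_year First survey year affected by the redesign (2011).
#' @param sample_start,sample_end Response-year window; `NULL` means use the
#'   full panel range.
#' @param extra_covariates Optional names of additional panel columns to be
#'   entered (logged, lagged) as state-specific regressors.
#' @return A `model_spec` object.
#' @export
model_spec <- function(state_vars = c("prev", "cons", "income", "elderly",
                                      "black", "hispanic"),
                       cs_averages = c("elderly", "hispanic", "hexp"),
                       tax_by_region = TRUE,
                       endogenous = "cons",
                       instruments = list(prev = c(2, 3), cons = 3),
                       lag = 1L,
                       bridge_mode = c("none", "intercept_shift",
                                       "slope_shift", "both"),
                       break_align = c("regressor", "response"),
                       break_year = 2011L,
                       sample_start = NULL,
                       sample_end = NULL,
                       extra_covariates = character()) {
  bridge_mode <- match.arg(bridge_mode)
  break_align <- match.arg(break_align)
  if (anyDuplicated(cs_averages)) stop_sc("duplicate cross-sectional average names")
  bad <- setdiff(cs_averages, cs_average_candidates())
  if (length(bad)) {
    stop_sc("cross-sectional average(s) not among the 7 candidates: %s",
            paste(bad, collapse = ", "))
  }
  if (!all(endogenous %in% state_vars)) {
    stop_sc("endogenous regressors must be listed in state_vars")
  }
  lag <- as.integer(lag)
  if (lag < 1L) stop_sc("lag must be >= 1")
  inst_lags <- unlist(instruments, use.names = FALSE)
  if (length(inst_lags) && any(inst_lags <= lag)) {
    stop_sc("instruments must use lags strictly deeper than the regression lag (%d)", lag)
  }
  spec <- structure(
    list(state_vars = state_vars, cs_averages = cs_averages,
         tax_by_region = isTRUE(tax_by_region), endogenous = endogenous,
         instruments = instruments, lag = lag, bridge_mode = bridge_mode,
         break_align = break_align, break_year = as.integer(break_year),
         sample_start = sample_start, sample_end = sample_end,
         extra_covariates = extra_covariates),
    class = "model_spec")
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model specification (log-log, lag", x$lag, ")\n")
  cat("  state regressors :", paste(x$state_vars, collapse = ", "), "\n")
  cat("  cross-sectional averages:",
      if (length(x$cs_averages)) paste(x$cs_averages, collapse = ", ") else "(none)", "\n")
  cat("  region-specific tax terms:", x$tax_by_region, "\n")
  cat("  endogenous:", paste(x$endogenous, collapse = ", "),
      " instruments:",
      paste(sprintf("%s(l%s)", names(x$instruments),
                    vapply(x$instruments, function(l) paste(l, collapse = ","), "")),
            collapse = " "), "\n")
  cat("  bridge:", x$bridge_mode, "at", x$break_year, "\n")
  invisible(x)
}

spec_id <- function(spec) {
  paste0("cs[", paste(sort(spec$cs_averages), collapse = "+"), "]",
         if (spec$bridge_mode != "none") paste0(":", spec$bridge_mode) else "")
}

# Deepest lag needed to build a design row (regressors + instruments).
max_lag <- function(spec) {
  max(c(spec$lag, unlist(spec$instruments, use.names = FALSE), 0L))
}
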