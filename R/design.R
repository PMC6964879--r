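#' Build the lagged log-log design matrix for one specification
#'
#' Assembles, from a [state_panel()] and a [model_spec()], the estimation
#' design: response `ln hexp` at year t; logged state regressors at t-lag;
#' logged equally-weighted cross-sectional national averages at t-lag
#' (averaged on the raw scale over all states observed that year, then
#' logged); the eight region-specific `log real tax` columns when enabled;
#' post-break slope interactions for the survey-measured variables when the
#' bridge mode asks for them; and the excluded-instrument columns (deeper
#' lags of prevalence and consumption). Rows with any missing ingredient are
#' dropped (listwise deletion). The post-break era of a row is indexed on
#' the regressor date `t - lag`, since that is the date at which the
#' survey-measured regressors break.
#'
#' @param panel A [state_panel()].
#' @param spec A [model_spec()].
#' @return A `panel_design` object: response `y`, regressor matrix `X`,
#'   excluded instruments `Z`, row index (`state`, `year`, `region`,
#'   `post`), fixed-effect grouping `group`, endogenous column names, and
#'   the spec.
#' @export
build_design <- function(panel, spec) {
  stopifnot(inherits(panel, "state_panel"), inherits(spec, "model_spec"))
  panel <- panel[order(panel$state, panel$year), , drop = FALSE]
  ml <- max_lag(spec)
  yr_min <- min(panel$year)
  yr_max <- max(panel$year)
  sample_start <- spec$sample_start %||% (yr_min + ml)
  sample_end <- spec$sample_end %||% yr_max
  if (sample_start > sample_end) stop_sc("empty sample window")
  if (spec$bridge_mode != "none" &&
      !(spec$break_year > sample_start && spec$break_year <= sample_end)) {
    stop_sc("bridge mode '%s' requires break year %d inside the sample window (%d, %d]",
            spec$bridge_mode, spec$break_year, sample_start, sample_end)
  }

  key <- paste(panel$state, panel$year)
  lagged <- function(var, k) {
    panel[[var]][match(paste(panel$state, panel$year - k), key)]
  }

  rows <- panel$year >= sample_start & panel$year <= sample_end
  take <- function(v) v[rows]

  y <- log(panel$hexp)[rows]
  state <- panel$state[rows]
  year <- panel$year[rows]
  region <- panel$region[rows]

  all_state_vars <- c(spec$state_vars, spec$extra_covariates)
  cols <- list()
  for (v in all_state_vars) {
    if (is.null(panel[[v]])) stop_sc("regressor '%s' not in panel", v)
    cols[[sprintf("ln_%s_l%d", v, spec$lag)]] <- log(take(lagged(v, spec$lag)))
  }

  # equally-weighted cross-state averages (raw scale, then logged) by year
  if (length(spec$cs_averages)) {
    for (v in spec$cs_averages) {
      avg <- tapply(panel[[v]], panel$year, mean, na.rm = TRUE)
      a <- as.numeric(avg[as.character(year - spec$lag)])
      a[is.nan(a)] <- NA_real_
      cols[[sprintf("ln_avg_%s_l%d", v, spec$lag)]] <- log(a)
    }
  }

  if (spec$tax_by_region) {
    ln_tax <- log(take(lagged("tax", spec$lag)))
    for (r in bea_regions()) {
      cols[[paste0("ln_tax_", r)]] <- ifelse(region == r, ln_tax, 0)
    }
    # rows missing tax must drop even outside their region column
    tax_na <- is.na(ln_tax)
  } else {
    tax_na <- rep(FALSE, length(y))
  }

  post <- if ((spec$break_align %||% "regressor") == "response") {
    year >= spec$break_year
  } else {
    (year - spec$lag) >= spec$break_year
  }
  if (spec$bridge_mode %in% c("slope_shift", "both")) {
    sv <- intersect(spec$state_vars, survey_fields())
    for (v in sv) {
      cols[[sprintf("post_x_ln_%s_l%d", v, spec$lag)]] <-
        as.numeric(post) * cols[[sprintf("ln_%s_l%d", v, spec$lag)]]
    }
    for (v in intersect(spec$cs_averages, survey_fields())) {
      cols[[sprintf("post_x_ln_avg_%s_l%d", v, spec$lag)]] <-
        as.numeric(post) * cols[[sprintf("ln_avg_%s_l%d", v, spec$lag)]]
    }
  }

  X <- do.call(cbind, cols)

  zcols <- list()
  for (nm in names(spec$instruments)) {
    for (k in spec$instruments[[nm]]) {
      zcols[[sprintf("iv_ln_%s_l%d", nm, k)]] <- log(take(lagged(nm, k)))
    }
  }
  Z <- if (length(zcols)) do.call(cbind, zcols) else
    matrix(numeric(0), nrow = length(y), ncol = 0)

  keep <- !is.na(y) & !tax_na &
    rowSums(is.na(X)) == 0 &
    (ncol(Z) == 0 | rowSums(is.na(Z)) == 0)
  if (!any(keep)) stop_sc("design is empty after listwise deletion")

  intercept_bridged <- spec$bridge_mode %in% c("intercept_shift", "both")
  group <- if (intercept_bridged) {
    paste0(state, ifelse(post, ":post", ":pre"))
  } else {
    state
  }

  endo <- sprintf("ln_%s_l%d", spec$endogenous, spec$lag)

  structure(
    list(y = y[keep],
         X = X[keep, , drop = FALSE],
         Z = Z[keep, , drop = FALSE],
         state = state[keep], year = year[keep], region = region[keep],
         post = post[keep], group = group[keep],
         endogenous = endo,
         spec = spec,
         sample_start = sample_start, sample_end = sample_end),
    class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat("Panel design:", length(x$y), "rows,",
      ncol(x$X), "regressors,", ncol(x$Z), "excluded instruments\n")
  cat("  response years", min(x$year), "-", max(x$year),
      " states:", length(unique(x$state)), "\n")
  invisible(x)
}

# Restrict a design to response years <= end (used by recursive fitting).
design_window <- function(design, end, start = NULL) {
  keep <- design$year <= end
  if (!is.null(start)) keep <- keep & design$year >= start
  if (!any(keep)) stop_sc("no design rows in window ending %d", end)
  out <- design
  for (f in c("y", "state", "year", "region", "post", "group")) {
    out[[f]] <- design[[f]][keep]
  }
  out$X <- design$X[keep, , drop = FALSE]
  out$Z <- design$Z[keep, , drop = FALSE]
  out$sample_end <- end
  out
}
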