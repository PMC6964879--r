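#' Recursive (expanding-window) estimation
#'
#' Re-estimates the model on expanding samples: the first fit uses response
#' years up to `base_end`, then one year of all states' data is added at a
#' time until `final_end`. Forecast origins use no data dated later than
#' the origin year by construction (the design row for response year t only
#' involves data up to t).
#'
#' @param panel A [state_panel()].
#' @param spec A [model_spec()].
#' @param base_end Last response year of the base estimation window.
#' @param final_end Last response year of the final window.
#' @param method Passed to [fe2sls()].
#' @return A `recursive_fits` list: one [fe2sls()] fit per sample end year,
#'   plus the shared full-sample design used for prediction rows.
#' @export
recursive_fit <- function(panel, spec, base_end, final_end = base_end,
                          method = "2sls") {
  if (final_end < base_end) stop_sc("final_end must be >= base_end")
  full <- build_design(panel, spec)
  ends <- base_end:final_end
  fits <- lapply(ends, function(e) {
    d <- tryCatch(design_window(full, e),
                  error = function(err) stop_sc("window ending %d: %s", e,
                                                conditionMessage(err)))
    tryCatch(fe2sls(d, method = method),
             error = function(err) stop_sc("estimation failed for window ending %d: %s",
                                           e, conditionMessage(err)))
  })
  structure(list(fits = fits, ends = ends, design = full, spec = spec),
            class = "recursive_fits")
}

#' One-step-ahead out-of-sample forecasts
#'
#' For each recursive fit ending at origin year t, forecasts log real per
#' capita expenditure for every state at t+1 using the regressors dated
#' t - lag + 1 (i.e. the design row for response year t+1) and that state's
#' fixed effect -- the post-break intercept once post-break observations
#' are in the estimation sample, with a flagged fall-back to the pre-break
#' intercept before that. Level forecasts apply the lognormal
#' back-transformation with the regression error variance.
#'
#' @param rf A [recursive_fit()] result.
#' @param panel Optional panel to rebuild prediction rows from; defaults to
#'   the design already inside `rf`.
#' @return A `forecast_set` data frame: state, origin, target, horizon,
#'   `yhat_log`, `se_log`, `y_obs_log`, `yhat_level`, `fallback` flag.
#' @export
one_step_forecasts <- function(rf, panel = NULL) {
  design <- if (is.null(panel)) rf$design else build_design(panel, rf$spec)
  out <- list()
  for (i in seq_along(rf$ends)) {
    origin <- rf$ends[i]
    fit <- rf$fits[[i]]
    rows <- which(design$year == origin + 1)
    if (!length(rows)) next
    d1 <- design
    for (f in c("y", "state", "year", "region", "post", "group")) {
      d1[[f]] <- design[[f]][rows]
    }
    d1$X <- design$X[rows, , drop = FALSE]
    d1$Z <- design$Z[rows, , drop = FALSE]
    pred <- predict(fit, d1)
    out[[length(out) + 1]] <- data.frame(
      state = d1$state,
      origin = origin,
      target = origin + 1,
      horizon = 1L,
      yhat_log = as.numeric(pred),
      se_log = fit$sigma,
      y_obs_log = d1$y,
      yhat_level = back_transform(as.numeric(pred), fit$sigma^2),
      fallback = attr(pred, "fallback"),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop_sc("no forecastable rows after the origins")
  res <- do.call(rbind, out)
  class(res) <- c("forecast_set", "data.frame")
  res
}

#' Multi-step-ahead forecasts from a single origin
#'
#' Uses the single fit at the origin to forecast horizons 1..h, conditioning
#' on the observed explanatory-variable paths (the reduced form treats the
#' regressors as exogenous; forecasting the unit-root regressors themselves
#' would produce extremely wide intervals). Targets whose explanatory rows
#' are unavailable are dropped with a flag.
#'
#' @param fit An [fe2sls()] fit whose sample ends at the origin.
#' @param design A full-sample design containing the later rows (e.g. the
#'   `design` element of [recursive_fit()]).
#' @param horizon Number of years ahead (>= 1).
#' @return A `forecast_set` data frame as in [one_step_forecasts()].
#' @export
multi_step_forecasts <- function(fit, design, horizon) {
  stopifnot(horizon >= 1)
  origin <- fit$design$sample_end
  out <- list()
  for (h in seq_len(horizon)) {
    rows <- which(design$year == origin + h)
    if (!length(rows)) next
    d1 <- design
    for (f in c("y", "state", "year", "region", "post", "group")) {
      d1[[f]] <- design[[f]][rows]
    }
    d1$X <- design$X[rows, , drop = FALSE]
    d1$Z <- design$Z[rows, , drop = FALSE]
    pred <- predict(fit, d1)
    out[[length(out) + 1]] <- data.frame(
      state = d1$state, origin = origin, target = origin + h, horizon = h,
      yhat_log = as.numeric(pred), se_log = fit$sigma, y_obs_log = d1$y,
      yhat_level = back_transform(as.numeric(pred), fit$sigma^2),
      fallback = attr(pred, "fallback"),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop_sc("no explanatory rows available beyond the origin")
  res <- do.call(rbind, out)
  class(res) <- c("forecast_set", "data.frame")
  res
}

#' Forecast-accuracy metrics
#'
#' RMSFE on the log scale, mean relative bias in percent on the level
#' scale (forecast minus observed over observed), and the correlation
#' between forecast and observed levels across state-target cells. The
#' correlation includes the cross-state variation carried by the state
#' intercepts, which inflates it; per-year summaries are also returned.
#'
#' @param fs A `forecast_set`.
#' @return A `forecast_metrics` list: `rmsfe`, `bias_pct`, `correlation`,
#'   `n`, and a per-year data frame.
#' @export
forecast_metrics <- function(fs) {
  fs <- fs[!is.na(fs$y_obs_log), , drop = FALSE]
  if (!nrow(fs)) stop_sc("no forecasts with observed values")
  err <- fs$yhat_log - fs$y_obs_log
  obs_level <- exp(fs$y_obs_log)
  rel <- (fs$yhat_level - obs_level) / obs_level
  corr <- if (stats::sd(fs$yhat_level) == 0 || stats::sd(obs_level) == 0) {
    if (all(abs(fs$yhat_level - obs_level) < 1e-12)) 1 else NA_real_
  } else {
    stats::cor(fs$yhat_level, obs_level)
  }
  per_year <- do.call(rbind, lapply(split(seq_len(nrow(fs)), fs$target),
                                    function(ix) {
    data.frame(target = fs$target[ix[1]],
               rmsfe = sqrt(mean(err[ix]^2)),
               bias_pct = 100 * mean(rel[ix]),
               n = length(ix))
  }))
  structure(
    list(rmsfe = sqrt(mean(err^2)),
         bias_pct = 100 * mean(rel),
         correlation = corr,
         n = nrow(fs),
         per_year = per_year),
    class = "forecast_metrics")
}

#' @export
print.forecast_metrics <- function(x, ...) {
  cat(sprintf("Forecast metrics over %d state-year cells:\n", x$n))
  cat(sprintf("  RMSFE (log scale)   %.4f\n", x$rmsfe))
  cat(sprintf("  mean relative bias  %.2f%%\n", x$bias_pct))
  cat(sprintf("  forecast-observed r %.3f\n", x$correlation))
  invisible(x)
}

#' Lognormal back-transformation
#'
#' Converts a normal log-scale mean forecast to the level scale:
#' `exp(yhat_log + var_log / 2)`.
#'
#' @param yhat_log Mean log forecast.
#' @param var_log Total log-scale forecast variance (>= 0).
#' @return Level forecast.
#' @export
back_transform <- function(yhat_log, var_log) {
  stopifnot(all(var_log >= 0))
  exp(yhat_log + var_log / 2)
}
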