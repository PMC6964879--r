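# MacKinnon (1994) approximate asymptotic p-value for the Dickey-Fuller
# tau distribution, constant-only case (the reference distribution of the
# Phillips-Perron Z-tau statistic).
mackinnon_p_tau_c <- function(stat) {
  if (is.na(stat)) return(NA_real_)
  if (stat > 2.74) return(1)
  if (stat < -18.83) return(0)
  if (stat <= -1.61) {
    p <- 2.1659 + 1.4412 * stat + 0.038269 * stat^2
  } else {
    p <- 1.7339 + 0.93202 * stat - 0.12745 * stat^2 - 0.010368 * stat^3
  }
  stats::pnorm(p)
}

# Phillips-Perron Z-tau for one series (constant, no trend), with a
# Newey-West (Bartlett) long-run variance at lag truncation q.
pp_z_tau <- function(y, q) {
  T1 <- length(y)
  yl <- y[-T1]
  yc <- y[-1]
  n <- length(yc)
  X <- cbind(1, yl)
  fit <- stats::lm.fit(X, yc)
  u <- fit$residuals
  rho <- fit$coefficients[2]
  XtXi <- solve(crossprod(X))
  s2 <- sum(u^2) / (n - 2)
  se_rho <- sqrt(s2 * XtXi[2, 2])
  t_rho <- (rho - 1) / se_rho
  gamma0 <- sum(u^2) / n
  lam2 <- gamma0
  if (q >= 1) {
    for (j in seq_len(min(q, n - 1))) {
      gj <- sum(u[(j + 1):n] * u[1:(n - j)]) / n
      lam2 <- lam2 + 2 * (1 - j / (q + 1)) * gj
    }
  }
  if (lam2 <= 0) lam2 <- gamma0
  z <- sqrt(gamma0 / lam2) * t_rho -
    (lam2 - gamma0) * n * se_rho / (2 * sqrt(lam2) * sqrt(s2))
  unname(z)
}

#' Panel unit-root test on regression residuals
#'
#' Applies a Phillips-Perron Z-tau test (constant, Newey-West long-run
#' variance) to each state's residual series and combines the per-state
#' p-values with Fisher's method, `-2 * sum(log p)` against a chi-square
#' with `2 * n_states` degrees of freedom. Stationary residuals (a rejected
#' unit-root null) indicate the estimated panel regression is
#' cointegrating. States with fewer than `min_obs` residuals or degenerate
#' (zero-variance) series are excluded and listed.
#'
#' @param residuals Either an [fe2sls()] fit or a named list of per-state
#'   residual series (each a numeric vector in time order).
#' @param lag_truncation Newey-West truncation; `NULL` uses the automatic
#'   rule `floor(4 * (T/100)^(2/9))`.
#' @param min_obs Minimum residual observations per state (default 8).
#' @param p_method Per-state p-values: `"simulated"` (default) calibrates
#'   against a simulated finite-sample random-walk null at the observed
#'   series length, keeping the Fisher combination sized correctly at the
#'   short panel T; `"asymptotic"` uses the MacKinnon approximate
#'   asymptotic tau p-values (liberal for T around 20).
#' @param null_reps,null_seed Size and fixed seed of the simulated null.
#' @return A `pp_panel_result` with per-state statistics and p-values, the
#'   Fisher combined statistic, its degrees of freedom and p-value, and the
#'   excluded states.
#' @export
pp_panel_unit_root <- function(residuals, lag_truncation = NULL, min_obs = 8L,
                               p_method = c("simulated", "asymptotic"),
                               null_reps = 2000L, null_seed = 20110101L) {
  p_method <- match.arg(p_method)
  if (inherits(residuals, "fe2sls")) {
    residuals <- split(unname(residuals$residuals), residuals$resid_state)
  }
  if (!length(residuals)) stop_sc("no residual series supplied")
  excluded <- character(0)
  stat <- pval <- numeric(0)
  used_q <- integer(0)
  null_tables <- list()   # simulated null distributions, one per (T, q)
  null_dist <- function(T1, q) {
    key <- paste(T1, q)
    if (is.null(null_tables[[key]])) {
      null_tables[[key]] <<- with_seed(null_seed, {
        vapply(seq_len(null_reps),
               function(i) pp_z_tau(cumsum(stats::rnorm(T1)), q), numeric(1))
      })
    }
    null_tables[[key]]
  }
  for (s in names(residuals)) {
    e <- residuals[[s]]
    e <- e[!is.na(e)]
    if (length(e) < min_obs) {
      excluded <- c(excluded, stats::setNames("too short", s))
      next
    }
    if (stats::sd(e) == 0) {
      excluded <- c(excluded, stats::setNames("zero variance", s))
      next
    }
    q <- lag_truncation %||% floor(4 * (length(e) / 100)^(2 / 9))
    z <- pp_z_tau(e, q)
    p <- if (p_method == "asymptotic") {
      mackinnon_p_tau_c(z)
    } else {
      # finite-sample p from the simulated random-walk null at this T
      nd <- null_dist(length(e), q)
      (sum(nd <= z) + 1) / (length(nd) + 1)
    }
    stat <- c(stat, stats::setNames(z, s))
    pval <- c(pval, stats::setNames(p, s))
    used_q <- c(used_q, stats::setNames(q, s))
  }
  if (!length(stat)) stop_sc("all residual series too short or degenerate")
  p_clip <- pmin(pmax(pval, 1e-16), 1)
  fisher <- -2 * sum(log(p_clip))
  df <- 2L * length(p_clip)
  combined_p <- stats::pchisq(fisher, df, lower.tail = FALSE)
  structure(
    list(statistic = stat, p_value = pval, lag_truncation = used_q,
         fisher = fisher, df = df, combined_p = combined_p,
         excluded = excluded),
    class = "pp_panel_result")
}

#' @export
print.pp_panel_result <- function(x, ...) {
  cat(sprintf("Phillips-Perron panel unit-root test (%d states, Fisher combination)\n",
              length(x$statistic)))
  cat(sprintf("  chi-square(%d) = %.2f, p = %.4g\n", x$df, x$fisher, x$combined_p))
  if (length(x$excluded)) {
    cat("  excluded:", paste(sprintf("%s (%s)", names(x$excluded), x$excluded),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Instrument-validity diagnostics
#'
#' Computes, on the within-transformed design: an underidentification LM
#' statistic (Anderson canonical-correlation test on the first stage), the
#' cluster-robust first-stage F on the excluded instruments with a weak-
#' instrument relative-bias category from the standard 2SLS tabulated
#' thresholds, and the Sargan overidentification statistic from the 2SLS
#' residual-instrument moment conditions (`J`, with
#' `#instruments - #endogenous` degrees of freedom; inapplicable for a
#' just-identified model).
#'
#' @param design A [build_design()] result.
#' @param fit Optional existing [fe2sls()] fit of this design.
#' @return An `iv_diagnostics` list.
#' @export
iv_diagnostics <- function(design, fit = NULL) {
  wt <- within_transform(design)
  keep <- setdiff(colnames(design$X), wt$absorbed)
  endo <- intersect(design$endogenous, keep)
  L <- ncol(design$Z)
  if (!length(endo) || L == 0) stop_sc("design has no instrumented regressors")
  if (L < length(endo)) stop_sc("underidentified: fewer instruments than endogenous regressors")
  if (is.null(fit)) fit <- fe2sls(design)

  exog <- setdiff(keep, endo)
  Xe <- wt$X[, exog, drop = FALSE]
  # partial out exogenous regressors
  resid_on <- function(M, A) {
    if (!ncol(A)) return(M)
    qa <- qr(A)
    M - A %*% qr.coef(qa, M)
  }
  Ez <- resid_on(wt$Z, Xe)
  Ee <- resid_on(wt$X[, endo, drop = FALSE], Xe)
  n <- nrow(Ez)

  # Anderson canonical-correlation LM: n * smallest squared canonical
  # correlation between endogenous block and excluded instruments
  cc2 <- tryCatch({
    Szz <- crossprod(Ez) / n
    See <- crossprod(Ee) / n
    Sze <- crossprod(Ez, Ee) / n
    M <- solve(See) %*% t(Sze) %*% solve(Szz) %*% Sze
    sort(Re(eigen(M, only.values = TRUE)$values))
  }, error = function(e) NA_real_)
  under_lm <- n * cc2[1]
  under_df <- L - length(endo) + 1L
  under_p <- stats::pchisq(under_lm, under_df, lower.tail = FALSE)

  fsF <- vapply(fit$first_stage %||% list(), function(f) f$F, numeric(1))
  Fmin <- if (length(fsF)) min(fsF) else NA_real_
  # Stock-Yogo 2SLS relative-bias thresholds (1 endogenous, 3 instruments)
  bias_cat <- if (is.na(Fmin)) NA_character_
  else if (Fmin >= 13.91) "<5%"
  else if (Fmin >= 9.08) "<10%"
  else if (Fmin >= 6.46) "<20%"
  else if (Fmin >= 5.39) "<30%"
  else ">=30%"

  j_df <- L - length(endo)
  if (j_df > 0) {
    u <- unname(fit$residuals)
    WZ <- cbind(Xe, wt$Z)
    qwz <- qr(WZ)
    uhat <- drop(WZ %*% qr.coef(qwz, u))
    J <- n * sum(uhat^2) / sum(u^2)
    j_p <- stats::pchisq(J, j_df, lower.tail = FALSE)
  } else {
    J <- NA_real_
    j_p <- NA_real_
  }

  structure(
    list(under_lm = under_lm, under_df = under_df, under_p = under_p,
         first_stage_F = fsF, weak_F_min = Fmin, bias_category = bias_cat,
         J = J, J_df = j_df, J_p = j_p,
         n_instruments = L, n_endogenous = length(endo)),
    class = "iv_diagnostics")
}

#' @export
print.iv_diagnostics <- function(x, ...) {
  cat("Instrument diagnostics\n")
  cat(sprintf("  underidentification LM = %.2f (chi2 df %d), p = %.4g\n",
              x$under_lm, x$under_df, x$under_p))
  cat(sprintf("  weak identification: min first-stage F = %.2f, relative bias %s\n",
              x$weak_F_min, x$bias_category))
  if (!is.na(x$J)) {
    cat(sprintf("  overidentification J = %.3f (chi2 df %d), p = %.4g\n",
                x$J, x$J_df, x$J_p))
  } else {
    cat("  overidentification: just-identified, J inapplicable\n")
  }
  invisible(x)
}

#' Per-state residual serial correlation
#'
#' Lag-1 sample autocorrelation of each state's residual series, with the
#' cross-state mean and range. In the cointegration reading, positive but
#' well-below-unit serial correlation is the stationary AR(1) adjustment
#' toward the long-run relation.
#'
#' @param fit An [fe2sls()] fit, or a named list of per-state residual
#'   series.
#' @param min_obs Minimum residuals per state (default 3).
#' @return List with `by_state`, `mean`, and `range`.
#' @export
residual_autocorrelation <- function(fit, min_obs = 3L) {
  series <- if (inherits(fit, "fe2sls")) {
    split(unname(fit$residuals), fit$resid_state)
  } else fit
  # fixed-effects residuals are mean zero within state by construction, so
  # the lag-1 autocorrelation is computed without re-demeaning (halving the
  # short-sample downward bias of the usual sample ACF)
  ac <- vapply(series, function(e) {
    e <- e[!is.na(e)]
    if (length(e) < min_obs || stats::sd(e) == 0) return(NA_real_)
    sum(e[-1] * e[-length(e)]) / sum(e^2)
  }, numeric(1))
  list(by_state = ac,
       mean = mean(ac, na.rm = TRUE),
       range = range(ac, na.rm = TRUE))
}
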