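#' Within (fixed-effects) transformation of a design
#'
#' Demeans the response, regressors and instruments by fixed-effect group.
#' Groups are states, or state-by-era cells when the spec bridges the
#' survey break with post-break intercept shifts. Columns that are constant
#' within every group are absorbed by the fixed effects; they are reported
#' and excluded from the slope vector rather than silently dropped.
#'
#' @param design A [build_design()] result.
#' @return List with demeaned `y`, `X`, `Z`, the group factor, group row
#'   counts, and the names of absorbed columns.
#' @export
within_transform <- function(design) {
  f <- factor(design$group)
  cnt <- as.vector(table(f))
  center <- function(M) {
    if (is.null(dim(M))) M <- matrix(M, ncol = 1)
    gm <- rowsum(M, f) / cnt
    M - gm[as.integer(f), , drop = FALSE]
  }
  yt <- drop(center(design$y))
  Xt <- center(design$X)
  Zt <- if (ncol(design$Z)) center(design$Z) else design$Z
  scale_ref <- pmax(apply(abs(design$X), 2, max), 1)
  absorbed <- colnames(design$X)[apply(abs(Xt), 2, max) < 1e-10 * scale_ref]
  list(y = yt, X = Xt, Z = Zt, group = f, counts = cnt, absorbed = absorbed)
}

#' Fit the fixed-effects 2SLS panel regression
#'
#' Estimates the log-log expenditure regression by fixed-effects two-stage
#' least squares: mismeasured regressors (by default log mean consumption)
#' are replaced in the second stage by their first-stage projection on the
#' excluded instruments (deeper lags of prevalence and consumption) plus
#' all exogenous regressors, everything within-transformed. Residuals and
#' the regression standard error use the original (not fitted) endogenous
#' columns, the standard 2SLS convention. The coefficient covariance is the
#' cluster-robust sandwich over states with a small-sample correction
#' `G/(G-1) * (N-1)/(N-K)`.
#'
#' With `method = "ols"` (or when the spec declares no endogenous
#' regressors / no instruments) the first stage is skipped and the fit is
#' the within OLS estimator; instrumenting a regressor with itself
#' reproduces OLS exactly.
#'
#' @param design A [build_design()] result.
#' @param method `"2sls"` (default) or `"ols"`.
#' @return An object of class `fe2sls`: coefficients (elasticities),
#'   cluster-robust `vcov`, per-group fixed effects, residuals indexed by
#'   state and year, `sigma` (regression RMSE), first-stage summaries, and
#'   the design/spec it was fitted to.
#' @export
fe2sls <- function(design, method = c("2sls", "ols")) {
  method <- match.arg(method)
  wt <- within_transform(design)
  keep <- setdiff(colnames(design$X), wt$absorbed)
  if (!length(keep)) stop_sc("all regressors absorbed by fixed effects")
  Xt <- wt$X[, keep, drop = FALSE]
  yt <- wt$y
  n <- length(yt)
  endo <- intersect(design$endogenous, keep)
  L <- ncol(design$Z)
  use_iv <- method == "2sls" && length(endo) > 0 && L > 0
  if (method == "2sls" && length(endo) > 0 && L < length(endo)) {
    stop_sc("order condition violated: %d instruments for %d endogenous regressors",
            L, length(endo))
  }

  cl <- factor(design$state)
  G <- nlevels(cl)
  if (G < 2) stop_sc("cluster-robust covariance needs at least 2 clusters (states)")

  first_stage <- NULL
  Xhat <- Xt
  if (use_iv) {
    exog <- setdiff(keep, endo)
    W <- cbind(Xt[, exog, drop = FALSE], wt$Z)
    qw <- qr(W)
    if (qw$rank < ncol(W)) {
      bad <- colnames(W)[qw$pivot[seq.int(qw$rank + 1, ncol(W))]]
      stop_sc("first-stage design is rank deficient (collinear: %s)",
              paste(bad, collapse = ", "))
    }
    first_stage <- list()
    for (e in endo) {
      fs_coef <- qr.coef(qw, Xt[, e])
      fit_e <- drop(W %*% fs_coef)
      v <- Xt[, e] - fit_e
      # cluster-robust Wald F on the excluded-instrument block
      Vfs <- sandwich_vcov(W, v, cl, small = TRUE)
      zi <- seq.int(ncol(W) - ncol(wt$Z) + 1, ncol(W))
      dz <- fs_coef[zi]
      Fz <- tryCatch(
        drop(t(dz) %*% solve(Vfs[zi, zi, drop = FALSE], dz)) / length(zi),
        error = function(err) NA_real_)
      first_stage[[e]] <- list(coef = fs_coef, F = Fz,
                               instruments = colnames(wt$Z))
      Xhat[, e] <- fit_e
    }
  }

  qx <- qr(Xhat)
  if (qx$rank < ncol(Xhat)) {
    bad <- colnames(Xhat)[qx$pivot[seq.int(qx$rank + 1, ncol(Xhat))]]
    stop_sc("design is rank deficient (collinear: %s)", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, yt)
  u <- yt - drop(Xt %*% beta)          # original endogenous columns
  K <- length(beta)
  n_fe <- nlevels(wt$group)
  dof <- n - K - n_fe
  sigma <- sqrt(sum(u^2) / max(dof, 1))

  V <- sandwich_vcov(Xhat, u, cl, small = TRUE)
  rownames(V) <- colnames(V) <- names(beta)

  # per-group intercepts recovered from group means
  gm_y <- rowsum(design$y, wt$group) / wt$counts
  gm_x <- rowsum(design$X[, keep, drop = FALSE], wt$group) / wt$counts
  fe <- drop(gm_y) - drop(gm_x %*% beta)

  se <- sqrt(pmax(diag(V), 0))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))

  structure(
    list(coefficients = beta, vcov = V, se = se, p_value = pval,
         fixed_effects = fe,
         residuals = stats::setNames(u, paste(design$state, design$year)),
         resid_state = design$state, resid_year = design$year,
         sigma = sigma, nobs = n, n_clusters = G, dof = dof,
         n_fixed_effects = n_fe, absorbed = wt$absorbed,
         first_stage = first_stage, method = if (use_iv) "2sls" else "ols",
         design = design, spec = design$spec),
    class = "fe2sls")
}

# Cluster-robust sandwich: bread solve(X'X), meat sum over clusters of
# score outer products, with the G/(G-1)*(N-1)/(N-K) small-sample factor.
sandwich_vcov <- function(X, u, cl, small = TRUE) {
  XtXi <- solve(crossprod(X))
  S <- rowsum(X * u, cl)
  meat <- crossprod(S)
  G <- nlevels(cl)
  n <- nrow(X)
  k <- ncol(X)
  corr <- if (small) (G / (G - 1)) * ((n - 1) / max(n - k, 1)) else 1
  V <- corr * XtXi %*% meat %*% XtXi
  (V + t(V)) / 2
}

#' Cluster-robust covariance of a fitted model
#'
#' Recomputes the sandwich covariance of the slope coefficients from a
#' fitted [fe2sls()] model: bread from the within-transformed instrumented
#' design, meat from per-state score sums using the residuals computed with
#' the original endogenous columns.
#'
#' @param fit A [fe2sls()] fit.
#' @param design Design to evaluate on; defaults to the fit's own.
#' @param small Apply the `G/(G-1) * (N-1)/(N-K)` correction (default TRUE).
#' @return Covariance matrix over the slope coefficients.
#' @export
cluster_robust_vcov <- function(fit, design = fit$design, small = TRUE) {
  wt <- within_transform(design)
  keep <- names(stats::coef(fit))
  Xt <- wt$X[, keep, drop = FALSE]
  Xhat <- Xt
  for (e in names(fit$first_stage %||% list())) {
    W <- cbind(Xt[, setdiff(keep, names(fit$first_stage)), drop = FALSE], wt$Z)
    Xhat[, e] <- drop(W %*% fit$first_stage[[e]]$coef)
  }
  u <- wt$y - drop(Xt %*% stats::coef(fit))
  V <- sandwich_vcov(Xhat, u, factor(design$state), small = small)
  rownames(V) <- colnames(V) <- keep
  V
}

#' Normal-theory confidence interval
#'
#' `estimate +/- z * se` with the standard normal quantile (1.959964 at the
#' 95% level); the published intervals for the smoking elasticities
#' reproduce with this convention.
#'
#' @param estimate Point estimate(s).
#' @param se Standard error(s), `>= 0`.
#' @param level Coverage in (0, 1); default 0.95.
#' @return Matrix with columns `low`, `high`.
#' @export
ci_normal <- function(estimate, se, level = 0.95) {
  stopifnot(all(se >= 0), level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  cbind(low = estimate - z * se, high = estimate + z * se)
}

#' @export
coef.fe2sls <- function(object, ...) object$coefficients

#' @export
vcov.fe2sls <- function(object, ...) object$vcov

#' @export
residuals.fe2sls <- function(object, ...) object$residuals

#' @export
nobs.fe2sls <- function(object, ...) object$nobs

#' @export
confint.fe2sls <- function(object, parm, level = 0.95, ...) {
  ci <- ci_normal(object$coefficients, object$se, level)
  rownames(ci) <- names(object$coefficients)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predict log expenditure for design rows
#'
#' Adds the appropriate fixed effect (the post-break intercept for
#' post-break rows under intercept bridging) to the linear score. Rows
#' whose fixed-effect group was not estimable in the fitting sample (e.g.
#' post-break rows forecast from a pre-break sample) fall back to the
#' state's pre-break intercept and are flagged.
#'
#' @param object A [fe2sls()] fit.
#' @param design Design providing the rows to predict; defaults to the
#'   fit's own design.
#' @param ... Unused.
#' @return Numeric vector of predicted log expenditure with attribute
#'   `fallback` marking rows predicted with a pre-break intercept.
#' @export
predict.fe2sls <- function(object, design = object$design, ...) {
  keep <- names(stats::coef(object))
  xb <- drop(design$X[, keep, drop = FALSE] %*% stats::coef(object))
  fe <- object$fixed_effects
  g <- design$group
  fallback <- !(g %in% names(fe))
  g_eff <- g
  if (any(fallback)) {
    g_eff[fallback] <- sub(":post$", ":pre", g[fallback])
    still <- !(g_eff %in% names(fe))
    if (any(still)) stop_sc("no fixed effect available for group(s): %s",
                            paste(unique(g[still]), collapse = ", "))
  }
  out <- fe[g_eff] + xb
  attr(out, "fallback") <- fallback
  unname_keep_attr(out)
}

unname_keep_attr <- function(x) {
  a <- attributes(x)
  x <- unname(x)
  attr(x, "fallback") <- a$fallback
  x
}

#' @export
print.fe2sls <- function(x, ...) {
  cat(sprintf("Fixed-effects %s panel regression (log-log)\n",
              toupper(x$method)))
  cat(sprintf("  %d obs, %d states (clusters), %d fixed effects, sigma = %.4g\n",
              x$nobs, x$n_clusters, x$n_fixed_effects, x$sigma))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.fe2sls <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  tab <- data.frame(
    estimate = object$coefficients,
    cluster_se = object$se,
    p_value = object$p_value,
    low = ci[, "low"], high = ci[, "high"])
  out <- list(table = tab, sigma = object$sigma, nobs = object$nobs,
              n_clusters = object$n_clusters, method = object$method,
              absorbed = object$absorbed,
              first_stage_F = vapply(object$first_stage %||% list(),
                                     function(f) f$F, numeric(1)),
              r2 = tryCatch(panel_r2(object), error = function(e) NULL))
  class(out) <- "summary.fe2sls"
  out
}

#' @export
print.summary.fe2sls <- function(x, ...) {
  cat(sprintf("Fixed-effects %s regression: %d obs, %d clusters\n",
              toupper(x$method), x$nobs, x$n_clusters))
  printCoefmat(as.matrix(x$table[, c("estimate", "cluster_se", "p_value")]),
               P.values = TRUE, has.Pvalue = TRUE)
  if (length(x$first_stage_F)) {
    cat("First-stage F (excluded instruments):",
        paste(sprintf("%s = %.1f", names(x$first_stage_F), x$first_stage_F),
              collapse = ", "), "\n")
  }
  if (length(x$absorbed)) {
    cat("Absorbed by fixed effects:", paste(x$absorbed, collapse = ", "), "\n")
  }
  if (!is.null(x$r2)) {
    cat(sprintf("R2 within %.3f between %.3f total %.3f | rho %.3f corr(u,Xb) %.3f RMSE %.4f\n",
                x$r2$within, x$r2$between, x$r2$total, x$r2$rho,
                x$r2$corr_u_xb, x$r2$rmse))
  }
  invisible(x)
}

#' Panel R-squared and error-structure statistics
#'
#' Within R-squared (on state-demeaned data), between (on state means),
#' and total R-squared, all as squared correlations between the linear
#' score and the response at the relevant aggregation; `rho`, the share of
#' the error variance due to the state constants
#' `sigma_alpha^2 / (sigma_alpha^2 + sigma_eps^2)`; and the correlation
#' between the state intercepts and the state-mean linear score.
#'
#' @param fit A [fe2sls()] fit.
#' @param design Design to evaluate on; defaults to the fit's own.
#' @return List with `within`, `between`, `total`, `rho`, `corr_u_xb`,
#'   `rmse`.
#' @export
panel_r2 <- function(fit, design = fit$design) {
  keep <- names(stats::coef(fit))
  xb <- drop(design$X[, keep, drop = FALSE] %*% stats::coef(fit))
  y <- design$y
  st <- factor(design$state)
  safe_cor2 <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)^2
  }
  # within: demeaned by the fixed-effect grouping actually absorbed
  fg <- factor(design$group)
  cntg <- as.vector(table(fg))
  dm <- function(v) v - (rowsum(v, fg) / cntg)[as.integer(fg)]
  within <- safe_cor2(dm(xb), dm(y))
  mb <- function(v) drop(rowsum(v, st) / as.vector(table(st)))
  between <- safe_cor2(mb(xb), mb(y))
  total <- safe_cor2(xb, y)
  sig_a <- stats::sd(fit$fixed_effects)
  rho <- if (is.na(sig_a)) NA_real_ else sig_a^2 / (sig_a^2 + fit$sigma^2)
  # intercepts vs state-mean score, on the fit's own design
  f0 <- factor(fit$design$group)
  xb0 <- drop(fit$design$X[, keep, drop = FALSE] %*% stats::coef(fit))
  gm_xb <- drop(rowsum(xb0, f0) / as.vector(table(f0)))
  fe0 <- fit$fixed_effects[levels(f0)]
  corr_u_xb <- if (stats::sd(fe0) == 0 || stats::sd(gm_xb) == 0) NA_real_ else
    stats::cor(fe0, gm_xb)
  list(within = within, between = between, total = total,
       rho = rho, corr_u_xb = corr_u_xb, rmse = fit$sigma)
}
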