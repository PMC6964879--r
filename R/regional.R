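#' Regional heterogeneity of the smoking elasticities
#'
#' Interacts the named regressors (by default smoking prevalence and mean
#' consumption) with BEA-region indicators, tests the null of homogeneous
#' elasticities across regions with an F statistic from the restricted
#' (pooled) and unrestricted (region-specific) sums of squared residuals,
#' and sequentially merges regions whose elasticities are statistically
#' indistinguishable.
#'
#' All candidate models are evaluated on the same instrumented column
#' space: the endogenous columns are projected on one shared first-stage
#' regressor set (exogenous columns with the varying ones region-interacted,
#' plus region-interacted excluded instruments). A pooled column is the sum
#' of its region-interacted columns, so every grouping is a linear
#' restriction of the fully regional model and `SSR_regional <= SSR_pooled`
#' holds by construction.
#'
#' @param design A [build_design()] result.
#' @param vary Variable short names whose elasticities may differ by
#'   region; default `c("prev", "cons")`.
#' @param alpha Level for the sequential merge tests (default 0.05).
#' @param min_region_obs Minimum rows per region (default 8).
#' @return A `heterogeneity_result`: per-region elasticities for the
#'   varying regressors, the homogeneity F statistic with its p-value, and
#'   the sequential grouping of regions.
#' @export
fit_regional <- function(design, vary = c("prev", "cons"), alpha = 0.05,
                         min_region_obs = 8L) {
  spec <- design$spec
  vcols <- sprintf("ln_%s_l%d", vary, spec$lag)
  missing_cols <- setdiff(vcols, colnames(design$X))
  if (length(missing_cols)) {
    stop_sc("varying regressor(s) not in design: %s",
            paste(missing_cols, collapse = ", "))
  }
  tab <- table(design$region)
  small <- names(tab)[tab < min_region_obs]
  if (length(small)) {
    stop_sc("region(s) with too few observations: %s",
            paste(small, collapse = ", "))
  }
  regions <- bea_regions()[bea_regions() %in% unique(design$region)]

  wt <- within_transform(design)
  keep <- setdiff(colnames(design$X), wt$absorbed)
  Xt <- wt$X[, keep, drop = FALSE]
  yt <- wt$y
  n <- length(yt)
  other <- setdiff(keep, vcols)                     # columns never interacted
  endo_all <- intersect(design$endogenous, keep)    # endogenous column names
  endo_vary <- intersect(endo_all, vcols)
  endo_fixed <- setdiff(endo_all, vcols)

  interact <- function(col, base) {
    m <- sapply(regions, function(r) ifelse(design$region == r, col, 0))
    colnames(m) <- paste0(base, ":", regions)
    m
  }
  Xi <- lapply(vcols, function(v) interact(Xt[, v], v))
  names(Xi) <- vcols

  # shared first-stage regressor set
  use_iv <- length(endo_all) > 0 && ncol(wt$Z) > 0
  if (use_iv) {
    Zi <- do.call(cbind, lapply(colnames(wt$Z), function(z)
      interact(wt$Z[, z], z)))
    exog_vary <- setdiff(vcols, endo_vary)
    W <- cbind(Xt[, setdiff(other, endo_fixed), drop = FALSE],
               if (length(exog_vary)) do.call(cbind, Xi[exog_vary]),
               Zi)
    qw <- qr(W)
    project <- function(M) {
      apply(M, 2, function(col) drop(W %*% qr.coef(qw, col)))
    }
  } else {
    project <- identity
  }

  build_design_cols <- function(groups) {
    # groups partitions `regions`; returns list(X, endo_flags)
    parts <- list()
    flags <- logical(0)
    for (v in vcols) {
      m <- sapply(groups, function(g) rowSums(Xi[[v]][, paste0(v, ":", g),
                                                      drop = FALSE]))
      if (is.null(dim(m))) m <- matrix(m, ncol = length(groups))
      colnames(m) <- paste0(v, ":", vapply(groups, paste, "", collapse = "+"))
      parts[[v]] <- m
      flags <- c(flags, rep(v %in% endo_vary, ncol(m)))
    }
    Xd <- cbind(Xt[, other, drop = FALSE], do.call(cbind, parts))
    endo_flag <- c(colnames(Xt[, other, drop = FALSE]) %in% endo_fixed, flags)
    list(X = Xd, endo = endo_flag)
  }

  fit_ssr <- function(groups) {
    d <- build_design_cols(groups)
    Xp <- d$X
    if (use_iv && any(d$endo)) {
      Xp[, d$endo] <- project(d$X[, d$endo, drop = FALSE])
    }
    qx <- qr(Xp)
    b <- qr.coef(qx, yt)
    res <- yt - drop(Xp %*% b)   # SSR in the projected space (nested F)
    list(beta = b, ssr = sum(res^2), k = ncol(Xp))
  }

  singletons <- as.list(regions)
  unres <- fit_ssr(singletons)
  pooled <- fit_ssr(list(regions))

  dof_res <- n - unres$k - nlevels(wt$group)
  q <- unres$k - pooled$k
  Fstat <- ((pooled$ssr - unres$ssr) / q) / (unres$ssr / dof_res)
  pval <- stats::pf(Fstat, q, dof_res, lower.tail = FALSE)

  per_region <- do.call(rbind, lapply(regions, function(r) {
    stats::setNames(unres$beta[paste0(vcols, ":", r)], vary)
  }))
  rownames(per_region) <- regions

  # sequential merging: join the pair with the largest merge p-value,
  # re-testing at `alpha` after each merge
  groups <- singletons
  current <- unres
  repeat {
    if (length(groups) == 1) break
    best <- NULL
    for (i in seq_along(groups)) {
      for (j in seq_len(i - 1)) {
        cand <- groups
        cand[[j]] <- c(cand[[j]], cand[[i]])
        cand[[i]] <- NULL
        f <- fit_ssr(cand)
        qm <- current$k - f$k
        dfm <- n - current$k - nlevels(wt$group)
        Fm <- ((f$ssr - current$ssr) / qm) / (current$ssr / dfm)
        pm <- stats::pf(Fm, qm, dfm, lower.tail = FALSE)
        if (is.null(best) || pm > best$p) best <- list(p = pm, groups = cand)
      }
    }
    if (best$p > alpha) {
      groups <- best$groups
      current <- fit_ssr(groups)
    } else break
  }

  structure(
    list(per_region = per_region, F = Fstat, df = c(q, dof_res),
         p_value = pval, groups = groups,
         ssr_pooled = pooled$ssr, ssr_regional = unres$ssr),
    class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat("Regional elasticities:\n")
  print(round(x$per_region, 4))
  cat(sprintf("Homogeneity F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p_value))
  cat("Sequential grouping:",
      paste(vapply(x$groups, paste, "", collapse = "+"), collapse = " | "), "\n")
  invisible(x)
}
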