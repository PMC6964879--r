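#' Enumerate all cross-sectional-average specifications
#'
#' One [model_spec()] per subset of the candidate averages (including the
#' empty set), all other fields copied from `base`, in binary-counter
#' order; 7 candidates give the full 2^7 = 128 candidate specifications.
#'
#' @param candidates Distinct average names (subset of
#'   [cs_average_candidates()]).
#' @param base A [model_spec()] supplying every other field.
#' @return List of [model_spec()] objects, length `2^length(candidates)`.
#' @export
enumerate_cs_specs <- function(candidates = cs_average_candidates(),
                               base = model_spec()) {
  if (anyDuplicated(candidates)) stop_sc("duplicate candidate names")
  k <- length(candidates)
  lapply(seq_len(2^k) - 1L, function(m) {
    sel <- candidates[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0]
    s <- base
    s$cs_averages <- sel
    s
  })
}

#' Evaluate candidate specifications by one-step forecast loss
#'
#' Runs recursive estimation and one-step-ahead forecasting for each
#' candidate over a common evaluation window and records squared log
#' forecast errors per (state, target-year) cell. All candidates are scored
#' on the identical cell set: cells any candidate cannot forecast are
#' dropped for all (fairness invariant). Candidates whose estimation fails
#' are excluded with a warning.
#'
#' @param panel A [state_panel()].
#' @param specs List of [model_spec()] candidates.
#' @param base_end Last response year of the base estimation window
#'   (origins run from here).
#' @param eval_start,eval_end Target-year evaluation window.
#' @param ids Optional candidate labels.
#' @return A `loss_table`: squared-error matrix (cells x candidates), cell
#'   index, per-candidate mean loss and RMSFE, the spec list, and failures.
#' @export
evaluate_specs <- function(panel, specs, base_end, eval_start, eval_end,
                           ids = NULL) {
  if (is.null(ids)) ids <- vapply(specs, spec_id, "")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  per_spec <- vector("list", length(specs))
  failed <- character(0)
  for (i in seq_along(specs)) {
    fs <- tryCatch({
      rf <- recursive_fit(panel, specs[[i]], base_end = base_end,
                          final_end = eval_end - 1)
      f <- one_step_forecasts(rf)
      f[f$target >= eval_start & f$target <= eval_end, , drop = FALSE]
    }, error = function(e) e)
    if (inherits(fs, "error")) {
      warning(sprintf("candidate '%s' failed estimation and is excluded: %s",
                      ids[i], conditionMessage(fs)), call. = FALSE)
      failed <- c(failed, ids[i])
      per_spec[i] <- list(NULL)
    } else {
      per_spec[[i]] <- fs
    }
  }
  ok <- !vapply(per_spec, is.null, logical(1))
  if (!any(ok)) stop_sc("every candidate specification failed")
  cells <- NULL
  for (fs in per_spec[ok]) {
    k <- paste(fs$state, fs$target)
    cells <- if (is.null(cells)) k else intersect(cells, k)
  }
  if (!length(cells)) stop_sc("no common evaluation cells across candidates")
  L <- sapply(per_spec[ok], function(fs) {
    k <- paste(fs$state, fs$target)
    e <- (fs$yhat_log - fs$y_obs_log)[match(cells, k)]
    e^2
  })
  colnames(L) <- ids[ok]
  cell_df <- data.frame(
    state = sub(" .*", "", cells),
    target = as.integer(sub(".* ", "", cells)),
    stringsAsFactors = FALSE)
  structure(
    list(losses = L, cells = cell_df,
         mean_loss = colMeans(L), rmsfe = sqrt(colMeans(L)),
         specs = stats::setNames(specs[ok], ids[ok]),
         failed = failed),
    class = "loss_table")
}

#' Model Confidence Set
#'
#' Iterative elimination over candidate forecast models: at each step the
#' null of equal predictive ability over the surviving set is tested with
#' the range (max-t) statistic on mean loss differentials; the null
#' distribution comes from a moving-block bootstrap that resamples whole
#' target-years (preserving the cross-state error correlation within a
#' year). While the null is rejected, the candidate with the largest
#' standardized mean excess loss is eliminated; each candidate's MCS
#' p-value is the running maximum of the elimination p-values, so the
#' survivor sets are nested and monotone in the level. Exact ties are
#' indistinguishable and survive together.
#'
#' @param losses A [evaluate_specs()] loss table.
#' @param alpha Level of the set (default 0.05).
#' @param reps Bootstrap replications (default 5000, >= 100).
#' @param block Moving-block length in years (default 2).
#' @param seed Seed for the bootstrap.
#' @return An `mcs_result`: MCS p-value per candidate, elimination order,
#'   survivors at `alpha`, and the bootstrap settings.
#' @export
model_confidence_set <- function(losses, alpha = 0.05, reps = 5000,
                                 block = 2, seed = NULL) {
  stopifnot(inherits(losses, "loss_table"))
  if (reps < 100) stop_sc("use at least 100 bootstrap replications")
  ids <- colnames(losses$losses)
  m <- length(ids)
  if (m < 1) stop_sc("empty loss table")

  # per-year mean losses (years are the bootstrap resampling unit)
  yr <- losses$cells$target
  yrs <- sort(unique(yr))
  M <- do.call(rbind, lapply(yrs, function(t) {
    colMeans(losses$losses[yr == t, , drop = FALSE])
  }))
  Tn <- length(yrs)
  b <- max(1L, min(as.integer(block), Tn))

  boot_idx <- with_seed(seed, {
    nb <- ceiling(Tn / b)
    starts <- matrix(sample.int(Tn - b + 1L, reps * nb, replace = TRUE),
                     reps, nb)
    idx <- matrix(0L, reps, nb * b)
    for (j in seq_len(b)) idx[, seq(j, nb * b, by = b)] <- starts + (j - 1L)
    # interleave properly: rebuild as consecutive blocks
    idx <- t(apply(starts, 1, function(s) {
      as.vector(vapply(s, function(st) st + 0:(b - 1L), integer(b)))
    }))
    idx[, seq_len(Tn), drop = FALSE]
  })

  pvals <- stats::setNames(rep(NA_real_, m), ids)
  elim_order <- character(0)
  elim_p <- numeric(0)
  S <- ids
  running <- 0
  while (length(S) > 1) {
    Ms <- M[, S, drop = FALSE]
    Lbar <- colMeans(Ms)
    d <- Lbar - mean(Lbar)
    # bootstrap distribution of the centered differentials
    Bd <- matrix(0, reps, length(S))
    for (r in seq_len(reps)) {
      Lb <- colMeans(Ms[boot_idx[r, ], , drop = FALSE])
      Bd[r, ] <- (Lb - mean(Lb)) - d
    }
    v <- colMeans(Bd^2)
    zero <- v <= .Machine$double.eps
    if (all(zero)) {    # exact ties: indistinguishable, all survive
      p <- 1
      for (s in S) pvals[s] <- max(running, 1)
      break
    }
    tstat <- ifelse(zero, 0, d / sqrt(v))
    Tobs <- max(tstat)
    Tboot <- apply(sweep(Bd, 2, sqrt(pmax(v, .Machine$double.eps)), "/"), 1, max)
    p <- mean(Tboot >= Tobs)
    running <- max(running, p)
    worst <- S[which.max(tstat)]
    pvals[worst] <- running
    elim_order <- c(elim_order, worst)
    elim_p <- c(elim_p, p)
    S <- setdiff(S, worst)
  }
  if (length(S) >= 1 && any(is.na(pvals[S]))) pvals[S[is.na(pvals[S])]] <- 1
  survivors <- ids[pvals > alpha]
  structure(
    list(p_values = pvals, survivors = survivors,
         elimination = data.frame(id = elim_order, p = elim_p,
                                  stringsAsFactors = FALSE),
         alpha = alpha, reps = reps, block = b, seed = seed),
    class = "mcs_result")
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(sprintf("Model Confidence Set at %g%%: %d of %d survive\n",
              100 * x$alpha, length(x$survivors), length(x$p_values)))
  print(round(sort(x$p_values, decreasing = TRUE), 3))
  invisible(x)
}

#' Select the final specification from the MCS survivors
#'
#' The survivor with the smallest mean one-step loss; ties are broken
#' toward the specification with fewer cross-sectional averages.
#'
#' @param mcs An [model_confidence_set()] result.
#' @param losses The matching [evaluate_specs()] loss table.
#' @return The chosen [model_spec()], with attribute `id`.
#' @export
select_best <- function(mcs, losses) {
  surv <- mcs$survivors
  if (!length(surv)) stop_sc("no surviving candidates")
  ml <- losses$mean_loss[surv]
  best <- surv[ml <= min(ml) + 1e-15]
  if (length(best) > 1) {
    sizes <- vapply(losses$specs[best], function(s) length(s$cs_averages),
                    integer(1))
    best <- best[order(sizes)][1]
  } else {
    best <- best[1]
  }
  out <- losses$specs[[best]]
  attr(out, "id") <- best
  out
}

#' Choose the survey-break bridging mode by post-break forecast loss
#'
#' Estimates the model recursively under each candidate bridge mode and
#' compares one-step-ahead RMSFE over the post-break evaluation window;
#' the minimal-RMSFE mode wins. A condition number of the within-
#' transformed regressor matrix is reported per mode, flagging the
#' near-collinearity that arises when post-break intercepts and slope
#' shifts are combined with the cross-sectional averages.
#'
#' @param panel A [state_panel()].
#' @param spec Base [model_spec()] (its averages, instruments etc. are
#'   kept; only `bridge_mode` varies).
#' @param modes Candidate modes, a subset of
#'   `c("none", "intercept_shift", "slope_shift", "both")`.
#' @param eval_start,eval_end Post-break target-year window
#'   (`spec$break_year <= eval_start`).
#' @param collinearity_threshold Condition number above which a mode is
#'   flagged (default 1e4).
#' @return A `bridge_selection`: best mode, per-mode RMSFE, per-mode
#'   forecast sets, condition numbers, and any failures.
#' @export
select_bridge <- function(panel, spec,
                          modes = c("intercept_shift", "slope_shift", "both"),
                          eval_start, eval_end,
                          collinearity_threshold = 1e4) {
  stopifnot(eval_start <= eval_end)
  if (spec$break_year > eval_start) {
    stop_sc("evaluation window must start at or after the break year")
  }
  rmsfe <- stats::setNames(rep(NA_real_, length(modes)), modes)
  fsets <- list()
  kappas <- stats::setNames(rep(NA_real_, length(modes)), modes)
  flagged <- character(0)
  for (mode in modes) {
    sm <- spec
    sm$bridge_mode <- mode
    res <- tryCatch({
      rf <- recursive_fit(panel, sm, base_end = eval_start - 1,
                          final_end = eval_end - 1)
      wt <- within_transform(rf$design)
      keep <- setdiff(colnames(rf$design$X), wt$absorbed)
      kp <- kappa(wt$X[, keep, drop = FALSE], exact = FALSE)
      f <- one_step_forecasts(rf)
      f <- f[f$target >= eval_start & f$target <= eval_end, , drop = FALSE]
      list(f = f, kappa = kp)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("bridge mode '%s' failed and is excluded: %s",
                      mode, conditionMessage(res)), call. = FALSE)
      next
    }
    kappas[mode] <- res$kappa
    if (is.finite(res$kappa) && res$kappa > collinearity_threshold) {
      flagged <- c(flagged, mode)
    }
    fsets[[mode]] <- res$f
    rmsfe[mode] <- sqrt(mean((res$f$yhat_log - res$f$y_obs_log)^2))
  }
  if (all(is.na(rmsfe))) stop_sc("every bridge mode failed estimation")
  best <- names(which.min(rmsfe))
  structure(
    list(best = best, rmsfe = rmsfe, forecasts = fsets,
         condition_numbers = kappas, collinear = flagged,
         eval_window = c(eval_start, eval_end)),
    class = "bridge_selection")
}

#' @export
print.bridge_selection <- function(x, ...) {
  cat("Bridge-mode selection over", x$eval_window[1], "-", x$eval_window[2], "\n")
  print(round(x$rmsfe, 5))
  cat("best:", x$best, "\n")
  if (length(x$collinear)) {
    cat("collinearity flagged for:", paste(x$collinear, collapse = ", "), "\n")
  }
  invisible(x)
}
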