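#' Configuration for a full pipeline run
#'
#' Collects the workflow settings of the three-phase analysis: a base
#' estimation window, a specification-selection forecast window (pre
#' break), a break-bridging window (post break), then the final fit,
#' diagnostics and counterfactual scenarios. The panel is either read from
#' CSV or simulated.
#'
#' @param panel_path CSV path of the input panel; `NULL` to simulate.
#' @param synth A [synth_config()] used when simulating.
#' @param spec Base [model_spec()].
#' @param base_end Last year of the base estimation window (default 2006).
#' @param select_window Target years for specification selection (default
#'   2007-2010).
#' @param bridge_window Target years for bridge-mode selection (default
#'   2011-2014; must not overlap the selection window).
#' @param search_candidates Cross-sectional average candidates to
#'   enumerate (default all seven). `NULL` skips the search.
#' @param mcs_alpha,mcs_reps,mcs_block Model Confidence Set settings.
#' @param scenario A [scenario_spec()]; `NULL` skips scenarios.
#' @param baseline_expenditure Per-capita baseline dollars for scenarios;
#'   `NULL` uses the final panel year's national mean.
#' @param seed Global seed; stage seeds derive from it.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(panel_path = NULL, synth = synth_config(),
                       spec = model_spec(),
                       base_end = 2006L,
                       select_window = c(2007L, 2010L),
                       bridge_window = c(2011L, 2014L),
                       search_candidates = cs_average_candidates(),
                       mcs_alpha = 0.05, mcs_reps = 2000L, mcs_block = 2L,
                       scenario = scenario_spec(),
                       baseline_expenditure = NULL,
                       seed = 1L, out_dir = "smokecast-run") {
  if (select_window[1] > select_window[2] ||
      bridge_window[1] > bridge_window[2]) {
    stop_sc("windows must be ordered (start <= end)")
  }
  if (select_window[2] >= bridge_window[1]) {
    stop_sc("selection window must precede the bridging window (they are kept disjoint)")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the three-phase forecasting pipeline
#'
#' simulate (optional) -> specification search over cross-sectional
#' averages with MCS selection -> break-bridging mode selection -> final
#' recursive fit -> diagnostics -> out-of-sample forecast evaluation ->
#' Monte-Carlo counterfactual scenarios. Each stage writes an artifact
#' under `cfg$out_dir`, plus a manifest recording the seed and a config
#' hash so every numeric artifact is reproducible from the manifest.
#'
#' @param cfg A [run_config()].
#' @param verbose Narrate the stages (default TRUE).
#' @return Invisible list of all stage results.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  artifacts <- character(0)
  emit_json <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    artifacts <<- c(artifacts, p)
    p
  }
  emit_csv <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    artifacts <<- c(artifacts, p)
    p
  }
  stage <- "load"
  res <- list()
  tryCatch({
    if (is.null(cfg$panel_path)) {
      stage <- "simulate"
      say("[simulate] generating synthetic panel (seed %s)", cfg$seed)
      sc <- cfg$synth
      sc$seed <- sc$seed %||% child_seed(cfg$seed, 1L)
      gen <- generate_panel(sc)
      panel <- gen$measured
      write_state_panel(panel, file.path(cfg$out_dir, "panel.csv"))
      artifacts <- c(artifacts, file.path(cfg$out_dir, "panel.csv"))
      emit_json(gen$report, "generation_report.json")
      res$generation <- gen$report
    } else {
      say("[load] reading panel from %s", cfg$panel_path)
      panel <- read_state_panel(cfg$panel_path)
    }
    res$panel <- panel

    spec <- cfg$spec
    if (!is.null(cfg$search_candidates)) {
      stage <- "search"
      say("[search] %d candidate average sets, selection window %d-%d (estimation from base %d)",
          2^length(cfg$search_candidates), cfg$select_window[1],
          cfg$select_window[2], cfg$base_end)
      base_nobridge <- spec
      base_nobridge$bridge_mode <- "none"
      cands <- enumerate_cs_specs(cfg$search_candidates, base_nobridge)
      lt <- evaluate_specs(panel, cands, base_end = cfg$base_end,
                           eval_start = cfg$select_window[1],
                           eval_end = cfg$select_window[2])
      mcs <- model_confidence_set(lt, alpha = cfg$mcs_alpha,
                                  reps = cfg$mcs_reps, block = cfg$mcs_block,
                                  seed = child_seed(cfg$seed, 2L))
      chosen <- select_best(mcs, lt)
      say("[search] best averages: {%s}; %d survivors at %g%%",
          paste(chosen$cs_averages, collapse = ", "),
          length(mcs$survivors), 100 * cfg$mcs_alpha)
      emit_csv(data.frame(id = names(lt$mean_loss), rmsfe = lt$rmsfe,
                          mcs_p = mcs$p_values[names(lt$mean_loss)],
                          survivor = names(lt$mean_loss) %in% mcs$survivors),
               "search_report.csv")
      spec$cs_averages <- chosen$cs_averages
      res$search <- list(losses = lt, mcs = mcs, chosen = chosen)
    }

    stage <- "bridge"
    say("[bridge] comparing bridge modes over %d-%d",
        cfg$bridge_window[1], cfg$bridge_window[2])
    br <- select_bridge(panel, spec,
                        eval_start = cfg$bridge_window[1],
                        eval_end = cfg$bridge_window[2])
    spec$bridge_mode <- br$best
    say("[bridge] best mode: %s", br$best)
    emit_json(list(best = br$best, rmsfe = as.list(br$rmsfe),
                   condition_numbers = as.list(br$condition_numbers),
                   collinear = br$collinear),
              "bridge_report.json")
    res$bridge <- br

    stage <- "fit"
    say("[fit] final recursive fit through %d", max(panel$year))
    rf <- recursive_fit(panel, spec, base_end = cfg$base_end,
                        final_end = max(panel$year))
    final <- rf$fits[[length(rf$fits)]]
    s <- summary(final)
    fit_tab <- data.frame(term = names(final$coefficients),
                          estimate = unname(final$coefficients),
                          cluster_se = unname(final$se),
                          p_value = unname(final$p_value))
    emit_csv(fit_tab, "fit_coefficients.csv")
    r2 <- panel_r2(final)
    emit_json(r2, "fit_statistics.json")
    res$fit <- final
    res$recursive <- rf

    stage <- "diagnose"
    say("[diagnose] residual unit root, instruments, serial correlation")
    pp <- pp_panel_unit_root(final)
    ivd <- iv_diagnostics(rf$design, fit = final)
    ac <- residual_autocorrelation(final)
    emit_json(list(
      phillips_perron = list(fisher = pp$fisher, df = pp$df,
                             combined_p = pp$combined_p),
      iv = list(under_lm = ivd$under_lm, under_p = ivd$under_p,
                weak_F_min = ivd$weak_F_min, bias_category = ivd$bias_category,
                J = ivd$J, J_p = ivd$J_p),
      residual_ar1 = list(mean = ac$mean, range = ac$range)),
      "diagnostics.json")
    res$diagnostics <- list(pp = pp, iv = ivd, autocorr = ac)

    stage <- "forecast"
    say("[forecast] one-step-ahead evaluation %d-%d",
        cfg$base_end + 1, max(panel$year))
    fs <- one_step_forecasts(rf)
    fm <- forecast_metrics(fs)
    emit_csv(as.data.frame(fs), "forecasts.csv")
    emit_json(list(rmsfe = fm$rmsfe, bias_pct = fm$bias_pct,
                   correlation = fm$correlation, n = fm$n),
              "forecast_metrics.json")
    res$forecasts <- fs
    res$forecast_metrics <- fm

    if (!is.null(cfg$scenario)) {
      stage <- "scenario"
      scen <- cfg$scenario
      scen$seed <- scen$seed %||% child_seed(cfg$seed, 3L)
      base_exp <- cfg$baseline_expenditure %||%
        mean(panel$hexp[panel$year == max(panel$year)], na.rm = TRUE)
      say("[scenario] %g%%/yr reductions, horizon %d, %d trials, baseline $%.0f",
          100 * scen$r_prev, scen$horizon, scen$n_trials, base_exp)
      sr <- simulate_savings(final, scen, base_exp)
      emit_csv(sr$table, "scenario_savings.csv")
      res$scenario <- sr
    }

    stage <- "manifest"
    cfg_json <- file.path(cfg$out_dir, "config.json")
    jsonlite::write_json(serialize_config(cfg), cfg_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    manifest <- list(
      seed = cfg$seed,
      config_hash = unname(tools::md5sum(cfg_json)),
      artifacts = basename(c(artifacts, cfg_json)),
      created = "run manifest")
    emit_json(manifest, "manifest.json")
    res$manifest <- manifest
  }, error = function(e) {
    partial <- list(failed_stage = stage, error = conditionMessage(e),
                    artifacts = basename(artifacts), seed = cfg$seed)
    jsonlite::write_json(partial, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    stop_sc("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}

# Flatten a run_config into JSON-serializable form.
serialize_config <- function(cfg) {
  x <- unclass(cfg)
  x$spec <- unclass(x$spec)
  x$synth <- if (!is.null(x$synth)) unclass(x$synth)
  x$scenario <- if (!is.null(x$scenario)) unclass(x$scenario)
  x
}
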