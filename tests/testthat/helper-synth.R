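# Shared fixtures: small, fast synthetic configurations built in code.

# Reduced panel for unit tests (20 states, 16 years).
small_cfg <- function(seed, ...) {
  synth_config(n_states = 20L, start_year = 1997L, end_year = 2012L,
               seed = seed, ...)
}

# Noise-free configuration: the structural equation holds exactly.
noiseless_cfg <- function(seed, ...) {
  synth_config(seed = seed, error_sd = 0, cons_meas_sd = 0, cons_meas_tax = 0,
               break_mean = numeric(0), break_sd = numeric(0), ...)
}

# Minimal spec without averages/taxes for hand-checkable oracles.
spec_min <- function(...) {
  model_spec(cs_averages = character(0), tax_by_region = FALSE,
             bridge_mode = "none", ...)
}

# Tiny latent panel for closed-form oracles.
toy_panel <- function(ns = 3, seed = 1, start = 2000, end = 2012, ...) {
  generate_panel(synth_config(n_states = ns, start_year = start,
                              end_year = end, seed = seed,
                              true_gamma = numeric(0),
                              break_mean = numeric(0), break_sd = numeric(0),
                              ...))$latent
}

# A small hand-written panel (3 states x 4 years, one region each).
hand_panel_df <- function() {
  data.frame(
    state = rep(c("CA", "NY", "TX"), each = 4),
    year = rep(2001:2004, times = 3),
    region = rep(c("FW", "ME", "SW"), each = 4),
    hexp = c(4000, 4100, 4200, 4300, 5000, 5100, 5150, 5200,
             3500, 3600, 3650, 3700),
    prev = c(15, 14.5, 14, 13.5, 18, 17.5, 17, 16.5, 22, 21.5, 21, 20.5),
    cons = c(300, 295, 290, 285, 320, 315, 310, 305, 380, 375, 370, 365),
    income = c(45000, 45500, 46000, 46500, 50000, 50500, 51000, 51500,
               38000, 38500, 39000, 39500),
    elderly = c(11, 11.1, 11.2, 11.3, 13, 13.1, 13.2, 13.3,
                10, 10.1, 10.2, 10.3),
    black = c(6, 6, 6, 6, 15, 15, 15, 15, 11, 11, 11, 11),
    hispanic = c(32, 32.5, 33, 33.5, 16, 16.2, 16.4, 16.6,
                 36, 36.5, 37, 37.5),
    tax = c(0.87, 0.87, 0.87, 0.87, 1.5, 1.55, 1.6, 1.65,
            0.41, 0.41, 0.41, 0.41),
    population = c(34e6, 34.2e6, 34.4e6, 34.6e6, 19e6, 19e6, 19.1e6, 19.1e6,
                   21e6, 21.3e6, 21.6e6, 21.9e6),
    stringsAsFactors = FALSE)
}
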