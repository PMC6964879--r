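#' BEA Economic Region codes
#'
#' The eight Bureau of Economic Analysis Economic Regions used to index the
#' region-specific cigarette-tax elasticities: New England (NE), Mideast
#' (ME), Great Lakes (GL), Plains (PL), Southeast (SE), Southwest (SW),
#' Rocky Mountains (RM), Far West (FW).
#'
#' @return Character vector of the eight region codes.
#' @export
bea_regions <- function() {
  c("NE", "ME", "GL", "PL", "SE", "SW", "RM", "FW")
}

# Canonical panel columns. `log_fields` must be strictly positive wherever
# observed because the model is estimated in natural logarithms.
panel_columns <- function() {
  c("state", "year", "region", "hexp", "prev", "cons", "income",
    "elderly", "black", "hispanic", "tax", "population")
}

log_fields <- function() {
  c("hexp", "prev", "cons", "income", "elderly", "black", "hispanic", "tax")
}

# Variables measured by the BRFSS telephone survey, i.e. the series broken
# by the 2011 redesign (cell-phone frame + raking weights).
survey_fields <- function() {
  c("prev", "cons", "black", "hispanic")
}

#' The seven cross-sectional average candidates
#'
#' Variables whose lagged, equally-weighted cross-state averages are the
#' candidate controls for long-run national trends: the six state
#' regressors plus healthcare expenditure itself.
#'
#' @return Character vector of seven variable names.
#' @export
cs_average_candidates <- function() {
  c("hexp", "prev", "cons", "income", "elderly", "black", "hispanic")
}

#' Construct and validate a state panel
#'
#' A state panel is a long-format annual data frame with one row per
#' state-year holding real per capita healthcare expenditure (`hexp`, base
#' year dollars), adult current smoking prevalence (`prev`, percent), mean
#' annual cigarette consumption per adult current smoker (`cons`,
#' packs/year), real per capita personal income (`income`), percent of the
#' population elderly / African-American / Hispanic, the real cigarette
#' excise tax (`tax`, dollars per pack), resident `population`, and the
#' state's BEA Economic Region. Missing cells (`NA`) are allowed and treated
#' as missing completely at random; log-transformed fields must be strictly
#' positive wherever observed.
#'
#' @param df Data frame with the columns of [panel_columns()]; extra columns
#'   are kept as optional covariates.
#' @return A `state_panel` (data frame) sorted by state and year.
#' @export
state_panel <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(panel_columns(), names(df))
  if (length(missing_cols)) {
    stop_sc("panel is missing mandatory column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  df$state <- as.character(df$state)
  df$region <- as.character(df$region)
  df$year <- as.integer(df$year)

  bad_region <- setdiff(unique(df$region), bea_regions())
  if (length(bad_region)) {
    stop_sc("unknown BEA region label(s): %s", paste(bad_region, collapse = ", "))
  }
  reg_per_state <- tapply(df$region, df$state, function(r) length(unique(r)))
  if (any(reg_per_state > 1)) {
    stop_sc("state(s) mapped to more than one region: %s",
            paste(names(reg_per_state)[reg_per_state > 1], collapse = ", "))
  }

  for (f in log_fields()) {
    v <- df[[f]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      i <- bad[1]
      stop_sc("non-positive value in log-transformed field '%s' at state %s, year %d (%d violation(s) total)",
              f, df$state[i], df$year[i], length(bad))
    }
  }

  # years must form a contiguous range within each state
  by_state <- split(df$year, df$state)
  for (s in names(by_state)) {
    yrs <- sort(by_state[[s]])
    if (any(duplicated(yrs))) {
      stop_sc("duplicate year(s) for state %s", s)
    }
    if (length(yrs) > 1 && !all(diff(yrs) == 1)) {
      stop_sc("years are not contiguous for state %s", s)
    }
  }

  df <- df[order(df$state, df$year), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("state_panel", "data.frame")
  df
}

#' Read a state panel from CSV
#'
#' @param path Path to a long-format CSV (comma separated, header row,
#'   missing cells empty).
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values).
#' @return A validated [state_panel()].
#' @export
read_state_panel <- function(path, schema = NULL) {
  if (!file.exists(path)) stop_sc("panel file does not exist: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(df))
    if (length(missing_src)) {
      stop_sc("schema maps to column(s) absent from file: %s",
              paste(missing_src, collapse = ", "))
    }
    idx <- match(unname(schema), names(df))
    names(df)[idx] <- names(schema)
  }
  state_panel(df)
}

#' Write a state panel to CSV
#'
#' @param panel A [state_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Deflate a nominal series to base-year dollars
#'
#' Converts nominal dollar values to real values in `base_year` dollars with
#' a price index: `real_t = nominal_t * index[base_year] / index[t]`.
#'
#' @param nominal Numeric vector of nominal values.
#' @param year Integer vector of the year of each value.
#' @param index Price index: either a named numeric vector (names = years)
#'   or a data frame with columns `year` and `index`.
#' @param base_year Year whose dollars the output is expressed in.
#' @return Numeric vector of real values.
#' @export
deflate <- function(nominal, year, index, base_year) {
  if (is.data.frame(index)) {
    idx <- stats::setNames(index$index, index$year)
  } else {
    idx <- index
  }
  if (any(idx <= 0, na.rm = TRUE)) stop_sc("price index must be strictly positive")
  if (!as.character(base_year) %in% names(idx)) {
    stop_sc("base year %s missing from price index", base_year)
  }
  pos <- match(as.character(year), names(idx))
  if (anyNA(pos)) {
    stop_sc("year(s) missing from price index: %s",
            paste(unique(year[is.na(pos)]), collapse = ", "))
  }
  nominal * idx[[as.character(base_year)]] / as.numeric(idx[pos])
}
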