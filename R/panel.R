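## Balanced state-year panel: data model, validation, CSV I/O.
##
## A panel is a long-format data.frame with one row per (state, year) and
## columns state, year, population, deaths, crude_rate plus arbitrary
## covariate columns (at minimum unemployment_rate for the canonical design).
## Rates are deaths per 100,000 persons. Calendar years are kept as labels;
## model code re-indexes them internally as t = 1..T.

PANEL_CORE_COLS <- c("state", "year", "population", "deaths", "crude_rate")

#' Construct a state-year panel
#'
#' Builds a validated balanced panel from a long-format data frame. If only
#' one of `deaths`/`crude_rate` is present the other is derived
#' (`crude_rate = deaths / population * 1e5`; deaths rounded to the nearest
#' integer when derived from rates).
#'
#' @param data data.frame with columns `state`, `year`, `population`, and at
#'   least one of `deaths`, `crude_rate`; extra columns are kept as covariates.
#' @param validate if `TRUE` (default), stop on any invariant violation.
#' @return A `state_panel`: a data.frame sorted by (state, year) with the five
#'   core columns first, covariates after.
#' @export
state_panel <- function(data, validate = TRUE) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  need <- c("state", "year", "population")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop_arg("panel is missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (!("deaths" %in% names(data)) && !("crude_rate" %in% names(data))) {
    stop_arg("panel needs at least one of 'deaths' or 'crude_rate'")
  }
  if (nrow(data) == 0) stop_arg("panel has no records")
  data$state <- as.character(data$state)
  data$year <- as.integer(data$year)
  if (!("deaths" %in% names(data))) {
    data$deaths <- as.integer(round(data$crude_rate * data$population / 1e5))
  } else if (is.numeric(data$deaths) &&
             all(abs(data$deaths - round(data$deaths)) < 1e-8, na.rm = TRUE)) {
    data$deaths <- as.integer(round(data$deaths))
  }
  if (!("crude_rate" %in% names(data))) {
    data$crude_rate <- data$deaths / data$population * 1e5
  }
  covs <- setdiff(names(data), PANEL_CORE_COLS)
  data <- data[order(data$state, data$year), c(PANEL_CORE_COLS, covs), drop = FALSE]
  rownames(data) <- NULL
  class(data) <- c("state_panel", "data.frame")
  if (validate) {
    v <- validate_panel(data)
    if (length(v) > 0) {
      stop_arg("invalid panel:\n", paste("-", v, collapse = "\n"))
    }
  }
  data
}

#' @export
print.state_panel <- function(x, ...) {
  cat(sprintf(
    "state-year panel: %d states x %d years (%d records), covariates: %s\n",
    length(panel_states(x)), length(panel_years(x)), nrow(x),
    paste(panel_covariates(x), collapse = ", ")
  ))
  NextMethod()
}

#' Panel accessors
#'
#' `panel_states()` returns the sorted distinct state ids, `panel_years()` the
#' sorted distinct calendar years, and `panel_covariates()` the names of the
#' non-core columns.
#'
#' @param panel a `state_panel` (or compatible data.frame).
#' @return character / integer / character vector respectively.
#' @export
panel_states <- function(panel) sort(unique(as.character(panel$state)))

#' @rdname panel_states
#' @export
panel_years <- function(panel) sort(unique(as.integer(panel$year)))

#' @rdname panel_states
#' @export
panel_covariates <- function(panel) setdiff(names(panel), PANEL_CORE_COLS)

#' Validate a state-year panel
#'
#' Checks balance (one record per state-year over a contiguous year range),
#' positivity of populations, nonnegative integer deaths, and consistency of
#' `crude_rate` with `deaths / population * 1e5` (relative tolerance 1e-9).
#' Violations are returned, not raised.
#'
#' @param panel data.frame to check.
#' @return Character vector of violation descriptions; empty if the panel is
#'   well formed.
#' @export
validate_panel <- function(panel) {
  v <- character(0)
  need <- c("state", "year", "population")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0) {
    return(paste0("missing required column: ", miss))
  }
  if (!("deaths" %in% names(panel)) && !("crude_rate" %in% names(panel))) {
    return("missing both 'deaths' and 'crude_rate'")
  }
  if (nrow(panel) == 0) return("panel has no records")

  states <- panel_states(panel)
  years <- panel_years(panel)
  if (length(years) > 1 && !all(diff(years) == 1L)) {
    v <- c(v, paste0(
      "years are not consecutive: gaps after ",
      paste(years[which(diff(years) != 1L)], collapse = ", ")
    ))
  }
  key <- paste(panel$state, panel$year)
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    v <- c(v, paste0("duplicate record for (", dup, ")"))
  }
  full <- as.vector(outer(states, years, paste))
  missing_cells <- setdiff(full, key)
  if (length(missing_cells) > 0) {
    v <- c(v, paste0("unbalanced: missing record for (", missing_cells, ")"))
  }

  bad_pop <- which(!is.finite(panel$population) | panel$population <= 0)
  if (length(bad_pop) > 0) {
    v <- c(v, paste0(
      "population must be > 0 at (", key[bad_pop], ")"
    ))
  }
  if ("deaths" %in% names(panel)) {
    bad_d <- which(!is.finite(panel$deaths) | panel$deaths < 0 |
                     abs(panel$deaths - round(panel$deaths)) > 1e-8)
    if (length(bad_d) > 0) {
      v <- c(v, paste0("deaths must be a nonnegative integer at (", key[bad_d], ")"))
    }
  }
  if (all(c("deaths", "crude_rate") %in% names(panel))) {
    expected <- panel$deaths / panel$population * 1e5
    denom <- pmax(abs(expected), abs(panel$crude_rate), 1e-12)
    bad_r <- which(abs(panel$crude_rate - expected) / denom > 1e-9 &
                     abs(panel$crude_rate - expected) > 1e-12)
    if (length(bad_r) > 0) {
      v <- c(v, sprintf(
        "rate mismatch at (%s): crude_rate %.6g != deaths/population*1e5 = %.6g",
        key[bad_r], panel$crude_rate[bad_r], expected[bad_r]
      ))
    }
  }
  v
}

#' Read a state-year panel from CSV
#'
#' Reads a delimited long-format file (one row per state-year, header
#' required) and returns a validated panel. Column names can be remapped via
#' `schema`, e.g. `c(state = "st", deaths = "n_deaths")` when the file uses
#' nonstandard headers. If only deaths are present crude rates are derived,
#' and vice versa.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping canonical names
#'   (`state`, `year`, `population`, `deaths`, `crude_rate`, covariates) to
#'   the file's column names.
#' @return A `state_panel`.
#' @export
read_panel <- function(path, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!(src %in% names(df))) {
        stop_arg("schema maps '", canon, "' to missing column '", src, "'")
      }
      names(df)[names(df) == src] <- canon
    }
  }
  need <- c("state", "year", "population")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_arg("file ", path, " is missing required column(s): ",
             paste(miss, collapse = ", "))
  }
  if (!("deaths" %in% names(df)) && !("crude_rate" %in% names(df))) {
    stop_arg("file ", path, " needs a 'deaths' or 'crude_rate' column")
  }
  state_panel(df)
}

#' Write a state-year panel to CSV
#'
#' Writes the panel in the same long CSV dialect `read_panel()` reads
#' (UTF-8, header row, one row per state-year, covariate columns preserved).
#' Round trip is exact for integer fields and within 1e-9 relative error for
#' real fields.
#'
#' @param panel a valid `state_panel`.
#' @param path destination file path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  v <- validate_panel(panel)
  if (length(v) > 0) {
    stop_arg("refusing to write invalid panel:\n", paste("-", v, collapse = "\n"))
  }
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
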