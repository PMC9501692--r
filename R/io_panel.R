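# Panel construction: raw World-Bank-style indicators -> analysis panel
# (LGDP, LHEP, EMP). Each country is analyzed independently.

#' Analysis variables
#'
#' The three series the pipeline analyzes: natural-log GDP per capita
#' (`LGDP`), natural-log health expenditure per capita (`LHEP`) and the
#' employment rate `EMP` = 1 - unemployment rate, stored as a fraction.
#'
#' @return Character vector of the three variable labels, in canonical order.
#' @export
panel_variables <- function() c("LGDP", "LHEP", "EMP")

# map a variable label to the panel list slot
var_slot <- function(var) {
  switch(match.arg(var, panel_variables()),
         LGDP = "lgdp", LHEP = "lhep", EMP = "emp")
}

#' Read raw indicator rows for one country
#'
#' Reads a CSV with columns `country, year, gdp_pc, he_pc, unemp_pct`,
#' extracts one country's rows, sorts by year and validates: years must be
#' contiguous annual observations, `gdp_pc`/`he_pc` strictly positive and
#' `unemp_pct` in \[0, 100\]. Interpolation of gaps is refused by design;
#' with roughly twenty annual observations per country there is no margin
#' for imputed data.
#'
#' @param path Path to the CSV file.
#' @param country Country label to extract.
#' @return A `raw_indicators` object (a validated data frame).
#' @seealso [build_panel()]
#' @export
read_panel <- function(path, country) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("country", "year", "gdp_pc", "he_pc", "unemp_pct")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("format error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[df$country == country, needed]
  if (nrow(df) == 0) stop("no rows for country: ", country)
  df <- df[order(df$year), ]
  validate_raw_indicators(df)
}

#' Validate raw indicator rows
#'
#' @param df Data frame with columns `country, year, gdp_pc, he_pc, unemp_pct`
#'   for a single country.
#' @return The validated data frame, classed `raw_indicators`.
#' @export
validate_raw_indicators <- function(df) {
  if (anyNA(df)) stop("validation error: missing values in indicator rows")
  yrs <- df$year
  if (any(diff(yrs) != 1)) {
    gap <- yrs[which(diff(yrs) != 1)[1]] + 1
    stop("validation error: gap in years, missing year ", gap)
  }
  if (any(df$gdp_pc <= 0)) stop("validation error: non-positive gdp_pc")
  if (any(df$he_pc <= 0)) stop("validation error: non-positive he_pc")
  if (any(df$unemp_pct < 0 | df$unemp_pct > 100)) {
    stop("validation error: unemp_pct outside [0, 100]")
  }
  structure(df, class = c("raw_indicators", "data.frame"))
}

#' Build the analysis panel from validated raw indicators
#'
#' Applies the transforms `lgdp = ln(gdp_pc)`, `lhep = ln(he_pc)` and
#' `emp = 1 - unemp_pct / 100`. Natural logarithms are used so level
#' coefficients read as elasticities; the employment rate is kept as a
#' fraction in (0, 1\].
#'
#' @param raw A `raw_indicators` object from [read_panel()] or
#'   [validate_raw_indicators()].
#' @return A `country_panel` object.
#' @export
build_panel <- function(raw) {
  stopifnot(inherits(raw, "raw_indicators"))
  country_panel(country = raw$country[1], years = raw$year,
                lgdp = log(raw$gdp_pc), lhep = log(raw$he_pc),
                emp = 1 - raw$unemp_pct / 100)
}

#' Construct a country panel
#'
#' The canonical per-country container: aligned annual series of log GDP
#' per capita, log health expenditure per capita and the employment rate,
#' with a contiguous year index. At least 12 observations are required so
#' the lag-augmented regressions downstream keep positive residual
#' degrees of freedom.
#'
#' @param country Country label.
#' @param years Integer vector of consecutive calendar years.
#' @param lgdp,lhep Numeric series (natural logs), same length as `years`.
#' @param emp Numeric series of employment-rate fractions in (0, 1].
#' @return A `country_panel` object (list with the five fields above).
#' @export
country_panel <- function(country, years, lgdp, lhep, emp) {
  n <- length(years)
  if (n < 12) stop("panel too short: need T >= 12, got ", n)
  if (length(lgdp) != n || length(lhep) != n || length(emp) != n) {
    stop("series lengths differ from year index")
  }
  if (any(diff(years) != 1)) stop("years must be consecutive")
  if (!all(is.finite(lgdp)) || !all(is.finite(lhep))) {
    stop("non-finite values in lgdp/lhep")
  }
  if (any(emp <= 0 | emp > 1)) stop("emp must lie in (0, 1]")
  structure(list(country = as.character(country), years = as.integer(years),
                 lgdp = as.numeric(lgdp), lhep = as.numeric(lhep),
                 emp = as.numeric(emp)),
            class = "country_panel")
}

#' @export
print.country_panel <- function(x, ...) {
  cat(sprintf("<country_panel> %s, %d-%d (T = %d)\n", x$country,
              min(x$years), max(x$years), length(x$years)))
  invisible(x)
}

#' Number of observations in a panel
#' @param panel A `country_panel`.
#' @return Integer sample length T.
#' @export
panel_length <- function(panel) length(panel$years)

#' Extract one series from a panel by variable label
#' @param panel A `country_panel`.
#' @param var One of `"LGDP"`, `"LHEP"`, `"EMP"`.
#' @return Numeric vector.
#' @export
panel_series <- function(panel, var) panel[[var_slot(var)]]

#' @export
as.data.frame.country_panel <- function(x, ...) {
  data.frame(country = x$country, year = x$years, lgdp = x$lgdp,
             lhep = x$lhep, emp = x$emp)
}

#' Write a panel to CSV
#'
#' Serializes the transformed schema `country,year,lgdp,lhep,emp` at full
#' double precision, so [load_panel()] round-trips exactly.
#'
#' @param panel A `country_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  for (col in c("lgdp", "lhep", "emp")) {
    df[[col]] <- formatC(df[[col]], digits = 17, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transformed panel written by [write_panel()]
#'
#' @param path CSV path with columns `country,year,lgdp,lhep,emp`.
#' @param country Country label to extract.
#' @return A `country_panel`.
#' @export
load_panel <- function(path, country) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("country", "year", "lgdp", "lhep", "emp")
  if (!all(needed %in% names(df))) {
    stop("format error: expected columns ", paste(needed, collapse = ","))
  }
  df <- df[df$country == country, ]
  if (nrow(df) == 0) stop("no rows for country: ", country)
  df <- df[order(df$year), ]
  country_panel(country, df$year, df$lgdp, df$lhep, df$emp)
}

#' Serialize a panel to JSON
#' @param panel A `country_panel`.
#' @return A JSON string.
#' @export
panel_to_json <- function(panel) {
  jsonlite::toJSON(unclass(panel), auto_unbox = TRUE, digits = NA)
}
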