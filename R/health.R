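#' Air-quality reference standards
#'
#' Built-in reference concentrations per pollutant for the 2021 WHO
#' guideline values and China's national first-class and second-class
#' ambient-air-quality limits.  Units: ug/m3, except CO in mg/m3.
#'
#' @param name Which standards to return: any of `"WHO guideline value"`,
#'   `"National first-class standard"`, `"National second-class standard"`
#'   (default: all three).
#' @return Tibble with columns `standard`, `pollutant`, `limit`, `unit`.
#' @export
exposure_standards <- function(name = NULL) {
  limits <- tibble(
    standard = rep(c("WHO guideline value",
                     "National first-class standard",
                     "National second-class standard"), each = 6L),
    pollutant = rep(c("PM25", "PM10", "O3", "NO2", "SO2", "CO"), times = 3L),
    limit = c(
      5, 15, 100, 10, 40, 4,      # WHO (2021)
      15, 40, 100, 40, 20, 4,     # national first-class
      35, 70, 160, 40, 60, 4      # national second-class
    )
  ) %>%
    mutate(unit = POLLUTANT_UNITS[.data$pollutant])
  if (!is.null(name)) {
    unknown <- setdiff(name, unique(limits$standard))
    if (length(unknown)) {
      abort(paste0("unknown standard(s): ", paste(unknown, collapse = ", ")))
    }
    limits <- filter(limits, .data$standard %in% name)
  }
  limits
}

#' Build a custom reference standard
#'
#' @param name Label for the standard.
#' @param limits Named numeric vector of reference concentrations; names
#'   must be among the six pollutant channels.  All limits must be > 0.
#' @return Tibble in the same shape as [exposure_standards()].
#' @export
custom_standard <- function(name, limits) {
  bad <- setdiff(names(limits), POLLUTANTS)
  if (length(bad)) abort(paste0("unknown pollutant(s): ", paste(bad, collapse = ", ")))
  if (any(limits <= 0)) abort("all limits must be > 0.")
  tibble(
    standard = name, pollutant = names(limits),
    limit = as.numeric(limits), unit = POLLUTANT_UNITS[names(limits)]
  )
}

#' Exposure-response coefficients for all-cause mortality
#'
#' Percentage increase in population mortality per 10 ug/m3 of pollutant
#' exceedance (per 1 mg/m3 for CO), with 95% confidence intervals, as
#' aggregated from the epidemiological literature.
#'
#' @return Tibble with columns `pollutant`, `er` (percent per unit step),
#'   `ci_low`, `ci_high`, `unit_step` (10 ug/m3, or 1 mg/m3 for CO).
#' @export
exposure_response <- function() {
  tibble(
    pollutant = c("PM25", "PM10", "O3", "NO2", "SO2", "CO"),
    er = c(0.38, 0.31, 0.40, 1.40, 0.90, 3.70),
    ci_low = c(0.31, 0.22, 0.30, 1.10, 0.60, 2.88),
    ci_high = c(0.45, 0.41, 0.50, 1.60, 1.10, 4.51),
    unit_step = c(10, 10, 10, 10, 10, 1)
  )
}

#' Annual mean concentration of one pollutant
#'
#' Arithmetic mean of the daily values over one fully covered calendar
#' year.
#'
#' @param panel A pollutant panel tibble (`date` plus pollutant columns)
#'   or a forecast tibble with `date` and a value column named by
#'   `pollutant`.
#' @param pollutant Channel name, e.g. `"PM25"`.
#' @param year Calendar year, e.g. 2021.
#' @return Scalar mean concentration.
#' @export
annual_mean <- function(panel, pollutant, year) {
  if (!pollutant %in% names(panel)) {
    abort(sprintf("pollutant '%s' not found in the panel.", pollutant))
  }
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  rows <- panel[panel$date %in% days, ]
  missing_days <- setdiff(as.character(days), as.character(rows$date))
  if (length(missing_days)) {
    abort(paste0(
      "year ", year, " is not fully covered; missing ", length(missing_days),
      " day(s), first gaps: ",
      paste(utils::head(missing_days, 3L), collapse = ", ")
    ))
  }
  mean(rows[[pollutant]])
}

#' Excess mortality fraction above a reference concentration
#'
#' Linear excess-risk model: `ER * max(0, c_mean - reference) / unit_step`
#' percent, with the confidence interval propagated from the ER interval.
#' Set `log_linear = TRUE` for the relative-risk form
#' `100 * (exp(beta * excess) - 1)` with
#' `beta = log(1 + ER/100) / unit_step`, a common sensitivity analysis.
#'
#' @param c_mean Annual mean concentration (>= 0).
#' @param reference Reference concentration in the same units.
#' @param pollutant Channel name used to look up the coefficient.
#' @param er_table Exposure-response tibble (default [exposure_response()]).
#' @param log_linear Use the log-linear relative-risk form.
#' @return One-row tibble: `excess_pct`, `ci_low`, `ci_high` (percent).
#' @examples
#' excess_fraction(50, 10, "NO2")  # 5.6% (CI 4.4-6.4)
#' @export
excess_fraction <- function(c_mean, reference, pollutant,
                            er_table = exposure_response(),
                            log_linear = FALSE) {
  if (c_mean < 0) abort("`c_mean` must be >= 0.")
  row <- er_table[er_table$pollutant == pollutant, ]
  if (nrow(row) != 1L) abort(sprintf("unknown pollutant '%s'.", pollutant))
  exceed <- max(0, c_mean - reference)
  frac <- function(er_pct) {
    if (log_linear) {
      100 * (exp(log(1 + er_pct / 100) / row$unit_step * exceed) - 1)
    } else {
      er_pct * exceed / row$unit_step
    }
  }
  tibble(
    excess_pct = frac(row$er),
    ci_low = frac(row$ci_low),
    ci_high = frac(row$ci_high)
  )
}

#' Avoidable premature deaths from an excess-mortality fraction
#'
#' @param excess One-row tibble from [excess_fraction()] (columns
#'   `excess_pct`, `ci_low`, `ci_high`).
#' @param baseline_deaths Annual all-cause deaths of the exposed
#'   population (a user input; count of people, >= 0).
#' @return One-row tibble of class `burden_estimate`: `deaths`,
#'   `deaths_low`, `deaths_high` in units of 10,000 people.
#' @export
avoidable_deaths <- function(excess, baseline_deaths) {
  if (baseline_deaths < 0) abort("`baseline_deaths` must be >= 0.")
  out <- tibble(
    deaths = baseline_deaths * excess$excess_pct / 100 / 1e4,
    deaths_low = baseline_deaths * excess$ci_low / 100 / 1e4,
    deaths_high = baseline_deaths * excess$ci_high / 100 / 1e4
  )
  class(out) <- c("burden_estimate", class(out))
  out
}

#' Avoidable-mortality table across pollutants and standards
#'
#' Cross-tabulates avoidable premature deaths for every pollutant under
#' every reference standard, from the annual mean concentrations of one
#' year of a panel (typically forecast concentrations).  An entry is
#' exactly zero whenever the annual mean meets the standard.
#'
#' @param panel Pollutant panel or forecast panel covering `year`.
#' @param baseline_deaths Annual all-cause deaths of the exposed
#'   population (scalar, user input).
#' @param year Calendar year to assess (default 2021).
#' @param standards Standards tibble (default all of
#'   [exposure_standards()]).
#' @param er_table Exposure-response tibble (default
#'   [exposure_response()]).
#' @param log_linear Passed to [excess_fraction()].
#' @return Tibble with `standard`, `pollutant`, `annual_mean`, `limit`,
#'   `excess_pct`, `deaths`, `deaths_low`, `deaths_high` (deaths in units
#'   of 10,000 people).
#' @export
burden_table <- function(panel, baseline_deaths, year = 2021,
                         standards = exposure_standards(),
                         er_table = exposure_response(),
                         log_linear = FALSE) {
  missing_p <- setdiff(unique(standards$pollutant), names(panel))
  if (length(missing_p)) {
    abort(paste0("panel lacks pollutant(s): ", paste(missing_p, collapse = ", ")))
  }
  means <- setNames(
    vapply(unique(standards$pollutant), function(p) annual_mean(panel, p, year),
           numeric(1)),
    unique(standards$pollutant)
  )
  tab <- standards %>% mutate(annual_mean = means[.data$pollutant])
  cells <- purrr::pmap(
    list(tab$annual_mean, tab$limit, tab$pollutant),
    function(cm, lim, p) {
      ex <- excess_fraction(cm, lim, p, er_table, log_linear)
      dplyr::bind_cols(tibble(excess_pct = ex$excess_pct),
                       avoidable_deaths(ex, baseline_deaths))
    }
  ) %>% bind_rows()
  dplyr::bind_cols(tab, cells) %>%
    select("standard", "pollutant", "annual_mean", "limit",
           "excess_pct", "deaths", "deaths_low", "deaths_high")
}
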