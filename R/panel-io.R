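#' Read a daily pollutant panel from CSV
#'
#' Expects a header with `date` plus the six pollutant columns
#' (order-insensitive; `PM2.5`/`pm2_5` style aliases are normalized to
#' `PM25`, case-insensitively).  Rows are date-sorted and validated:
#' duplicate dates, unparseable dates and non-numeric cells are reported
#' with their row numbers; calendar gaps abort unless `fill_gaps = TRUE`,
#' which forward-fills and reports the count.
#'
#' @param path CSV file path.
#' @param fill_gaps Forward-fill missing calendar days (default `FALSE`).
#' @return A `pollutant_panel` tibble (`date` plus the six channels).
#' @export
read_panel_csv <- function(path, fill_gaps = FALSE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(raw) <- normalize_channel_names(names(raw))
  missing_cols <- setdiff(c("date", POLLUTANTS), names(raw))
  if (length(missing_cols)) {
    abort(paste0("panel CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  bad_dates <- which(is.na(dates))
  if (length(bad_dates)) {
    abort(paste0("unparseable date(s) at row(s): ",
                 paste(utils::head(bad_dates, 5L), collapse = ", ")))
  }
  dup <- which(duplicated(dates))
  if (length(dup)) {
    abort(paste0("duplicate date(s) at row(s): ",
                 paste(utils::head(dup, 5L), collapse = ", ")))
  }
  values <- lapply(POLLUTANTS, function(p) {
    v <- suppressWarnings(as.numeric(raw[[p]]))
    bad <- which(is.na(v) & !is.na(raw[[p]]) | is.na(raw[[p]]))
    if (length(bad)) {
      abort(paste0("non-numeric or missing ", p, " value(s) at row(s): ",
                   paste(utils::head(bad, 5L), collapse = ", ")))
    }
    v
  })
  panel <- tibble(date = dates)
  for (i in seq_along(POLLUTANTS)) panel[[POLLUTANTS[i]]] <- values[[i]]
  panel <- arrange(panel, .data$date)
  gaps <- as.integer(diff(panel$date)) - 1L
  n_missing <- sum(gaps)
  if (n_missing > 0) {
    if (!fill_gaps) {
      abort(sprintf(
        "panel has %d missing calendar day(s); re-run with fill_gaps = TRUE to forward-fill.",
        n_missing))
    }
    full_dates <- seq(min(panel$date), max(panel$date), by = "day")
    idx <- findInterval(full_dates, panel$date)
    panel <- panel[idx, ]
    panel$date <- full_dates
    inform(sprintf("forward-filled %d missing day(s).", n_missing))
  }
  attr(panel, "units") <- POLLUTANT_UNITS
  class(panel) <- c("pollutant_panel", class(panel))
  panel
}

normalize_channel_names <- function(nms) {
  key <- toupper(gsub("[^A-Za-z0-9]", "", nms))
  map <- c(
    DATE = "date", PM25 = "PM25", PM10 = "PM10", SO2 = "SO2",
    NO2 = "NO2", CO = "CO", O3 = "O3"
  )
  out <- unname(map[key])
  ifelse(is.na(out), nms, out)
}

#' Write a pollutant panel to CSV
#'
#' Header `date,PM25,PM10,SO2,NO2,CO,O3`, ISO-8601 dates, one row per
#' day; the exact format [read_panel_csv()] expects.
#'
#' @param panel A pollutant panel tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  out <- panel[, c("date", POLLUTANTS)]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write / read a panel spec as JSON
#'
#' @param spec A [panel_spec()].
#' @param path JSON file path.
#' @return `path` (write) or a `panel_spec` (read).
#' @export
write_panel_spec <- function(spec, path) {
  payload <- list(
    n_days = spec$n_days, start_date = format(spec$start_date),
    seed = spec$seed,
    pollutants = spec$pollutants,
    cross_correlation = spec$cross_correlation
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel_spec
#' @export
read_panel_spec <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc <- as.matrix(p$cross_correlation)
  dimnames(cc) <- list(POLLUTANTS, POLLUTANTS)
  panel_spec(
    n_days = p$n_days, start_date = p$start_date, seed = p$seed,
    pollutants = as_tibble(p$pollutants), cross_correlation = cc
  )
}
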