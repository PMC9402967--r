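#' Specify a synthetic pollutant panel
#'
#' Builds the parameter block for [generate_panel()].  The generator emulates
#' the qualitative structure of daily monitoring records from heavily
#' polluted northern-Chinese cities: an annual cycle peaking in January for
#' PM2.5, PM10, SO2, NO2 and CO ("U"-shaped years) and in summer for O3
#' ("inverted-U"), a slow multi-year decline for most channels,
#' autocorrelated day-to-day noise, and cross-pollutant correlation.
#'
#' @param n_days Number of daily steps (default 2192, i.e. 2016-01-01 to
#'   2021-12-31 inclusive).  Must be at least 40.
#' @param start_date First calendar day (`Date` or ISO-8601 string).
#' @param seed Integer seed; the same spec and seed give bit-identical
#'   panels.
#' @param pollutants Tibble with one row per channel and columns
#'   `pollutant`, `base_level`, `seasonal_amplitude`, `seasonal_phase`
#'   (`"winter-peak"` or `"summer-peak"`), `annual_trend` (fraction per
#'   year; negative means decline), `ar_coefficient` (in `[0, 1)`) and
#'   `noise_sd`.  Defaults cover all six channels in the canonical order
#'   PM25, PM10, SO2, NO2, CO, O3; units are ug/m3 except CO in mg/m3.
#' @param cross_correlation 6 x 6 correlation matrix for the noise
#'   innovations (symmetric, unit diagonal, positive semidefinite).  The
#'   default couples the five winter-peak channels positively and O3
#'   negatively to them.
#'
#' @return A list of class `panel_spec`.
#' @seealso [generate_panel()]
#' @export
panel_spec <- function(n_days = 2192L,
                       start_date = "2016-01-01",
                       seed = 1L,
                       pollutants = default_pollutant_blocks(),
                       cross_correlation = default_cross_correlation()) {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 40L) {
    abort("`n_days` must be an integer >= 40 (two window upper bounds).")
  }
  start_date <- as.Date(start_date)
  if (is.na(start_date)) abort("`start_date` is not a valid date.")
  stopifnot(is_tibble(pollutants) || is.data.frame(pollutants))
  pollutants <- as_tibble(pollutants)
  needed <- c("pollutant", "base_level", "seasonal_amplitude",
              "seasonal_phase", "annual_trend", "ar_coefficient", "noise_sd")
  missing_cols <- setdiff(needed, names(pollutants))
  if (length(missing_cols)) {
    abort(paste0("`pollutants` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!identical(sort(pollutants$pollutant), sort(POLLUTANTS))) {
    abort("`pollutants` must contain exactly the six channels PM25, PM10, SO2, NO2, CO, O3.")
  }
  pollutants <- pollutants[match(POLLUTANTS, pollutants$pollutant), ]
  if (!all(pollutants$seasonal_phase %in% c("winter-peak", "summer-peak"))) {
    abort("`seasonal_phase` must be \"winter-peak\" or \"summer-peak\".")
  }
  if (any(pollutants$ar_coefficient < 0 | pollutants$ar_coefficient >= 1)) {
    abort("`ar_coefficient` must lie in [0, 1).")
  }
  check_correlation_matrix(cross_correlation)

  structure(
    list(
      n_days = n_days, start_date = start_date, seed = as.integer(seed),
      pollutants = pollutants, cross_correlation = cross_correlation
    ),
    class = "panel_spec"
  )
}

#' Default per-pollutant generator blocks
#'
#' Levels, amplitudes, declines and noise scales chosen once to resemble a
#' heavily polluted northern-Chinese city over 2016--2021 (annual-mean PM2.5
#' around 50 ug/m3 falling a few percent a year, strong winter peaks, O3
#' peaking in summer and not declining).
#'
#' @return Tibble with one row per pollutant channel.
#' @export
default_pollutant_blocks <- function() {
  tibble(
    pollutant = POLLUTANTS,
    base_level = c(55, 100, 25, 40, 1.1, 95),
    seasonal_amplitude = c(30, 45, 14, 14, 0.45, 45),
    seasonal_phase = c(rep("winter-peak", 5), "summer-peak"),
    annual_trend = c(-0.06, -0.05, -0.12, -0.04, -0.06, 0.01),
    ar_coefficient = c(0.7, 0.7, 0.6, 0.6, 0.7, 0.6),
    noise_sd = c(12, 20, 5, 8, 0.18, 14)
  )
}

#' Default cross-pollutant correlation of noise innovations
#'
#' Moderate positive coupling among the combustion-related channels and a
#' negative coupling between O3 and the rest; a placeholder for the
#' qualitative statement that the six pollutants co-move, not an estimate
#' from any monitoring data set.
#'
#' @return 6 x 6 positive-definite correlation matrix.
#' @export
default_cross_correlation <- function() {
  r <- matrix(0.4, 6, 6, dimnames = list(POLLUTANTS, POLLUTANTS))
  r["PM25", "PM10"] <- r["PM10", "PM25"] <- 0.7
  r["PM25", "CO"] <- r["CO", "PM25"] <- 0.55
  r[, "O3"] <- r["O3", ] <- -0.25
  diag(r) <- 1
  r
}

check_correlation_matrix <- function(r) {
  if (!is.matrix(r) || nrow(r) != 6L || ncol(r) != 6L) {
    abort("`cross_correlation` must be a 6 x 6 matrix.")
  }
  if (max(abs(r - t(r))) > 1e-10) abort("`cross_correlation` must be symmetric.")
  if (max(abs(diag(r) - 1)) > 1e-10) abort("`cross_correlation` must have a unit diagonal.")
  if (any(abs(r) > 1 + 1e-10)) abort("`cross_correlation` entries must lie in [-1, 1].")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(paste0("`cross_correlation` is not positive semidefinite ",
                 "(smallest eigenvalue ", format(min(ev), digits = 4), ")."))
  }
  invisible(r)
}

#' Generate a seeded synthetic pollutant panel
#'
#' Simulates daily concentrations for the six channels.  Each channel is
#' `max(0, base * (1 + trend * t / 365.25) + amplitude * cos(2 * pi *
#' (t - peak) / 365.25) + e_t)`, where the noise `e_t` is a channelwise
#' AR(1) recursion driven by cross-correlated Gaussian innovations
#' (Cholesky factor of `cross_correlation`), scaled so the stationary
#' standard deviation equals `noise_sd`.  Winter-peak channels peak near
#' mid-January, summer-peak channels near mid-July.
#'
#' @param spec A [panel_spec()].
#' @return A tibble of class `pollutant_panel` with columns `date`, `PM25`,
#'   `PM10`, `SO2`, `NO2`, `CO`, `O3`; concentrations are non-negative,
#'   dates contiguous daily.  Units are attached as the `units` attribute.
#' @examples
#' panel <- generate_panel(panel_spec(n_days = 400, seed = 7))
#' dplyr::glimpse(panel)
#' @export
generate_panel <- function(spec = panel_spec()) {
  if (!inherits(spec, "panel_spec")) abort("`spec` must be a `panel_spec`.")
  n <- spec$n_days
  blocks <- spec$pollutants
  dates <- spec$start_date + seq_len(n) - 1L
  t_days <- as.numeric(dates - as.Date(paste0(format(spec$start_date, "%Y"), "-01-01")))

  root <- sym_sqrt(spec$cross_correlation)
  withr_seed <- set_local_seed(spec$seed)
  on.exit(withr_seed(), add = TRUE)

  innov <- matrix(rnorm(n * 6L), n, 6L) %*% root  # correlated N(0,1) rows
  values <- matrix(0, n, 6L, dimnames = list(NULL, POLLUTANTS))
  # day-of-year of the seasonal peak: Jan 15 (winter) / Jul 15 (summer)
  peak_day <- ifelse(blocks$seasonal_phase == "winter-peak", 14, 195.5)
  for (j in seq_len(6L)) {
    b <- blocks[j, ]
    phi <- b$ar_coefficient
    e <- numeric(n)
    scale <- b$noise_sd * sqrt(1 - phi^2)
    e[1] <- b$noise_sd * innov[1, j]
    for (t in seq(2L, n)) e[t] <- phi * e[t - 1] + scale * innov[t, j]
    seasonal <- b$seasonal_amplitude *
      cos(2 * pi * (t_days - peak_day[j]) / 365.25)
    trend <- b$base_level * (1 + b$annual_trend * t_days / 365.25)
    values[, j] <- pmax(0, trend + seasonal + e)
  }

  out <- as_tibble(as.data.frame(values))
  out <- tibble(date = dates) %>% dplyr::bind_cols(out)
  attr(out, "units") <- POLLUTANT_UNITS
  class(out) <- c("pollutant_panel", class(out))
  out
}

# Symmetric square root tolerating a semidefinite matrix.
sym_sqrt <- function(r) {
  ev <- eigen(r, symmetric = TRUE)
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
}

# Scoped RNG: restores the caller's .Random.seed on exit.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Generate a multi-tone analytic test signal
#'
#' Sum of sinusoids plus optional Gaussian noise, with the exact closed-form
#' components retained so decomposition results can be compared against the
#' truth.
#'
#' @param frequencies Distinct tone frequencies in cycles per sample.
#' @param amplitudes One amplitude per tone.
#' @param n_points Number of samples.
#' @param noise_sd Standard deviation of additive white noise (0 = none).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return List of class `tone_signal`: `signal` (numeric vector),
#'   `components` (matrix, one column per tone, low frequency last),
#'   `frequencies`, `time` (0-based sample index).
#' @examples
#' s <- generate_tone_signal(c(0.05, 0.005), c(1, 1), 2000)
#' max(abs(s$signal - rowSums(s$components)))
#' @export
generate_tone_signal <- function(frequencies, amplitudes = rep(1, length(frequencies)),
                                 n_points, noise_sd = 0, seed = 1L) {
  if (length(frequencies) == 0L) abort("`frequencies` must contain at least one tone.")
  if (anyDuplicated(frequencies)) abort("`frequencies` must be distinct.")
  if (length(amplitudes) != length(frequencies)) {
    abort("`amplitudes` must match `frequencies` in length.")
  }
  ord <- order(frequencies, decreasing = TRUE)  # highest frequency first
  frequencies <- frequencies[ord]
  amplitudes <- amplitudes[ord]
  tt <- seq_len(n_points) - 1
  components <- vapply(
    seq_along(frequencies),
    function(k) amplitudes[k] * sin(2 * pi * frequencies[k] * tt),
    numeric(n_points)
  )
  colnames(components) <- paste0("tone_", signif(frequencies, 6))
  signal <- rowSums(components)
  if (noise_sd > 0) {
    restore <- set_local_seed(seed)
    on.exit(restore(), add = TRUE)
    signal <- signal + rnorm(n_points, sd = noise_sd)
  }
  structure(
    list(signal = signal, components = components,
         frequencies = frequencies, time = tt),
    class = "tone_signal"
  )
}
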