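test_that("built-in standards carry all 18 published limits", {
  std <- exposure_standards()
  expect_equal(nrow(std), 18L)
  lim <- function(s, p) std$limit[std$standard == s & std$pollutant == p]
  who <- "WHO guideline value"
  first <- "National first-class standard"
  second <- "National second-class standard"
  expect_equal(lim(who, "PM25"), 5)
  expect_equal(lim(who, "PM10"), 15)
  expect_equal(lim(who, "O3"), 100)
  expect_equal(lim(who, "NO2"), 10)
  expect_equal(lim(who, "SO2"), 40)
  expect_equal(lim(who, "CO"), 4)
  expect_equal(lim(first, "PM25"), 15)
  expect_equal(lim(first, "PM10"), 40)
  expect_equal(lim(first, "O3"), 100)
  expect_equal(lim(first, "NO2"), 40)
  expect_equal(lim(first, "SO2"), 20)
  expect_equal(lim(first, "CO"), 4)
  expect_equal(lim(second, "PM25"), 35)
  expect_equal(lim(second, "PM10"), 70)
  expect_equal(lim(second, "O3"), 160)
  expect_equal(lim(second, "NO2"), 40)
  expect_equal(lim(second, "SO2"), 60)
  expect_equal(lim(second, "CO"), 4)
})

test_that("exposure-response registry matches the published coefficients", {
  er <- exposure_response()
  expect_equal(nrow(er), 6L)
  row <- function(p) er[er$pollutant == p, ]
  expect_equal(unlist(row("PM25")[, c("er", "ci_low", "ci_high")], use.names = FALSE),
               c(0.38, 0.31, 0.45))
  expect_equal(unlist(row("PM10")[, c("er", "ci_low", "ci_high")], use.names = FALSE),
               c(0.31, 0.22, 0.41))
  expect_equal(unlist(row("O3")[, c("er", "ci_low", "ci_high")], use.names = FALSE),
               c(0.40, 0.30, 0.50))
  expect_equal(unlist(row("NO2")[, c("er", "ci_low", "ci_high")], use.names = FALSE),
               c(1.40, 1.10, 1.60))
  expect_equal(unlist(row("SO2")[, c("er", "ci_low", "ci_high")], use.names = FALSE),
               c(0.90, 0.60, 1.10))
  expect_equal(unlist(row("CO")[, c("er", "ci_low", "ci_high")], use.names = FALSE),
               c(3.70, 2.88, 4.51))
  expect_true(all(er$ci_low <= er$er & er$er <= er$ci_high))
  expect_equal(row("CO")$unit_step, 1)
  expect_true(all(er$unit_step[er$pollutant != "CO"] == 10))
})

test_that("excess fraction is zero at the reference and scales linearly", {
  at_ref <- excess_fraction(40, 40, "SO2")
  expect_equal(unlist(at_ref, use.names = FALSE), c(0, 0, 0))
  no2 <- excess_fraction(50, 10, "NO2")
  expect_equal(no2$excess_pct, 5.60)
  expect_equal(no2$ci_low, 4.40)
  expect_equal(no2$ci_high, 6.40)
  single <- excess_fraction(20, 10, "PM25")
  double <- excess_fraction(30, 10, "PM25")
  expect_equal(double$excess_pct, 2 * single$excess_pct)
  expect_error(excess_fraction(10, 5, "NOX"), "unknown")
})

test_that("below-reference concentrations never produce negative excess", {
  low <- excess_fraction(3, 10, "PM25")
  expect_equal(low$excess_pct, 0)
  expect_equal(low$ci_high, 0)
})

test_that("avoidable deaths convert baseline counts into 1e4-person units", {
  zero <- avoidable_deaths(excess_fraction(5, 10, "PM25"), 1e6)
  expect_equal(zero$deaths, 0)
  one <- avoidable_deaths(tibble::tibble(excess_pct = 1, ci_low = 0.5, ci_high = 1.5), 1e6)
  expect_equal(one$deaths, 1.0)       # 1% of 1e6 = 1e4 = 1.0 in 1e4 units
  expect_equal(one$deaths_low, 0.5)
  expect_equal(one$deaths_high, 1.5)
  expect_true(one$deaths_low <= one$deaths && one$deaths <= one$deaths_high)
  expect_error(avoidable_deaths(excess_fraction(5, 10, "PM25"), -1), ">= 0")
})

make_flat_panel <- function(levels, year = 2021) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  out <- tibble::tibble(date = dates)
  for (p in names(levels)) out[[p]] <- levels[[p]]
  out
}

test_that("annual mean requires full coverage and averages correctly", {
  p <- make_flat_panel(c(PM25 = 50, PM10 = 80, SO2 = 10, NO2 = 20, CO = 1, O3 = 90))
  expect_equal(annual_mean(p, "PM25", 2021), 50)
  alt <- p
  alt$PM25 <- rep(c(0, 100), length.out = nrow(p))
  expect_equal(annual_mean(alt, "PM25", 2021), mean(alt$PM25))
  expect_equal(annual_mean(alt, "PM25", 2021), sum(alt$PM25) / nrow(alt))
  expect_error(annual_mean(p[-5, ], "PM25", 2021), "missing")
  expect_error(annual_mean(p, "PM7", 2021), "not found")
})

test_that("a clean-air scenario yields an all-zero burden table", {
  p <- make_flat_panel(c(PM25 = 4, PM10 = 10, SO2 = 5, NO2 = 5, CO = 0.5, O3 = 50))
  tab <- burden_table(p, baseline_deaths = 1e6)
  expect_equal(nrow(tab), 18L)
  expect_true(all(tab$deaths == 0))
  expect_true(all(tab$deaths_high == 0))
})

test_that("burden is zero exactly when the annual mean meets the standard", {
  p <- make_flat_panel(c(PM25 = 40, PM10 = 60, SO2 = 30, NO2 = 25, CO = 2, O3 = 120))
  tab <- burden_table(p, baseline_deaths = 5e5)
  expect_true(all((tab$deaths == 0) == (tab$annual_mean <= tab$limit)))
})

test_that("tightening the standard never decreases the estimate", {
  p <- make_flat_panel(c(PM25 = 60, PM10 = 120, SO2 = 45, NO2 = 45, CO = 5, O3 = 170))
  tab <- burden_table(p, baseline_deaths = 1e6)
  for (pol in unique(tab$pollutant)) {
    sub <- tab[tab$pollutant == pol, ]
    ord <- order(sub$limit)  # stricter = smaller limit
    expect_true(all(diff(sub$deaths[ord]) <= 1e-12))
  }
})

test_that("burden table cells equal the composition of the three steps", {
  p <- make_flat_panel(c(PM25 = 60, PM10 = 120, SO2 = 45, NO2 = 45, CO = 5, O3 = 170))
  base <- 7.5e5
  tab <- burden_table(p, baseline_deaths = base)
  for (i in seq_len(nrow(tab))) {
    ex <- excess_fraction(tab$annual_mean[i], tab$limit[i], tab$pollutant[i])
    d <- avoidable_deaths(ex, base)
    expect_equal(tab$deaths[i], d$deaths, tolerance = 1e-12)
    expect_true(tab$deaths_low[i] <= tab$deaths[i] + 1e-12)
    expect_true(tab$deaths[i] <= tab$deaths_high[i] + 1e-12)
  }
})

test_that("the log-linear sensitivity form is close to linear for small excess", {
  lin <- excess_fraction(12, 10, "PM25")
  log_ <- excess_fraction(12, 10, "PM25", log_linear = TRUE)
  expect_equal(log_$excess_pct, lin$excess_pct, tolerance = 2e-2)
  lin_big <- excess_fraction(110, 10, "NO2")
  log_big <- excess_fraction(110, 10, "NO2", log_linear = TRUE)
  expect_gt(log_big$excess_pct, lin_big$excess_pct)  # convexity
})

test_that("custom standards validate their inputs", {
  cs <- custom_standard("city plan", c(PM25 = 30, NO2 = 30))
  expect_equal(nrow(cs), 2L)
  expect_error(custom_standard("bad", c(PMX = 10)), "unknown")
  expect_error(custom_standard("bad", c(PM25 = 0)), "> 0")
})
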