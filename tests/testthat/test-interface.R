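test_that("panel CSV writing and reading round-trips", {
  panel <- quick_panel(n_days = 120)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(panel, path)
  back <- read_panel_csv(path)
  expect_equal(back$date, panel$date)
  for (p in c("PM25", "PM10", "SO2", "NO2", "CO", "O3")) {
    expect_equal(back[[p]], panel[[p]], tolerance = 1e-12)
  }
})

test_that("shuffled rows come back date-sorted", {
  panel <- quick_panel(n_days = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  shuffled <- panel[sample(nrow(panel)), ]
  write_panel_csv(shuffled, path)
  back <- read_panel_csv(path)
  expect_equal(back$date, sort(panel$date))
  expect_false(is.unsorted(back$date))
})

test_that("a hand-written three-row fixture parses to known values", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "date,PM2.5,PM10,SO2,NO2,CO,O3",
    "2020-01-01,55.5,101,20,41,1.2,30",
    "2020-01-02,60,110,22,44,1.3,28",
    "2020-01-03,48.25,95,19,39,1.1,33"
  ), path)
  panel <- read_panel_csv(path)
  expect_equal(nrow(panel), 3L)
  expect_equal(panel$PM25, c(55.5, 60, 48.25))   # alias normalized
  expect_equal(panel$CO, c(1.2, 1.3, 1.1))
  expect_equal(panel$date, as.Date(c("2020-01-01", "2020-01-02", "2020-01-03")))
})

test_that("duplicate and unparseable dates are reported with rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "date,PM25,PM10,SO2,NO2,CO,O3",
    "2020-01-01,1,1,1,1,1,1",
    "2020-01-01,2,2,2,2,2,2"
  ), path)
  expect_error(read_panel_csv(path), "duplicate")
  writeLines(c(
    "date,PM25,PM10,SO2,NO2,CO,O3",
    "not-a-date,1,1,1,1,1,1"
  ), path)
  expect_error(read_panel_csv(path), "unparseable")
  writeLines(c(
    "date,PM25,PM10,SO2,NO2,CO,O3",
    "2020-01-01,oops,1,1,1,1,1"
  ), path)
  expect_error(read_panel_csv(path), "non-numeric")
})

test_that("calendar gaps abort unless forward-filling is requested", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "date,PM25,PM10,SO2,NO2,CO,O3",
    "2020-01-01,1,1,1,1,1,1",
    "2020-01-04,4,4,4,4,4,4"
  ), path)
  expect_error(read_panel_csv(path), "missing calendar")
  panel <- suppressMessages(read_panel_csv(path, fill_gaps = TRUE))
  expect_equal(nrow(panel), 4L)
  expect_equal(panel$PM25, c(1, 1, 1, 4))  # forward fill
})

test_that("panel specs survive a JSON round trip", {
  spec <- panel_spec(n_days = 100, seed = 33)
  path <- withr::local_tempfile(fileext = ".json")
  write_panel_spec(spec, path)
  back <- read_panel_spec(path)
  expect_identical(generate_panel(back), generate_panel(spec))
})

test_that("the workflow writes every stage artifact plus a manifest", {
  dir <- withr::local_tempdir()
  cfg <- run_config(
    panel = panel_spec(n_days = 366 + 365 + 365, seed = 4),  # full 2016-2018
    target = "PM25",
    pipeline = pipeline_config(
      train_years = 2016:2017, test_years = 2018,
      epochs = 3L, decomposition = "ceemdan", covariates = FALSE,
      decomp_config = decomposition_config(ensemble_size = 8L, seed = 4)
    ),
    spec = forecast_model_spec(n = 3, cells = 5, epochs = 3, seed = 4),
    baseline_deaths = 1e6,
    seed = 4
  )
  # the burden stage assesses the test year
  cfg$pipeline$test_years <- 2018
  manifest <- run_workflow(cfg, dir)
  expect_setequal(names(manifest$stages),
                  c("ingest", "decompose", "forecast", "evaluate", "burden"))
  expect_true(all(vapply(manifest$stages, function(s) s$status, "") == "ok"))
  for (f in c("panel.csv", "decomposition.csv", "predictions.csv",
              "metrics.json", "burden.csv", "manifest.json")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  preds <- readr::read_csv(file.path(dir, "predictions.csv"),
                           show_col_types = FALSE)
  expect_named(preds, c("date", "y_true", "y_pred"))
  expect_equal(manifest$seed, 4L)
})

test_that("disabling decomposition omits the decomposition artifact", {
  dir <- withr::local_tempdir()
  cfg <- run_config(
    panel = panel_spec(n_days = 3 * 365, seed = 5),
    pipeline = pipeline_config(
      train_years = 2016:2017, test_years = 2018,
      epochs = 2L, decomposition = "none", covariates = FALSE
    ),
    spec = forecast_model_spec(n = 2, cells = 4, epochs = 2, seed = 5),
    seed = 5
  )
  manifest <- run_workflow(cfg, dir)
  expect_false("decompose" %in% names(manifest$stages))
  expect_false(file.exists(file.path(dir, "decomposition.csv")))
  expect_false("burden" %in% names(manifest$stages))
})

test_that("re-running the same config reproduces identical metrics", {
  cfg <- run_config(
    panel = panel_spec(n_days = 3 * 365, seed = 6),
    pipeline = pipeline_config(
      train_years = 2016:2017, test_years = 2018,
      epochs = 2L, decomposition = "none", covariates = FALSE
    ),
    spec = forecast_model_spec(n = 2, cells = 4, epochs = 2, seed = 6),
    seed = 6
  )
  m1 <- run_workflow(cfg, withr::local_tempdir())
  m2 <- run_workflow(cfg, withr::local_tempdir())
  expect_identical(m1$metrics, m2$metrics)
})

test_that("run_config validates its target and panel path", {
  expect_error(run_config(target = "XX"), "target")
  expect_error(run_config(panel_csv = "/nonexistent/file.csv"), "does not exist")
})
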