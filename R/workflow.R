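#' Run configuration for the end-to-end workflow
#'
#' @param panel_csv Path to a panel CSV, or `NULL` to simulate a panel
#'   from `panel` (a [panel_spec()]).
#' @param panel A [panel_spec()] used when `panel_csv` is `NULL`.
#' @param target Pollutant to forecast.
#' @param pipeline A [pipeline_config()].
#' @param pso A [pso_config()] or `NULL` for the default search.
#' @param spec A [forecast_model_spec()] to skip tuning, or `NULL`.
#' @param baseline_deaths Annual deaths for the burden stage, or `NULL`
#'   to skip it.
#' @param seed Master seed, copied into every stage that accepts one.
#' @return List of class `run_config`.
#' @export
run_config <- function(panel_csv = NULL, panel = panel_spec(),
                       target = "PM25", pipeline = pipeline_config(),
                       pso = NULL, spec = NULL, baseline_deaths = NULL,
                       seed = 1L) {
  if (!target %in% POLLUTANTS) {
    abort(paste0("`target` must be one of: ", paste(POLLUTANTS, collapse = ", ")))
  }
  if (!is.null(panel_csv) && !file.exists(panel_csv)) {
    abort(sprintf("panel file '%s' does not exist.", panel_csv))
  }
  seed <- as.integer(seed)
  pipeline$seed <- seed
  if (!is.null(panel) && is.null(panel_csv)) panel$seed <- seed
  structure(
    list(panel_csv = panel_csv, panel = panel, target = target,
         pipeline = pipeline, pso = pso, spec = spec,
         baseline_deaths = baseline_deaths, seed = seed),
    class = "run_config"
  )
}

#' Execute the full forecasting workflow
#'
#' Chains the stages simulate/ingest, decompose, tune, forecast, evaluate
#' and (when baseline deaths are given) burden, writing every artifact
#' plus a manifest JSON into `out_dir`.  The manifest records the
#' configuration, seed, package version, per-stage timings and the final
#' metrics, so a run can be reproduced from the manifest alone.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly (list).
#' @export
run_workflow <- function(config, out_dir = tempfile("aerocast_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("aerocast")),
    seed = config$seed,
    target = config$target,
    decomposition = config$pipeline$decomposition,
    stages = list()
  )
  stage <- function(name, fun) {
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      abort(sprintf("workflow stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    )
    out
  }

  panel <- stage("ingest", function() {
    if (!is.null(config$panel_csv)) {
      read_panel_csv(config$panel_csv)
    } else {
      p <- generate_panel(config$panel)
      write_panel_csv(p, file.path(out_dir, "panel.csv"))
      p
    }
  })

  decomp <- NULL
  if (config$pipeline$decomposition != "none") {
    decomp <- stage("decompose", function() {
      d <- decompose_series(panel[[config$target]],
                            config$pipeline$decomposition,
                            config$pipeline$decomp_config)
      readr::write_csv(
        tidyr::pivot_wider(tidy(d), names_from = "component",
                           values_from = "value"),
        file.path(out_dir, "decomposition.csv"), progress = FALSE)
      d
    })
    manifest$n_imfs <- length(decomp$imfs)
  }

  spec <- config$spec
  if (is.null(spec)) {
    tuning <- stage("tune", function() {
      tune_hyperparameters(panel, config$target, config$pso, config$pipeline)
    })
    spec <- tuning$spec
    manifest$tuned <- list(n = spec$n, cells = spec$cells,
                           fitness = tuning$fitness)
    readr::write_csv(tuning$history, file.path(out_dir, "tuning_history.csv"),
                     progress = FALSE)
  } else {
    manifest$tuned <- list(n = spec$n, cells = spec$cells,
                           fitness = NA_real_)
  }

  fc <- stage("forecast", function() {
    forecast_hybrid(panel, config$target, spec, config$pipeline)
  })
  readr::write_csv(tidy(fc)[, c("date", "y_true", "y_pred")],
                   file.path(out_dir, "predictions.csv"), progress = FALSE)

  metrics <- stage("evaluate", function() {
    m <- as.list(fc$metrics)
    jsonlite::write_json(m, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    m
  })
  manifest$metrics <- metrics

  if (!is.null(config$baseline_deaths)) {
    burden <- stage("burden", function() {
      b <- burden_table(panel, config$baseline_deaths,
                        year = max(config$pipeline$test_years))
      readr::write_csv(b, file.path(out_dir, "burden.csv"), progress = FALSE)
      b
    })
  }

  manifest$config <- serialize_config(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

serialize_config <- function(config) {
  list(
    panel_csv = config$panel_csv,
    panel = if (!is.null(config$panel)) {
      list(n_days = config$panel$n_days,
           start_date = format(config$panel$start_date),
           seed = config$panel$seed)
    },
    target = config$target,
    pipeline = unclass(config$pipeline)[
      setdiff(names(config$pipeline), "decomp_config")],
    decomp_config = unclass(config$pipeline$decomp_config),
    baseline_deaths = config$baseline_deaths,
    seed = config$seed
  )
}
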