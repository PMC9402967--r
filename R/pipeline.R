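#' Pipeline configuration
#'
#' Settings for the end-to-end hybrid forecast: decomposition choice,
#' split years, training budgets and the reduced budget used inside the
#' hyperparameter search.
#'
#' @param decomposition `"ceemdan"` (default), `"eemd"`, `"emd"` or
#'   `"none"` (no decomposition; plain CNN-LSTM on the raw series).
#' @param decomp_config A [decomposition_config()].
#' @param covariates Use the other five pollutant series as raw input
#'   channels (default `TRUE`).
#' @param train_years,test_years,validation_fraction Passed to
#'   [split_panel()].
#' @param epochs Training epochs for the final per-component models
#'   (default 60).
#' @param search_epochs Reduced epoch budget inside the swarm search
#'   (default 15).
#' @param fitness_windows During the search, each component model is
#'   trained only on this many most-recent training windows (default 250,
#'   roughly the last eight months of the training period) to keep
#'   fitness evaluations affordable; final models use all rows.
#' @param batch_size,learning_rate Optimizer settings for every component
#'   model.
#' @param decompose_mode `"full"` decomposes the whole series once (the
#'   conventional decomposition-ensemble protocol, which lets test-period
#'   values influence the component shapes); `"strict"` re-decomposes
#'   using only data before each forecast origin (slower, leakage-free).
#' @param seed Master seed for model initialization.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(decomposition = c("ceemdan", "eemd", "emd", "none"),
                            decomp_config = decomposition_config(),
                            covariates = TRUE,
                            train_years = 2016:2020, test_years = 2021,
                            validation_fraction = 0.2,
                            epochs = 60L, search_epochs = 15L,
                            fitness_windows = 250L,
                            batch_size = 32L, learning_rate = 1e-3,
                            decompose_mode = c("full", "strict"),
                            seed = 1L) {
  structure(
    list(
      decomposition = arg_match(decomposition),
      decomp_config = decomp_config,
      covariates = isTRUE(covariates),
      train_years = train_years, test_years = test_years,
      validation_fraction = validation_fraction,
      epochs = as.integer(epochs), search_epochs = as.integer(search_epochs),
      fitness_windows = as.integer(fitness_windows),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      decompose_mode = arg_match(decompose_mode),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# Components of the target series under the configured decomposition:
# a named list of series (imf_0, ..., residue), each the full length.
target_components <- function(series, config) {
  if (config$decomposition == "none") {
    return(list(series = as.numeric(series)))
  }
  dec <- decompose_series(series, config$decomposition, config$decomp_config)
  if (length(dec$imfs) == 0L) {
    warn("decomposition produced no IMFs (near-constant series); using residue only.")
    return(list(residue = dec$residue))
  }
  comps <- c(dec$imfs, list(dec$residue))
  names(comps) <- c(paste0("imf_", seq_along(dec$imfs) - 1L), "residue")
  comps
}

covariate_matrix <- function(panel, target, use_covariates) {
  if (!use_covariates) return(NULL)
  others <- setdiff(POLLUTANTS, target)
  as.matrix(panel[, others, drop = FALSE])
}

# Train one model per component and predict the scaled targets at the
# given window positions; returns per-component predictions in original
# units (matrix rows = positions).  With `train_subset`, the series are
# sliced to the most recent subset of training days (plus the prediction
# range) before windows are built — the reduced-cost protocol used
# inside the swarm search.
fit_and_predict_components <- function(comps, covar, spec, split, config,
                                       predict_rows, train_subset = NULL) {
  scaler_rows <- NULL
  if (!is.null(train_subset)) {
    train_rows <- tail(split$train, train_subset)
    lo <- max(1L, min(train_rows) - spec$n)
    slice <- seq.int(lo, max(predict_rows))
    comps <- lapply(comps, function(x) x[slice])
    if (!is.null(covar)) covar <- covar[slice, , drop = FALSE]
    train_rows <- train_rows - lo + 1L
    predict_rows_local <- predict_rows - lo + 1L
  } else {
    # final models: refit on training + validation rows (the validation
    # partition informs only the hyperparameter selection); the scaler
    # stays fitted on the training rows alone
    train_rows <- c(split$train, split$validation)
    scaler_rows <- split$train
    predict_rows_local <- predict_rows
  }
  pred <- matrix(0, length(predict_rows), length(comps),
                 dimnames = list(NULL, names(comps)))
  fits <- vector("list", length(comps))
  names(fits) <- names(comps)
  for (j in seq_along(comps)) {
    win <- make_windows(comps[[j]], covar, spec$n,
                        train_rows = scaler_rows %||% train_rows)
    comp_spec <- spec
    comp_spec$seed <- spec$seed + 1000L * j
    fit <- cnnlstm_fit(subset_windows(win, window_positions(win, train_rows)),
                       comp_spec)
    pos <- window_positions(win, predict_rows_local)
    if (length(pos) != length(predict_rows)) {
      abort("some requested prediction days have no admissible window.")
    }
    pred[, j] <- inverse_scale_target(
      predict(fit, subset_windows(win, pos)), win
    )
    fits[[j]] <- fit
  }
  list(predictions = pred, fits = fits)
}

#' Tune window length and cell count with particle swarm search
#'
#' Minimizes the validation RMSE of the reconstructed forecast over the
#' integer box `n` in `[1, 20]`, `cells` in `[1, 100]`.  One shared
#' `(n, cells)` pair is selected for all component models.  During the
#' search, component models are trained at the reduced
#' `config$search_epochs` budget on the most recent
#' `config$fitness_windows` training windows; repeated integer positions
#' are looked up from a cache rather than retrained.
#'
#' @param panel Pollutant panel tibble.
#' @param target Pollutant column to forecast (default `"PM25"`).
#' @param pso A [pso_config()]; defaults to a 10-particle, 10-iteration
#'   swarm over [hyperparameter_bounds()].
#' @param config A [pipeline_config()].
#' @return List of class `tuning_result`: `spec` (a
#'   [forecast_model_spec()] with the tuned `n` and `cells`), `fitness`
#'   (validation RMSE of the tuned pair), `history` (swarm convergence
#'   tibble) and `evaluations` (tibble of every distinct pair tried).
#' @export
tune_hyperparameters <- function(panel, target = "PM25",
                                 pso = NULL, config = pipeline_config()) {
  if (is.null(pso)) {
    pso <- pso_config(swarm_size = 10L, iterations = 10L,
                      bounds = hyperparameter_bounds(), seed = config$seed)
  }
  split <- split_panel(panel, config$train_years, config$test_years,
                       config$validation_fraction)
  series <- panel[[target]]
  comps <- target_components(series, config)
  covar <- covariate_matrix(panel, target, config$covariates)
  y_val <- series[split$validation]

  cache <- new.env(parent = emptyenv())
  evals <- new.env(parent = emptyenv())
  evals$tab <- list()
  fitness <- function(position) {
    hp <- encode_hyperparameters(position)
    key <- paste0(hp$n, "_", hp$cells)
    if (!is.null(cache[[key]])) return(cache[[key]])
    spec <- forecast_model_spec(
      n = hp$n, cells = hp$cells, epochs = config$search_epochs,
      batch_size = config$batch_size, learning_rate = config$learning_rate,
      seed = config$seed
    )
    out <- fit_and_predict_components(
      comps, covar, spec, split, config,
      predict_rows = split$validation, train_subset = config$fitness_windows
    )
    val <- rmse(y_val, rowSums(out$predictions))
    cache[[key]] <- val
    evals$tab[[length(evals$tab) + 1L]] <- tibble(
      n = hp$n, cells = hp$cells, fitness = val
    )
    val
  }

  res <- pso_optimize(fitness, pso)
  hp <- encode_hyperparameters(res$par)
  structure(
    list(
      spec = forecast_model_spec(
        n = hp$n, cells = hp$cells, epochs = config$epochs,
        batch_size = config$batch_size, learning_rate = config$learning_rate,
        seed = config$seed
      ),
      fitness = res$value,
      history = res$history,
      evaluations = bind_rows(evals$tab),
      target = target
    ),
    class = "tuning_result"
  )
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result: %s, n=%d, cells=%d, validation RMSE %.4g>\n",
              x$target, x$spec$n, x$spec$cells, x$fitness))
  invisible(x)
}

#' Hybrid decomposition-ensemble forecast of one pollutant
#'
#' The full method: decompose the target series, train one CNN-LSTM per
#' component (each seeing its component plus, optionally, the five raw
#' covariate pollutant series as channels), roll one-step-ahead windows
#' over the test year using observed history, and sum the component
#' predictions into the concentration forecast.  Final component models
#' are fit on the training and validation rows together (the validation
#' partition is only used to select hyperparameters); the min-max scaler
#' is always fitted on the training rows alone.
#'
#' @inheritParams tune_hyperparameters
#' @param spec A [forecast_model_spec()] (typically from
#'   [tune_hyperparameters()]); `NULL` triggers tuning first.
#' @param pso Swarm settings used only when `spec` is `NULL`.
#' @return Object of class `forecast_result`: tibble-friendly fields
#'   `dates`, `y_true`, `y_pred`, per-component prediction matrix
#'   `component_predictions` (summing exactly to `y_pred`), `metrics`
#'   ([metrics_report()] on the test year), `spec`, `config`, `target`.
#' @export
forecast_hybrid <- function(panel, target = "PM25", spec = NULL,
                            config = pipeline_config(), pso = NULL) {
  if (is.null(spec)) {
    spec <- tune_hyperparameters(panel, target, pso, config)$spec
  }
  split <- split_panel(panel, config$train_years, config$test_years,
                       config$validation_fraction)
  series <- panel[[target]]
  covar <- covariate_matrix(panel, target, config$covariates)

  if (config$decompose_mode == "strict" && config$decomposition != "none") {
    return(forecast_hybrid_strict(panel, target, spec, config, split,
                                  series, covar))
  }

  comps <- target_components(series, config)
  out <- fit_and_predict_components(
    comps, covar, spec, split, config, predict_rows = split$test
  )
  build_forecast_result(panel, target, spec, config, split,
                        out$predictions, out$fits)
}

# Strict (leakage-free) variant: models are trained on the decomposition
# of the training+validation period only; each test-day window comes from
# re-decomposing the history up to the forecast origin.  Component counts
# are aligned to the training decomposition (extra modes fold into the
# residue, missing ones contribute zeros).
forecast_hybrid_strict <- function(panel, target, spec, config, split,
                                   series, covar) {
  hist_end <- max(c(split$train, split$validation))
  comps_train <- target_components(series[seq_len(hist_end)], config)
  k <- length(comps_train)
  # fit models on the training-period decomposition
  fits <- vector("list", k)
  scalers <- vector("list", k)
  for (j in seq_len(k)) {
    win <- make_windows(comps_train[[j]],
                        if (is.null(covar)) NULL else covar[seq_len(hist_end), , drop = FALSE],
                        spec$n, train_rows = split$train)
    comp_spec <- spec
    comp_spec$seed <- spec$seed + 1000L * j
    fit_rows <- window_positions(win, c(split$train, split$validation))
    fits[[j]] <- cnnlstm_fit(subset_windows(win, fit_rows), comp_spec)
    scalers[[j]] <- win$scaler
  }
  pred <- matrix(0, length(split$test), k, dimnames = list(NULL, names(comps_train)))
  for (i in seq_along(split$test)) {
    t <- split$test[i]
    dec <- target_components(series[seq_len(t - 1L)], config)
    aligned <- align_components(dec, k)
    for (j in seq_len(k)) {
      comp <- aligned[[j]]
      rows <- seq.int(t - spec$n, t - 1L)
      chan <- cbind(comp[rows],
                    if (is.null(covar)) NULL else covar[rows, , drop = FALSE])
      sc <- scalers[[j]]
      scaled <- scale_minmax(chan, sc)
      X <- array(scaled, c(1L, spec$n, ncol(chan)))
      pred[i, j] <- predict(fits[[j]], list(X = X))[1] * sc$range[1] + sc$min[1]
    }
  }
  build_forecast_result(panel, target, spec, config, split, pred, fits)
}

align_components <- function(comps, k) {
  if (length(comps) == k) return(comps)
  n <- length(comps[[1]])
  if (length(comps) > k) {
    extra <- Reduce(`+`, comps[seq.int(k, length(comps))])
    comps <- c(comps[seq_len(k - 1L)], list(extra))
  } else {
    pad <- rep(list(rep(0, n)), k - length(comps))
    comps <- c(comps[seq_len(length(comps) - 1L)], pad, comps[length(comps)])
  }
  comps
}

build_forecast_result <- function(panel, target, spec, config, split,
                                  predictions, fits) {
  y_true <- panel[[target]][split$test]
  y_pred <- rowSums(predictions)
  structure(
    list(
      dates = panel$date[split$test],
      y_true = y_true, y_pred = y_pred,
      component_predictions = predictions,
      metrics = metrics_report(y_true, y_pred),
      spec = spec, config = config, target = target,
      split = split, fits = fits
    ),
    class = "forecast_result"
  )
}

#' Forecast one pollutant without decomposition and/or covariates
#'
#' The ablation runs: `use_decomposition = FALSE` gives the plain
#' swarm-tuned CNN-LSTM on the raw series; `use_covariates = FALSE` gives
#' the univariate (single-sequence) forecast.
#'
#' @inheritParams forecast_hybrid
#' @param use_decomposition Decompose the target first (default `FALSE`
#'   here).
#' @param use_covariates Include the other five pollutants as channels.
#' @return A `forecast_result`.
#' @export
forecast_single <- function(panel, target = "PM25", spec = NULL,
                            config = pipeline_config(),
                            use_decomposition = FALSE,
                            use_covariates = TRUE, pso = NULL) {
  config$covariates <- isTRUE(use_covariates)
  if (!use_decomposition) config$decomposition <- "none"
  forecast_hybrid(panel, target, spec, config, pso)
}

#' @export
print.forecast_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<forecast_result: %s, %s, %d test days; RMSE %.3f, MAE %.3f, R2 %.3f>\n",
    x$target, x$config$decomposition, length(x$y_pred),
    m$rmse, m$mae, m$r2_conventional))
  invisible(x)
}

#' Per-day tidy view of a forecast
#'
#' @param x A `forecast_result`.
#' @param ... Unused.
#' @return Tibble with `date`, `y_true`, `y_pred` and `residual`.
#' @export
tidy.forecast_result <- function(x, ...) {
  tibble(
    date = x$dates, y_true = x$y_true, y_pred = x$y_pred,
    residual = x$y_true - x$y_pred
  )
}

#' One-row accuracy summary of a forecast
#'
#' @param x A `forecast_result`.
#' @param ... Unused.
#' @return One-row tibble: target, decomposition, n, cells, RMSE, MAE,
#'   both R-squared forms, test size.
#' @export
glance.forecast_result <- function(x, ...) {
  m <- as_tibble(x$metrics)
  m <- rename(m, n_test = "n")
  dplyr::bind_cols(
    tibble(target = x$target, decomposition = x$config$decomposition,
           n = x$spec$n, cells = x$spec$cells),
    m
  )
}
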