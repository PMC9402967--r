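#' Root mean square error
#'
#' `sqrt(mean((y_true - y_pred)^2))`.
#'
#' @param y_true,y_pred Numeric vectors of equal length (n >= 1).
#' @return Scalar RMSE in the units of the inputs.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(25 / 2)
#' @export
rmse <- function(y_true, y_pred) {
  check_paired(y_true, y_pred)
  sqrt(mean((y_true - y_pred)^2))
}

#' Mean absolute error
#'
#' @inheritParams rmse
#' @return Scalar MAE.
#' @export
mae <- function(y_true, y_pred) {
  check_paired(y_true, y_pred)
  mean(abs(y_pred - y_true))
}

check_paired <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort(sprintf("`y_true` (%d) and `y_pred` (%d) must have equal length.",
                  length(y_true), length(y_pred)))
  }
  if (length(y_true) < 1L) abort("need at least one observation.")
  invisible(TRUE)
}

#' Coefficient-of-determination variants
#'
#' Two conventions are in circulation for reporting forecast R-squared.
#' `"conventional"` is `1 - SSE/SST`.  `"ratio"` is the explained-variance
#' ratio `sum((f - mean(y))^2) / sum((y - mean(y))^2)`, which some applied
#' forecasting studies print; the two agree when the predictions are an
#' orthogonal projection of the observations, but the ratio form can
#' exceed 1 for biased forecasts.  Rankings in [comparison_report()] use
#' the conventional form.
#'
#' @inheritParams rmse
#' @param form `"ratio"` or `"conventional"`.
#' @return Scalar R-squared.
#' @export
r2 <- function(y_true, y_pred, form = c("conventional", "ratio")) {
  form <- arg_match(form)
  check_paired(y_true, y_pred)
  ybar <- mean(y_true)
  sst <- sum((y_true - ybar)^2)
  if (sst <= 0) abort("`y_true` is constant; R-squared is undefined (zero denominator).")
  if (form == "ratio") {
    sum((y_pred - ybar)^2) / sst
  } else {
    1 - sum((y_true - y_pred)^2) / sst
  }
}

#' Full accuracy report for one forecast
#'
#' @inheritParams rmse
#' @return One-row tibble of class `metrics_report`: `rmse`, `mae`,
#'   `r2_ratio`, `r2_conventional`, `n`.
#' @export
metrics_report <- function(y_true, y_pred) {
  out <- tibble(
    rmse = rmse(y_true, y_pred),
    mae = mae(y_true, y_pred),
    r2_ratio = r2(y_true, y_pred, "ratio"),
    r2_conventional = r2(y_true, y_pred, "conventional"),
    n = length(y_true)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Percent reduction of an error metric
#'
#' `100 * (before - after) / before`; positive when the second model is
#' better.  Report tables round to 2 decimals, the return value is exact.
#'
#' @param before Reference (baseline) metric, must be > 0.
#' @param after Comparison metric.
#' @return Percent reduction (unrounded scalar).
#' @examples
#' percent_reduction(21.25, 18.65)  # ~12.24
#' @export
percent_reduction <- function(before, after) {
  if (any(before <= 0)) abort("`before` must be > 0.")
  100 * (before - after) / before
}

#' Side-by-side model comparison table
#'
#' Per-model RMSE/MAE/R-squared plus percent error reductions and
#' R-squared gains of every model against a baseline (by default the first
#' entry), the arithmetic used throughout decomposition-ablation and
#' joint-versus-single comparisons.
#'
#' @param results Named list of metric rows (each a [metrics_report()] or
#'   any one-row data frame with `rmse`, `mae` and an R-squared column),
#'   or a tibble with a `model` column and those metric columns.
#' @param baseline Label of the reference model (default: the first).
#' @return Tibble with one row per model, input order preserved, and
#'   columns `model`, `rmse`, `mae`, `r2`, `rmse_reduction_pct`,
#'   `mae_reduction_pct`, `r2_gain` (all reductions relative to
#'   `baseline`; the baseline row shows 0).
#' @export
comparison_report <- function(results, baseline = NULL) {
  if (is.data.frame(results)) {
    tab <- as_tibble(results)
    if (!"model" %in% names(tab)) abort("`results` tibble needs a `model` column.")
  } else {
    if (length(results) < 2L) abort("need at least two models to compare.")
    labels <- names(results)
    if (is.null(labels) || any(labels == "")) abort("`results` must be a fully named list.")
    tab <- purrr::imap(results, function(m, nm) {
      m <- as_tibble(m)
      tibble(
        model = nm, rmse = m$rmse[1], mae = m$mae[1],
        r2 = if ("r2_conventional" %in% names(m)) m$r2_conventional[1] else m$r2[1]
      )
    }) %>% bind_rows()
  }
  if (!"r2" %in% names(tab) && "r2_conventional" %in% names(tab)) {
    tab$r2 <- tab$r2_conventional
  }
  if (anyDuplicated(tab$model)) abort("duplicate model labels in `results`.")
  if (nrow(tab) < 2L) abort("need at least two models to compare.")
  if (is.null(baseline)) baseline <- tab$model[1]
  if (!baseline %in% tab$model) abort(sprintf("baseline '%s' not found.", baseline))
  base <- tab[tab$model == baseline, ]
  tab %>%
    mutate(
      rmse_reduction_pct = percent_reduction(base$rmse, .data$rmse),
      mae_reduction_pct = percent_reduction(base$mae, .data$mae),
      r2_gain = .data$r2 - base$r2
    )
}
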