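#' Chronological train / validation / test split of a panel
#'
#' Splits the rows of a daily panel by calendar year: the test set is the
#' requested test years, and the training-period rows are split
#' chronologically with the last `validation_fraction` (rounded down)
#' held out for validation.  No shuffling anywhere.
#'
#' @param panel Pollutant panel tibble with a `date` column.
#' @param train_years,test_years Integer vectors of calendar years
#'   (defaults 2016--2020 and 2021).
#' @param validation_fraction Fraction of the training-period rows used
#'   for validation (in `(0, 1)`, default 0.2).
#' @return List of class `panel_split` with integer row indices `train`,
#'   `validation`, `test`.
#' @export
split_panel <- function(panel, train_years = 2016:2020, test_years = 2021,
                        validation_fraction = 0.2) {
  if (length(intersect(train_years, test_years))) {
    abort("`train_years` and `test_years` must be disjoint.")
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort("`validation_fraction` must lie in (0, 1).")
  }
  years <- as.integer(format(panel$date, "%Y"))
  missing_years <- setdiff(c(train_years, test_years), unique(years))
  if (length(missing_years)) {
    abort(paste0("panel does not cover year(s): ",
                 paste(missing_years, collapse = ", ")))
  }
  trainval <- which(years %in% train_years)
  test <- which(years %in% test_years)
  n_val <- floor(length(trainval) * validation_fraction)
  n_train <- length(trainval) - n_val
  structure(
    list(
      train = trainval[seq_len(n_train)],
      validation = trainval[seq.int(n_train + 1L, length(trainval))],
      test = test
    ),
    class = "panel_split"
  )
}

# Min-max parameters fitted on a set of rows; degenerate (constant)
# channels get range 1 so scaling stays defined.
fit_scaler <- function(mat, rows) {
  mn <- apply(mat[rows, , drop = FALSE], 2L, min)
  mx <- apply(mat[rows, , drop = FALSE], 2L, max)
  rng <- mx - mn
  rng[rng == 0] <- 1
  list(min = mn, range = rng)
}

scale_minmax <- function(mat, scaler) {
  sweep(sweep(mat, 2L, scaler$min, "-"), 2L, scaler$range, "/")
}

#' Invert the min-max scaling of a windows object
#'
#' @param y Numeric vector on the scaled target scale.
#' @param windows A `supervised_windows` object.
#' @return Vector on the original concentration scale.
#' @export
inverse_scale_target <- function(y, windows) {
  y * windows$scaler$range[1] + windows$scaler$min[1]
}

#' Build supervised one-step-ahead windows
#'
#' For every admissible day `t`, the predictor block `X[t]` holds rows
#' `t - n ... t - 1` of the channel matrix `[component, covariates]` and
#' the target `y[t]` is `component[t]`, so every feature predates its
#' target.  All channels are min-max scaled to `[0, 1]` with parameters
#' fitted on the training rows only (the target shares the component
#' channel's parameters).
#'
#' @param component Numeric vector (the series being forecast, e.g. one
#'   IMF).
#' @param covariates Optional matrix of aligned covariate series (one
#'   column each), e.g. the other five pollutants.
#' @param n Window length in days (>= 1).
#' @param train_rows Integer rows treated as the training partition when
#'   fitting the scaler (default: all rows).
#' @param channel_names Optional channel labels.
#' @return Object of class `supervised_windows`: `X` (array samples x n x
#'   channels, scaled), `y` (scaled targets), `target_index` (the day
#'   index of each `y`), `channel_names`, `scaler` (per-channel min and
#'   range, training rows only).
#' @export
make_windows <- function(component, covariates = NULL, n,
                         train_rows = seq_along(component),
                         channel_names = NULL) {
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be >= 1.")
  len <- length(component)
  if (len < n + 1L) {
    abort(sprintf("series of length %d is too short for windows of length %d.",
                  len, n))
  }
  chan <- cbind(component, covariates)
  if (is.null(channel_names)) {
    channel_names <- c("component",
                       if (!is.null(covariates)) {
                         colnames(covariates) %||%
                           paste0("covariate_", seq_len(ncol(chan) - 1L))
                       })
  }
  colnames(chan) <- channel_names
  if (nrow(chan) != len) abort("`covariates` must be aligned with `component`.")
  scaler <- fit_scaler(chan, train_rows)
  scaled <- scale_minmax(chan, scaler)
  targets <- seq.int(n + 1L, len)
  X <- array(0, c(length(targets), n, ncol(chan)),
             dimnames = list(NULL, NULL, channel_names))
  for (i in seq_along(targets)) {
    t <- targets[i]
    X[i, , ] <- scaled[(t - n):(t - 1L), ]
  }
  structure(
    list(
      X = X, y = scaled[targets, 1L], target_index = targets,
      channel_names = channel_names, scaler = scaler
    ),
    class = "supervised_windows"
  )
}

#' @export
print.supervised_windows <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<supervised_windows: %d samples x %d days x %d channel(s)>\n",
              d[1], d[2], d[3]))
  invisible(x)
}

# Subset a windows object by positions of its samples.
subset_windows <- function(windows, idx) {
  out <- windows
  out$X <- windows$X[idx, , , drop = FALSE]
  out$y <- windows$y[idx]
  out$target_index <- windows$target_index[idx]
  out
}

# Positions of the window samples whose target day falls in `rows`.
window_positions <- function(windows, rows) {
  which(windows$target_index %in% rows)
}

#' Naive persistence forecast
#'
#' The no-skill floor: predicts each day with the previous day's observed
#' value.
#'
#' @param series Numeric vector of observations.
#' @param test_rows Integer indices to forecast (all > 1).
#' @return Numeric vector `series[test_rows - 1]`.
#' @export
persistence_forecast <- function(series, test_rows) {
  if (any(test_rows < 2L)) abort("persistence needs a preceding observation.")
  series[test_rows - 1L]
}
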