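#' Component forecaster specification
#'
#' Hyperparameters of the CNN-LSTM that forecasts one decomposition
#' component one day ahead.  The swarm search tunes `n` and `cells`; the
#' architecture around them is fixed: one valid 1-D convolution layer with
#' ReLU, one non-overlapping max pool (size 2 when the convolved window
#' still has at least two rows, else 1), one LSTM layer and a linear unit.
#'
#' @param n Window length in days (1--20).
#' @param cells LSTM hidden units (1--100).
#' @param conv_filters Convolution filters (default 16).
#' @param kernel_size Convolution kernel length (default 2; reduced to `n`
#'   automatically when `n` is shorter).
#' @param pool_size Max-pool width, or `NULL` to choose 2/1 from the
#'   window length.
#' @param epochs Training epochs (default 60).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return List of class `forecast_model_spec`.
#' @export
forecast_model_spec <- function(n = 4L, cells = 32L, conv_filters = 16L,
                                kernel_size = 2L, pool_size = NULL,
                                epochs = 60L, batch_size = 32L,
                                learning_rate = 1e-3, seed = 1L) {
  n <- as.integer(n)
  cells <- as.integer(cells)
  if (n < 1L || n > 20L) abort("`n` must lie in [1, 20].")
  if (cells < 1L || cells > 100L) abort("`cells` must lie in [1, 100].")
  kernel_size <- min(as.integer(kernel_size), n)
  conv_len <- n - kernel_size + 1L
  if (is.null(pool_size)) pool_size <- if (conv_len >= 2L) 2L else 1L
  pool_size <- as.integer(pool_size)
  if (pool_size < 1L) abort("`pool_size` must be >= 1.")
  if (ceiling(conv_len / pool_size) < 1L) abort("pool output length must be >= 1.")
  structure(
    list(
      n = n, cells = cells, conv_filters = as.integer(conv_filters),
      kernel_size = kernel_size, pool_size = pool_size,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, seed = as.integer(seed)
    ),
    class = "forecast_model_spec"
  )
}

#' @export
print.forecast_model_spec <- function(x, ...) {
  cat(sprintf(
    "<forecast_model_spec: n=%d, cells=%d, %d filters (k=%d, pool=%d), %d epochs>\n",
    x$n, x$cells, x$conv_filters, x$kernel_size, x$pool_size, x$epochs))
  invisible(x)
}

#' 1-D convolution forward pass
#'
#' Valid (no padding) cross-correlation of a multichannel window with a
#' bank of kernels, plus bias and activation:
#' `out[t, j] = act(sum_{a,c} window[t + a - 1, c] * kernels[a, c, j] + biases[j])`.
#'
#' @param window Numeric matrix, window length by channels.
#' @param kernels Numeric array `kernel_size x channels x filters`.
#' @param biases Numeric vector, one per filter.
#' @param activation `"relu"` or `"linear"`.
#' @return Matrix `(window length - kernel_size + 1) x filters`.
#' @examples
#' w <- matrix(1:4, ncol = 1)
#' conv1d_forward(w, array(c(1, -1), c(2, 1, 1)), 0)  # finite difference
#' @export
conv1d_forward <- function(window, kernels, biases,
                           activation = c("relu", "linear")) {
  activation <- arg_match(activation)
  if (!is.matrix(window)) window <- matrix(window, ncol = 1L)
  if (length(dim(kernels)) != 3L) {
    abort("`kernels` must be a 3-d array (kernel_size x channels x filters).")
  }
  k <- dim(kernels)[1]
  if (dim(kernels)[2] != ncol(window)) {
    abort(sprintf("channel mismatch: window has %d channels, kernels expect %d.",
                  ncol(window), dim(kernels)[2]))
  }
  if (k > nrow(window)) {
    abort(sprintf("kernel size %d exceeds window length %d.", k, nrow(window)))
  }
  n_out <- nrow(window) - k + 1L
  filters <- dim(kernels)[3]
  out <- matrix(0, n_out, filters)
  for (j in seq_len(filters)) {
    for (t in seq_len(n_out)) {
      out[t, j] <- sum(window[t:(t + k - 1L), , drop = FALSE] * kernels[, , j]) +
        biases[j]
    }
  }
  if (activation == "relu") out <- pmax(out, 0)
  out
}

#' Non-overlapping max pooling over time
#'
#' @param feature_map Matrix, time by filters (vectors are treated as one
#'   filter).
#' @param pool_size Window width (>= 1); a trailing partial window is
#'   pooled as-is.
#' @return Pooled matrix with `ceiling(nrow / pool_size)` rows.
#' @export
max_pool <- function(feature_map, pool_size) {
  if (pool_size < 1L) abort("`pool_size` must be >= 1.")
  if (!is.matrix(feature_map)) feature_map <- matrix(feature_map, ncol = 1L)
  n <- nrow(feature_map)
  starts <- seq(1L, n, by = pool_size)
  out <- matrix(0, length(starts), ncol(feature_map))
  for (i in seq_along(starts)) {
    rows <- starts[i]:min(starts[i] + pool_size - 1L, n)
    out[i, ] <- apply(feature_map[rows, , drop = FALSE], 2L, max)
  }
  out
}

#' One LSTM cell update
#'
#' Single step of the gated recurrence used by the component forecaster:
#' \deqn{i_t = \sigma(W_{hi} h_{t-1} + W_{xi} x_t + b_i)}
#' \deqn{f_t = \sigma(W_{hf} h_{t-1} + W_{xf} x_t + b_f)}
#' \deqn{c_t = f_t \odot c_{t-1} + i_t \odot \tanh(W_{xc} x_t + W_{hc} h_{t-1} + b_c)}
#' \deqn{o_t = \sigma(W_{xo} x_t + W_{ho} h_{t-1} + W_{co} c_t + b_o)}
#' \deqn{h_t = o_t \odot \tanh(c_t)}
#'
#' @param x_t Input vector (features).
#' @param state List with numeric vectors `c` and `h` (length `cells`).
#' @param weights List with matrices `W_hi`, `W_xi`, `W_hf`, `W_xf`,
#'   `W_xc`, `W_hc`, `W_xo`, `W_ho`, `W_co` (each `cells x cells` or
#'   `cells x features`) and bias vectors `b_i`, `b_f`, `b_c`, `b_o`.
#' @return List with the new `state` (fields `c`, `h`) and `output`
#'   (`= h`).
#' @export
lstm_cell_step <- function(x_t, state, weights) {
  w <- weights
  h <- state$h
  cc <- state$c
  cells <- length(h)
  dims_ok <- function(mat, rows, cols) {
    is.matrix(mat) && nrow(mat) == rows && ncol(mat) == cols
  }
  fx <- length(x_t)
  for (nm in c("W_hi", "W_hf", "W_hc", "W_ho", "W_co")) {
    if (!dims_ok(w[[nm]], cells, cells)) {
      abort(sprintf("weight %s must be %d x %d.", nm, cells, cells))
    }
  }
  for (nm in c("W_xi", "W_xf", "W_xc", "W_xo")) {
    if (!dims_ok(w[[nm]], cells, fx)) {
      abort(sprintf("weight %s must be %d x %d (got %dx%d).",
                    nm, cells, fx, NROW(w[[nm]]), NCOL(w[[nm]])))
    }
  }
  sig <- function(z) 1 / (1 + exp(-z))
  i_t <- sig(drop(w$W_hi %*% h + w$W_xi %*% x_t) + w$b_i)
  f_t <- sig(drop(w$W_hf %*% h + w$W_xf %*% x_t) + w$b_f)
  c_t <- f_t * cc + i_t * tanh(drop(w$W_xc %*% x_t + w$W_hc %*% h) + w$b_c)
  o_t <- sig(drop(w$W_xo %*% x_t + w$W_ho %*% h + w$W_co %*% c_t) + w$b_o)
  h_t <- o_t * tanh(c_t)
  list(state = list(c = c_t, h = h_t), output = h_t)
}

# Internal parameter container passed to the C++ engine.
params_layout <- function(spec, channels) {
  list(
    dims = list(
      kernel_size = spec$kernel_size, channels = as.integer(channels),
      filters = spec$conv_filters, cells = spec$cells,
      pool_size = spec$pool_size
    )
  )
}

#' Train the CNN-LSTM component forecaster
#'
#' Minimizes mean squared one-step-ahead error with Adam on the supervised
#' windows; reproducible under a fixed seed and single-threaded BLAS.
#'
#' @param windows A `supervised_windows` object from [make_windows()], or
#'   a list with array `X` (samples x window x channels) and vector `y`.
#' @param spec A [forecast_model_spec()].
#' @param validation Optional windows held out for a per-epoch validation
#'   loss (list/`supervised_windows` with `X`, `y`).
#' @return Object of class `cnnlstm_fit`: `params` (C++ layout),
#'   `spec`, `channels`, `loss` (tibble `epoch`, `train_loss`,
#'   `val_loss`).
#' @export
cnnlstm_fit <- function(windows, spec = forecast_model_spec(),
                        validation = NULL) {
  X <- windows$X
  y <- windows$y
  if (length(dim(X)) != 3L) abort("`windows$X` must be a 3-d array.")
  if (dim(X)[1] != length(y)) abort("sample count mismatch between X and y.")
  if (dim(X)[2] != spec$n) {
    abort(sprintf("window length %d does not match spec n = %d.",
                  dim(X)[2], spec$n))
  }
  if (dim(X)[1] < 1L) abort("need at least one training sample.")
  channels <- dim(X)[3]
  par <- cnnlstm_init_cpp(spec$kernel_size, channels, spec$conv_filters,
                          spec$cells, spec$pool_size, spec$seed)
  Xv <- NULL
  yv <- NULL
  if (!is.null(validation)) {
    Xv <- validation$X
    yv <- validation$y
  }
  fitted <- cnnlstm_fit_cpp(X, y, par, spec$epochs, spec$batch_size,
                            spec$learning_rate, spec$seed, Xv, yv)
  loss <- tibble(
    epoch = seq_len(spec$epochs),
    train_loss = as.numeric(fitted$train_loss),
    val_loss = if (!is.null(fitted$val_loss)) as.numeric(fitted$val_loss) else NA_real_
  )
  structure(
    list(
      params = list(dims = fitted$dims, weights = fitted$weights),
      spec = spec, channels = channels, loss = loss
    ),
    class = "cnnlstm_fit"
  )
}

#' @export
print.cnnlstm_fit <- function(x, ...) {
  cat(sprintf(
    "<cnnlstm_fit: n=%d, cells=%d, %d channel(s); final train MSE %.4g>\n",
    x$spec$n, x$spec$cells, x$channels, tail(x$loss$train_loss, 1)))
  invisible(x)
}

#' Predict one-step-ahead values from a fitted component forecaster
#'
#' @param object A `cnnlstm_fit`.
#' @param newdata A `supervised_windows` object or list with array `X`
#'   whose channel count matches training.
#' @param ... Unused.
#' @return Numeric vector, one prediction per window row (on the scaled
#'   training scale; see [make_windows()] for inverse scaling).
#' @export
predict.cnnlstm_fit <- function(object, newdata, ...) {
  X <- if (is.list(newdata) && !is.null(newdata$X)) newdata$X else newdata
  if (length(dim(X)) != 3L) abort("`newdata` must contain a 3-d window array X.")
  if (dim(X)[3] != object$channels) {
    abort(sprintf("channel mismatch: model trained on %d channel(s), got %d.",
                  object$channels, dim(X)[3]))
  }
  as.numeric(cnnlstm_predict_cpp(X, object$params))
}

#' Extract network weights in the operator convention
#'
#' Returns the fitted weights shaped for the exported operators
#' ([conv1d_forward()], [lstm_cell_step()]), so a forward pass can be
#' recomposed outside the training engine: conv kernels as a
#' `kernel_size x channels x filters` array, LSTM matrices as
#' `cells x features` / `cells x cells`, and the dense head.
#'
#' @param fit A `cnnlstm_fit`.
#' @return List with `kernels`, `conv_biases`, `lstm` (weights list for
#'   [lstm_cell_step()]), `dense_w`, `dense_b`, `pool_size`.
#' @export
model_weights <- function(fit) {
  w <- fit$params$weights
  d <- fit$params$dims
  kernels <- array(w$Wc, c(d$kernel_size, d$channels, d$filters))
  list(
    kernels = kernels,
    conv_biases = as.numeric(w$bc),
    lstm = list(
      W_xi = t(w$Wxi), W_xf = t(w$Wxf), W_xc = t(w$Wxc), W_xo = t(w$Wxo),
      W_hi = t(w$Whi), W_hf = t(w$Whf), W_hc = t(w$Whc), W_ho = t(w$Who),
      W_co = t(w$Wco),
      b_i = as.numeric(w$bi), b_f = as.numeric(w$bf),
      b_c = as.numeric(w$bg), b_o = as.numeric(w$bo)
    ),
    dense_w = as.numeric(w$wd),
    dense_b = as.numeric(w$bd),
    pool_size = d$pool_size
  )
}

#' One-row training summary of a fitted component forecaster
#'
#' @param x A `cnnlstm_fit`.
#' @param ... Unused.
#' @return Tibble with the hyperparameters and first/final training loss.
#' @export
glance.cnnlstm_fit <- function(x, ...) {
  tibble(
    n = x$spec$n, cells = x$spec$cells, channels = x$channels,
    epochs = x$spec$epochs,
    first_train_loss = x$loss$train_loss[1],
    final_train_loss = tail(x$loss$train_loss, 1)
  )
}

#' Save / load a fitted component forecaster as JSON
#'
#' The model directory layout is a single JSON file holding the
#' hyperparameter spec, channel count and all weight matrices (stored as
#' flat numeric vectors with dimensions), so saved models are plain text.
#'
#' @param fit A `cnnlstm_fit`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
save_cnnlstm <- function(fit, path) {
  payload <- list(
    spec = unclass(fit$spec),
    channels = fit$channels,
    dims = fit$params$dims,
    weights = purrr::map(fit$params$weights, function(m) {
      list(dim = dim(as.matrix(m)), data = as.numeric(m))
    }),
    loss = as.list(fit$loss)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cnnlstm
#' @export
read_cnnlstm <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- purrr::map(payload$weights, function(w) {
    matrix(w$data, nrow = w$dim[1], ncol = w$dim[2])
  })
  spec <- do.call(forecast_model_spec, payload$spec[
    c("n", "cells", "conv_filters", "kernel_size", "pool_size",
      "epochs", "batch_size", "learning_rate", "seed")
  ])
  structure(
    list(
      params = list(dims = as.list(payload$dims), weights = weights),
      spec = spec, channels = payload$channels,
      loss = as_tibble(payload$loss)
    ),
    class = "cnnlstm_fit"
  )
}
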