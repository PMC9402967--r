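test_that("conv1d with an identity kernel reproduces ReLU of the input", {
  w <- matrix(c(-1, 2, -3, 4), ncol = 1)
  out <- conv1d_forward(w, array(1, c(1, 1, 1)), 0)
  expect_equal(out, matrix(pmax(w, 0), ncol = 1))
})

test_that("a difference kernel on a ramp is constant and dies under ReLU", {
  w <- matrix(1:4, ncol = 1)
  pre <- conv1d_forward(w, array(c(1, -1), c(2, 1, 1)), 0, activation = "linear")
  expect_equal(as.numeric(pre), rep(-1, 3))
  post <- conv1d_forward(w, array(c(1, -1), c(2, 1, 1)), 0)
  expect_equal(as.numeric(post), rep(0, 3))
})

test_that("conv1d matches a nested-loop oracle on random multichannel input", {
  set.seed(31)
  w <- matrix(rnorm(8 * 3), 8, 3)
  k <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  b <- rnorm(4)
  got <- conv1d_forward(w, k, b, activation = "linear")
  want <- matrix(0, 7, 4)
  for (j in 1:4) {
    for (t in 1:7) {
      acc <- b[j]
      for (a in 1:2) {
        for (ch in 1:3) acc <- acc + w[t + a - 1, ch] * k[a, ch, j]
      }
      want[t, j] <- acc
    }
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("max pooling behaves on the canonical cases", {
  expect_equal(as.numeric(max_pool(c(1, 3, 2, 5), 2)), c(3, 5))
  x <- matrix(rnorm(10 * 3), 10, 3)
  expect_equal(max_pool(x, 1), x)
  expect_equal(max(max_pool(x, 4)), max(x))            # max conservation
  expect_equal(nrow(max_pool(x, 4)), 3L)               # trailing partial window
})

test_that("an all-zero LSTM cell gives half-open gates and zero state", {
  cells <- 3
  z <- matrix(0, cells, cells)
  zx <- matrix(0, cells, 2)
  w <- list(W_hi = z, W_xi = zx, W_hf = z, W_xf = zx, W_xc = zx, W_hc = z,
            W_xo = zx, W_ho = z, W_co = z,
            b_i = rep(0, cells), b_f = rep(0, cells),
            b_c = rep(0, cells), b_o = rep(0, cells))
  st <- list(c = rep(0, cells), h = rep(0, cells))
  out <- lstm_cell_step(c(1, -1), st, w)
  expect_equal(out$state$c, rep(0, cells))
  expect_equal(out$state$h, rep(0, cells))
  expect_equal(out$output, rep(0, cells))
})

test_that("a scalar LSTM cell matches the hand-evaluated gate equations", {
  # one cell, one input feature, hand-picked weights
  w <- list(
    W_hi = matrix(0.5), W_xi = matrix(-0.3),
    W_hf = matrix(0.2), W_xf = matrix(0.7),
    W_xc = matrix(1.1), W_hc = matrix(-0.4),
    W_xo = matrix(0.6), W_ho = matrix(-0.2), W_co = matrix(0.9),
    b_i = 0.1, b_f = -0.2, b_c = 0.05, b_o = 0.3
  )
  h0 <- 0.25
  c0 <- -0.5
  x <- 0.8
  i_t <- sigm(0.5 * h0 + (-0.3) * x + 0.1)
  f_t <- sigm(0.2 * h0 + 0.7 * x - 0.2)
  c_t <- f_t * c0 + i_t * tanh(1.1 * x + (-0.4) * h0 + 0.05)
  o_t <- sigm(0.6 * x + (-0.2) * h0 + 0.9 * c_t + 0.3)
  h_t <- o_t * tanh(c_t)
  out <- lstm_cell_step(x, list(c = c0, h = h0), w)
  expect_equal(out$state$c, c_t, tolerance = 1e-12)
  expect_equal(out$state$h, h_t, tolerance = 1e-12)
})

test_that("hidden states stay strictly inside (-1, 1)", {
  set.seed(77)
  cells <- 4
  w <- list(
    W_hi = matrix(rnorm(16, sd = 2), 4), W_xi = matrix(rnorm(8, sd = 2), 4),
    W_hf = matrix(rnorm(16, sd = 2), 4), W_xf = matrix(rnorm(8, sd = 2), 4),
    W_xc = matrix(rnorm(8, sd = 2), 4), W_hc = matrix(rnorm(16, sd = 2), 4),
    W_xo = matrix(rnorm(8, sd = 2), 4), W_ho = matrix(rnorm(16, sd = 2), 4),
    W_co = matrix(rnorm(16, sd = 2), 4),
    b_i = rnorm(4), b_f = rnorm(4), b_c = rnorm(4), b_o = rnorm(4)
  )
  st <- list(c = rep(0, cells), h = rep(0, cells))
  for (k in 1:20) {
    st <- lstm_cell_step(rnorm(2, sd = 5), st, w)$state
    expect_true(all(abs(st$h) < 1))
  }
})

test_that("shape mismatches are reported with dimensions", {
  w <- list(W_hi = matrix(0.5), W_xi = matrix(-0.3))
  expect_error(
    lstm_cell_step(c(1, 2), list(c = 0, h = 0),
                   c(w, list(W_hf = matrix(1), W_xf = matrix(1),
                             W_xc = matrix(1), W_hc = matrix(1),
                             W_xo = matrix(1), W_ho = matrix(1),
                             W_co = matrix(1),
                             b_i = 0, b_f = 0, b_c = 0, b_o = 0))),
    "W_xi"
  )
  expect_error(conv1d_forward(matrix(1:4, ncol = 1), array(1, c(1, 2, 1)), 0),
               "channel")
})

test_that("training fits a constant target to within 0.01", {
  series <- rep(5, 200)
  w <- make_windows(series, NULL, 4)
  spec <- forecast_model_spec(n = 4, cells = 8, epochs = 30, seed = 2)
  fit <- cnnlstm_fit(w, spec)
  pred <- inverse_scale_target(predict(fit, w), w)
  expect_lt(max(abs(pred - 5)), 1e-2)
})

test_that("a noiseless sinusoid component is learned well and loss decreases", {
  tt <- 1:800
  comp <- sin(2 * pi * tt / 50)
  w <- make_windows(comp, NULL, 4, train_rows = 1:600)
  tr <- which(w$target_index <= 600)
  te <- which(w$target_index > 600)
  spec <- forecast_model_spec(n = 4, cells = 32, epochs = 60, seed = 1)
  fit <- cnnlstm_fit(list(X = w$X[tr, , , drop = FALSE], y = w$y[tr]), spec)
  pred <- inverse_scale_target(predict(fit, list(X = w$X[te, , , drop = FALSE])), w)
  expect_lt(rmse(comp[w$target_index[te]], pred), 0.1)  # < 10% of amplitude
  expect_lte(tail(fit$loss$train_loss, 1), fit$loss$train_loss[1])
})

test_that("training is reproducible and inference deterministic", {
  tt <- 1:300
  comp <- sin(2 * pi * tt / 40) + 0.1 * cos(2 * pi * tt / 7)
  w <- make_windows(comp, NULL, 5)
  spec <- forecast_model_spec(n = 5, cells = 12, epochs = 10, seed = 9)
  f1 <- cnnlstm_fit(w, spec)
  f2 <- cnnlstm_fit(w, spec)
  expect_identical(f1$loss$train_loss, f2$loss$train_loss)
  p1 <- predict(f1, w)
  expect_identical(p1, predict(f1, w))
  # batch-of-one equals the row of batch-of-many
  one <- predict(f1, list(X = w$X[3, , , drop = FALSE]))
  expect_equal(one, p1[3], tolerance = 1e-12)
})

test_that("predict rejects a channel mismatch", {
  w <- make_windows(sin(1:100), NULL, 4)
  fit <- cnnlstm_fit(w, forecast_model_spec(n = 4, cells = 4, epochs = 2, seed = 1))
  bad <- array(0, c(2, 4, 3))
  expect_error(predict(fit, list(X = bad)), "channel")
})

test_that("the trained network equals the composition of the exported operators", {
  tt <- 1:400
  comp <- sin(2 * pi * tt / 60) + 0.2 * sin(2 * pi * tt / 11)
  cov <- cbind(a = cos(2 * pi * tt / 90), b = sin(2 * pi * tt / 30))
  w <- make_windows(comp, cov, 6)
  spec <- forecast_model_spec(n = 6, cells = 10, epochs = 5, seed = 3)
  fit <- cnnlstm_fit(w, spec)
  preds <- predict(fit, w)
  for (i in c(1, 7, 50)) {
    expect_equal(compose_forward(fit, w$X[i, , ]), preds[i], tolerance = 1e-8)
  }
})

test_that("models survive a JSON save/load round trip", {
  w <- make_windows(sin(1:150), NULL, 3)
  fit <- cnnlstm_fit(w, forecast_model_spec(n = 3, cells = 5, epochs = 3, seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  save_cnnlstm(fit, path)
  back <- read_cnnlstm(path)
  expect_equal(predict(back, w), predict(fit, w), tolerance = 1e-12)
})
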