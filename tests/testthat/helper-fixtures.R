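# Shared fixtures and independent oracles, built in code at test time.

# A short panel whose calendar spans 2016-2018 so splits can use small
# year ranges and pipeline tests stay fast.
quick_panel <- function(n_days = 3 * 365, seed = 7) {
  generate_panel(panel_spec(n_days = n_days, seed = seed))
}

quick_split_args <- list(train_years = 2016:2017, test_years = 2018)

# Brute-force interior extrema scan, independent of find_extrema().
scan_extrema <- function(x) {
  n <- length(x)
  maxima <- integer()
  minima <- integer()
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) maxima <- c(maxima, i)
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) minima <- c(minima, i)
  }
  list(maxima = maxima, minima = minima)
}

# Minimal independent EMD used only as a cross-check oracle: one mirrored
# extremum per end, fmm splines, a fixed number of sift passes.
# Deliberately a different implementation path from the package (which
# mirrors two extrema, uses natural splines and an SD stopping rule).
oracle_emd <- function(x, n_sift = 10, max_imfs = 8) {
  env_mean <- function(h) {
    n <- length(h)
    ext <- scan_extrema(h)
    ma <- ext$maxima
    mi <- ext$minima
    if (length(ma) < 2 || length(mi) < 2) return(NULL)
    up <- stats::spline(c(2 - ma[1], ma, 2 * n - ma[length(ma)]),
                        c(h[ma[1]], h[ma], h[ma[length(ma)]]), xout = 1:n)$y
    lo <- stats::spline(c(2 - mi[1], mi, 2 * n - mi[length(mi)]),
                        c(h[mi[1]], h[mi], h[mi[length(mi)]]), xout = 1:n)$y
    (up + lo) / 2
  }
  residue <- x
  imfs <- list()
  while (length(imfs) < max_imfs) {
    h <- residue
    ok <- TRUE
    for (s in seq_len(n_sift)) {
      m <- env_mean(h)
      if (is.null(m)) {
        ok <- s > 1
        break
      }
      h <- h - m
    }
    if (!ok || is.null(env_mean(residue))) break
    imfs[[length(imfs) + 1]] <- h
    residue <- residue - h
  }
  list(imfs = imfs, residue = residue)
}

# Two-tone fixture with frequency ratio 10 used across decomposition tests.
two_tone <- function(n = 2000) generate_tone_signal(c(0.05, 0.005), c(1, 1), n)

# Scalar sigmoid for hand computations.
sigm <- function(z) 1 / (1 + exp(-z))

# Compose the exported operators into a full forward pass on one window;
# the independent route checked against predict().
compose_forward <- function(fit, window_matrix) {
  mw <- model_weights(fit)
  fm <- conv1d_forward(window_matrix, mw$kernels, mw$conv_biases)
  pm <- max_pool(fm, mw$pool_size)
  state <- list(c = rep(0, fit$spec$cells), h = rep(0, fit$spec$cells))
  for (i in seq_len(nrow(pm))) {
    step <- lstm_cell_step(pm[i, ], state, mw$lstm)
    state <- step$state
  }
  sum(mw$dense_w * state$h) + mw$dense_b
}
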