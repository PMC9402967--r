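test_that("find_extrema handles the canonical small cases", {
  ext <- find_extrema(c(0, 1, 0, -1, 0))
  expect_equal(ext$maxima, 2L)
  expect_equal(ext$minima, 4L)
  ramp <- find_extrema(1:50)
  expect_length(ramp$maxima, 0)
  expect_length(ramp$minima, 0)
  flat <- find_extrema(rep(3, 10))
  expect_length(flat$maxima, 0)
  expect_length(flat$minima, 0)
  expect_error(find_extrema(c(1, 2)), "length")
})

test_that("find_extrema matches a brute-force scan on a multi-cycle sine", {
  tt <- 0:999
  x <- sin(2 * pi * 5 * tt / 1000)
  got <- find_extrema(x)
  want <- scan_extrema(x)
  expect_equal(got$maxima, want$maxima)
  expect_equal(got$minima, want$minima)
  expect_length(got$maxima, 5)
  expect_length(got$minima, 5)
})

test_that("plateau extrema are reported at their midpoint", {
  x <- c(0, 1, 2, 2, 2, 1, 0, -1, -1, 0)
  ext <- find_extrema(x)
  expect_equal(ext$maxima, 4L)   # plateau 3..5
  expect_equal(ext$minima, 8L)   # plateau 8..9 -> floor midpoint
})

test_that("envelopes bracket the signal at extrema and average out a sinusoid", {
  tt <- 0:999
  x <- sin(2 * pi * 8 * tt / 1000)
  env <- compute_envelopes(x)
  ext <- find_extrema(x)
  expect_true(all(env$upper[ext$maxima] >= x[ext$maxima] - 1e-10))
  expect_true(all(env$lower[ext$minima] <= x[ext$minima] + 1e-10))
  interior <- 101:900
  expect_lt(max(abs(env$mean[interior])), 0.05)
})

test_that("a constant offset shifts the envelope mean by that constant", {
  tt <- 0:499
  x <- sin(2 * pi * 6 * tt / 500)
  base <- compute_envelopes(x)
  shifted <- compute_envelopes(x + 5)
  expect_equal(shifted$mean, base$mean + 5, tolerance = 1e-6)
})

test_that("too few extrema signals residue instead of erroring", {
  expect_null(compute_envelopes(1:100))
  expect_null(compute_envelopes(exp(seq(0, 1, length.out = 50))))
})

test_that("sifting a pure tone is a near fixed point that satisfies the IMF criterion", {
  tt <- 0:1999
  x <- sin(2 * pi * 0.02 * tt)
  h <- sift(x)
  expect_lt(sqrt(sum((h - x)^2) / sum(x^2)), 1e-3)
  expect_true(is_imf(h))
})

test_that("sifting a two-tone sum extracts the fast tone first", {
  s <- two_tone()
  h <- sift(s$signal)
  expect_gt(cor(h, s$components[, 1]), 0.95)
})

test_that("emd of a constant returns no IMFs and the input as residue", {
  x <- rep(4.2, 50)
  d <- emd(x)
  expect_length(d$imfs, 0)
  expect_equal(d$residue, x)
})

test_that("emd separates a frequency-ratio-10 two-tone signal", {
  s <- two_tone()
  d <- emd(s$signal)
  expect_gte(length(d$imfs), 2)
  expect_gt(abs(cor(d$imfs[[1]], s$components[, 1])), 0.95)
  expect_gt(abs(cor(d$imfs[[2]], s$components[, 2])), 0.95)
})

test_that("emd reconstruction is exact and modes slow down with index", {
  s <- two_tone()
  d <- emd(s$signal)
  rel <- sqrt(sum((reconstruct(d) - s$signal)^2) / sum(s$signal^2))
  expect_lt(rel, 1e-8)
  zc <- vapply(d$imfs, count_zero_crossings, integer(1))
  expect_true(all(diff(zc) <= 0))
})

test_that("emd components agree with an independently coded sifting oracle", {
  s <- two_tone(1500)
  mine <- emd(s$signal)
  ref <- oracle_emd(s$signal)
  k <- min(2, length(mine$imfs), length(ref$imfs))
  expect_gte(k, 2)
  for (j in seq_len(k)) {
    expect_gt(abs(cor(mine$imfs[[j]], ref$imfs[[j]])), 0.9)
  }
})

test_that("ceemdan reconstructs exactly for any seed and is deterministic", {
  s <- two_tone(600)
  cfg <- decomposition_config(ensemble_size = 16, seed = 11)
  d1 <- ceemdan(s$signal, cfg)
  d2 <- ceemdan(s$signal, cfg)
  expect_identical(d1$imfs, d2$imfs)
  expect_equal(max(abs(reconstruct(d1) - s$signal)), 0, tolerance = 1e-12)
  d3 <- ceemdan(s$signal, decomposition_config(ensemble_size = 16, seed = 99))
  expect_equal(max(abs(reconstruct(d3) - s$signal)), 0, tolerance = 1e-12)
})

test_that("ceemdan approaches plain emd as the noise amplitude shrinks", {
  s <- two_tone(500)
  ref <- emd(s$signal)
  dist_for <- function(ns) {
    d <- ceemdan(s$signal, decomposition_config(ensemble_size = 2, noise_scale = ns,
                                                seed = 4))
    k <- min(length(d$imfs), length(ref$imfs))
    sqrt(sum((d$imfs[[1]] - ref$imfs[[1]])^2)) / sqrt(sum(ref$imfs[[1]]^2))
  }
  d_big <- dist_for(0.4)
  d_small <- dist_for(0.01)
  expect_lt(d_small, d_big)
  expect_lt(d_small, 0.05)
})

test_that("paired noise requires an even ensemble", {
  expect_error(decomposition_config(ensemble_size = 5), "even")
  expect_silent(decomposition_config(ensemble_size = 5, paired_noise = FALSE))
})

test_that("eemd is deterministic, reports its reconstruction error, and keeps IMF shape", {
  s <- two_tone(500)
  cfg <- decomposition_config(ensemble_size = 8, seed = 2)
  d1 <- eemd(s$signal, cfg)
  d2 <- eemd(s$signal, cfg)
  expect_identical(d1$imfs, d2$imfs)
  expect_true(is.finite(d1$reconstruction_error))
  rel <- sqrt(sum((reconstruct(d1) - s$signal)^2) / sum(s$signal^2))
  expect_equal(rel, d1$reconstruction_error, tolerance = 1e-12)
  # added white noise occupies the highest-frequency modes, so the fast
  # tone is recovered by one of the leading IMFs rather than IMF1 itself
  cors <- vapply(d1$imfs, function(m) abs(cor(m, s$components[, 1])), numeric(1))
  expect_gt(max(cors), 0.9)
})

test_that("decompose_series dispatches and 'none' passes the signal through", {
  x <- two_tone(300)$signal
  d <- decompose_series(x, "none")
  expect_length(d$imfs, 0)
  expect_equal(d$residue, x)
  expect_equal(decompose_series(x, "emd")$method, "emd")
})

test_that("tidy and glance views of a decomposition are well formed", {
  d <- emd(two_tone(400)$signal)
  td <- tidy(d)
  expect_equal(nrow(td), 400 * (length(d$imfs) + 1))
  expect_equal(levels(td$component)[1], "imf_0")
  g <- glance(d)
  expect_equal(g$n_imfs, length(d$imfs))
})
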