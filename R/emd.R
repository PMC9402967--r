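#' Decomposition configuration
#'
#' Settings shared by [emd()], [eemd()] and [ceemdan()].
#'
#' @param max_imfs Maximum number of intrinsic mode functions to extract
#'   (`Inf` = until the residue is monotone).
#' @param max_sift_iterations Cap on sifting iterations per mode (default
#'   50).
#' @param sd_threshold Cauchy-type stopping threshold for sifting: stop when
#'   `sum((h_prev - h)^2) / sum(h_prev^2)` falls below it (default 0.2).
#' @param ensemble_size Number of noise realizations for the ensemble
#'   variants (default 100; must be even when `paired_noise`).
#' @param noise_scale Noise amplitude as a fraction of the standard
#'   deviation of the series being decomposed (default 0.2; in `(0, 1)`).
#' @param paired_noise Use each white-noise draw with both + and - signs so
#'   noise cancels exactly in ensemble means (default `TRUE`).
#' @param adaptive_noise Rescale the noise at every stage by the standard
#'   deviation of the current residue (default `TRUE`); `FALSE` keeps the
#'   stage-1 amplitude throughout.
#' @param seed Integer seed for the noise draws.
#' @return List of class `decomposition_config`.
#' @export
decomposition_config <- function(max_imfs = Inf,
                                 max_sift_iterations = 50L,
                                 sd_threshold = 0.2,
                                 ensemble_size = 100L,
                                 noise_scale = 0.2,
                                 paired_noise = TRUE,
                                 adaptive_noise = TRUE,
                                 seed = 1L) {
  if (sd_threshold <= 0) abort("`sd_threshold` must be > 0.")
  if (ensemble_size < 2) abort("`ensemble_size` must be >= 2.")
  if (paired_noise && ensemble_size %% 2L != 0L) {
    abort("`ensemble_size` must be even when `paired_noise` is TRUE.")
  }
  if (noise_scale <= 0 || noise_scale >= 1) abort("`noise_scale` must lie in (0, 1).")
  structure(
    list(
      max_imfs = max_imfs, max_sift_iterations = as.integer(max_sift_iterations),
      sd_threshold = sd_threshold, ensemble_size = as.integer(ensemble_size),
      noise_scale = noise_scale, paired_noise = isTRUE(paired_noise),
      adaptive_noise = isTRUE(adaptive_noise), seed = as.integer(seed)
    ),
    class = "decomposition_config"
  )
}

#' Locate strict local extrema
#'
#' Interior local maxima and minima of a series; a plateau (run of equal
#' values higher/lower than both neighbours) contributes its midpoint
#' index.  Endpoints are never returned; boundary behaviour is handled by
#' mirroring inside [compute_envelopes()].
#'
#' @param signal Numeric vector of length >= 3.
#' @return List with integer vectors `maxima` and `minima` (both empty for
#'   a constant signal).
#' @examples
#' find_extrema(c(0, 1, 0, -1, 0))
#' @export
find_extrema <- function(signal) {
  n <- length(signal)
  if (n < 3L) abort("`signal` must have length >= 3.")
  s <- sign(diff(signal))
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(maxima = integer(), minima = integer()))
  s_nz <- s[nz]
  change <- which(diff(s_nz) != 0)
  if (!length(change)) return(list(maxima = integer(), minima = integer()))
  i1 <- nz[change]        # last slope sample before the turn
  i2 <- nz[change + 1L]   # first slope sample after the turn
  # the extremum plateau spans samples (i1 + 1) .. i2; take its midpoint
  pos <- (i1 + 1L + i2) %/% 2L
  is_max <- s_nz[change] > 0
  list(maxima = pos[is_max], minima = pos[!is_max])
}

#' Cubic-spline envelopes of a signal
#'
#' Upper and lower envelopes through the local extrema, with the two
#' nearest extrema mirrored about each endpoint before fitting a natural
#' cubic spline, and their pointwise mean.
#'
#' @param signal Numeric vector.
#' @param maxima,minima Extrema indices as returned by [find_extrema()];
#'   found automatically when omitted.
#' @return List with numeric vectors `upper`, `lower`, `mean`, or `NULL`
#'   when fewer than two maxima or two minima exist (the caller treats the
#'   signal as a residue).
#' @export
compute_envelopes <- function(signal, maxima = NULL, minima = NULL) {
  if (is.null(maxima) || is.null(minima)) {
    ext <- find_extrema(signal)
    maxima <- ext$maxima
    minima <- ext$minima
  }
  if (length(maxima) < 2L || length(minima) < 2L) return(NULL)
  n <- length(signal)
  upper <- mirrored_spline(signal, maxima, n)
  lower <- mirrored_spline(signal, minima, n)
  list(upper = upper, lower = lower, mean = (upper + lower) / 2)
}

# Natural cubic spline through extrema, extended by mirroring the two
# nearest extrema about each endpoint (standard EMD boundary remedy).
mirrored_spline <- function(signal, idx, n) {
  l <- utils::head(idx, 2L)  # two extrema nearest the left endpoint
  r <- utils::tail(idx, 2L)  # two nearest the right endpoint
  xs <- c(2L - rev(l), idx, 2L * n - rev(r))
  ys <- c(signal[rev(l)], signal[idx], signal[rev(r)])
  keep <- !duplicated(xs)
  stats::spline(xs[keep], ys[keep], xout = seq_len(n), method = "natural")$y
}

#' Extract one intrinsic-mode-function candidate by sifting
#'
#' Repeatedly subtracts the mean of the upper and lower spline envelopes
#' until the Cauchy SD criterion drops below `sd_threshold` *and* the
#' candidate satisfies the mode-shape condition
#' `|#extrema - #zero-crossings| <= 1` (the SD rule alone is only a
#' proxy for it), or until the iteration cap is reached.
#'
#' @param signal Non-constant numeric vector.
#' @param config A [decomposition_config()].
#' @return Numeric vector (the candidate), with attribute `iterations`.
#'   Returns `NULL` when the signal has too few extrema to sift (residue).
#' @export
sift <- function(signal, config = decomposition_config()) {
  h <- signal
  iter <- 0L
  repeat {
    env <- compute_envelopes(h)
    if (is.null(env)) {
      if (iter == 0L) return(NULL)
      break
    }
    h_new <- h - env$mean
    iter <- iter + 1L
    sd_crit <- sum((h - h_new)^2) / sum(h^2)
    h <- h_new
    if (iter >= config$max_sift_iterations || !is.finite(sd_crit)) break
    if (sd_crit < config$sd_threshold && is_imf(h)) break
  }
  attr(h, "iterations") <- iter
  h
}

new_imf_set <- function(imfs, residue, method, config = NULL,
                        reconstruction_error = 0) {
  structure(
    list(
      imfs = imfs, residue = residue, source_length = length(residue),
      method = method, config = config,
      reconstruction_error = reconstruction_error
    ),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set: %s, %d IMF(s) + residue, length %d>\n",
              x$method, length(x$imfs), x$source_length))
  invisible(x)
}

#' Reconstruct the signal from an IMF set
#'
#' @param x An `imf_set`.
#' @return Numeric vector: the sum of all IMFs and the residue.
#' @export
reconstruct <- function(x) {
  stopifnot(inherits(x, "imf_set"))
  out <- x$residue
  for (imf in x$imfs) out <- out + imf
  out
}

#' Empirical mode decomposition
#'
#' Splits a series into intrinsic mode functions (highest frequency first)
#' plus a monotone-or-flat residue by repeated sifting.  The components sum
#' back to the input exactly up to accumulation rounding.
#'
#' @param signal Numeric vector, length >= 10.
#' @param config A [decomposition_config()].
#' @return An `imf_set` with fields `imfs` (list of numeric vectors),
#'   `residue`, `source_length`, `method`.
#' @examples
#' s <- generate_tone_signal(c(0.05, 0.005), c(1, 1), 1000)
#' d <- emd(s$signal)
#' length(d$imfs)
#' @export
emd <- function(signal, config = decomposition_config()) {
  if (length(signal) < 10L) abort("`signal` must have length >= 10.")
  residue <- as.numeric(signal)
  imfs <- list()
  while (length(imfs) < config$max_imfs) {
    ext <- find_extrema(residue)
    if (length(ext$maxima) < 2L || length(ext$minima) < 2L) break
    imf <- sift(residue, config)
    if (is.null(imf)) break
    attributes(imf) <- NULL
    imfs[[length(imfs) + 1L]] <- imf
    residue <- residue - imf
  }
  new_imf_set(imfs, residue, "emd", config)
}

# White-noise realizations for the ensemble variants: a list of vectors;
# with paired noise each base draw appears with both signs, adjacently.
draw_noise_ensemble <- function(n, config) {
  restore <- set_local_seed(config$seed)
  on.exit(restore(), add = TRUE)
  n_draws <- if (config$paired_noise) config$ensemble_size %/% 2L else config$ensemble_size
  draws <- lapply(seq_len(n_draws), function(i) rnorm(n))
  if (config$paired_noise) {
    draws <- unlist(lapply(draws, function(w) list(w, -w)), recursive = FALSE)
  }
  draws
}

# Extra sifting applied to an ensemble-mean mode: averaging first modes
# over noise realizations does not preserve the IMF shape property, so
# each CEEMDAN mode is polished until it satisfies it (the correction is
# absorbed into the next-stage residue, keeping reconstruction exact).
polish_to_imf <- function(h, config) {
  for (i in seq_len(config$max_sift_iterations)) {
    if (is_imf(h)) break
    env <- compute_envelopes(h)
    if (is.null(env)) break
    h <- h - env$mean
  }
  h
}

# First EMD mode of a series; zero vector when nothing can be extracted
# (keeps ensemble means well-defined near the end of a decomposition).
first_mode <- function(x, config) {
  ext <- find_extrema(x)
  if (length(ext$maxima) < 2L || length(ext$minima) < 2L) return(rep(0, length(x)))
  imf <- sift(x, config)
  if (is.null(imf)) return(rep(0, length(x)))
  attributes(imf) <- NULL
  imf
}

#' Complete ensemble EMD with adaptive noise (CEEMDAN)
#'
#' Stage-wise noise-assisted decomposition: the k-th mode is the ensemble
#' mean, over white-noise realizations, of the first EMD mode of the
#' current residue plus scaled noise; the residue is updated by
#' subtraction, so the components reconstruct the input to machine
#' precision by construction.  At stage k the injected noise is the k-th
#' EMD mode of each white-noise realization (stage 1 uses the raw noise),
#' scaled by `noise_scale` times the standard deviation of the current
#' residue (`adaptive_noise = TRUE`) or of the input.  With
#' `paired_noise = TRUE` every draw enters with both + and - signs.
#'
#' @inheritParams emd
#' @return An `imf_set` with `method = "ceemdan"`.
#' @export
ceemdan <- function(signal, config = decomposition_config()) {
  if (length(signal) < 10L) abort("`signal` must have length >= 10.")
  x <- as.numeric(signal)
  n <- length(x)
  noise <- draw_noise_ensemble(n, config)
  # EMD modes of each noise realization, used as stage-k injections
  noise_modes <- lapply(noise, function(w) emd(w, config)$imfs)

  residue <- x
  imfs <- list()
  sd0 <- sd(x)
  while (length(imfs) < config$max_imfs) {
    ext <- find_extrema(residue)
    if (length(ext$maxima) < 2L || length(ext$minima) < 2L) break
    k <- length(imfs) + 1L
    eps <- config$noise_scale * if (config$adaptive_noise) sd(residue) else sd0
    if (!is.finite(eps) || eps <= 0) eps <- 0
    mode_sum <- numeric(n)
    for (i in seq_along(noise)) {
      w_k <- if (k == 1L) {
        noise[[i]]
      } else if (k - 1L <= length(noise_modes[[i]])) {
        noise_modes[[i]][[k - 1L]]
      } else {
        NULL
      }
      perturbed <- if (is.null(w_k) || eps == 0) residue else residue + eps * w_k
      mode_sum <- mode_sum + first_mode(perturbed, config)
    }
    imf <- mode_sum / length(noise)
    if (all(abs(imf) < .Machine$double.eps * 10)) break
    imf <- polish_to_imf(imf, config)
    imfs[[k]] <- imf
    residue <- residue - imf
  }
  new_imf_set(imfs, residue, "ceemdan", config)
}

#' Ensemble EMD (EEMD)
#'
#' Fully decomposes every noise-added copy of the signal with [emd()] and
#' averages the modes index-by-index (realizations lacking a mode
#' contribute zeros); the residue is the ensemble mean of residues.
#' Reconstruction is not exact in general; the achieved error is stored in
#' `reconstruction_error` (relative L2).
#'
#' @inheritParams emd
#' @return An `imf_set` with `method = "eemd"`.
#' @export
eemd <- function(signal, config = decomposition_config()) {
  if (length(signal) < 10L) abort("`signal` must have length >= 10.")
  x <- as.numeric(signal)
  n <- length(x)
  noise <- draw_noise_ensemble(n, config)
  eps <- config$noise_scale * sd(x)
  decomps <- lapply(noise, function(w) emd(x + eps * w, config))
  k_max <- max(vapply(decomps, function(d) length(d$imfs), integer(1)))
  m <- length(decomps)
  imfs <- lapply(seq_len(k_max), function(k) {
    acc <- numeric(n)
    for (d in decomps) if (k <= length(d$imfs)) acc <- acc + d$imfs[[k]]
    acc / m
  })
  residue <- Reduce(`+`, lapply(decomps, `[[`, "residue")) / m
  total <- residue
  for (imf in imfs) total <- total + imf
  rel_err <- sqrt(sum((total - x)^2) / max(sum(x^2), .Machine$double.eps))
  new_imf_set(imfs, residue, "eemd", config, reconstruction_error = rel_err)
}

#' Decompose a series with a chosen method
#'
#' Dispatcher used by the forecasting pipeline and the command-line tool.
#'
#' @param signal Numeric vector.
#' @param method `"ceemdan"`, `"eemd"`, `"emd"` or `"none"` (returns the
#'   signal as a single pseudo-component).
#' @param config A [decomposition_config()].
#' @return An `imf_set`.
#' @export
decompose_series <- function(signal, method = c("ceemdan", "eemd", "emd", "none"),
                             config = decomposition_config()) {
  method <- arg_match(method)
  switch(method,
    ceemdan = ceemdan(signal, config),
    eemd = eemd(signal, config),
    emd = emd(signal, config),
    none = new_imf_set(list(), as.numeric(signal), "none", config)
  )
}

#' Count zero crossings of a series
#'
#' Sign changes between consecutive non-zero samples; used for the IMF
#' criterion `|#extrema - #zero-crossings| <= 1`.
#'
#' @param x Numeric vector.
#' @return Integer count.
#' @export
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Check the intrinsic-mode-function criterion
#'
#' @param x Numeric vector (a candidate mode).
#' @return `TRUE` when the number of interior extrema and the number of
#'   zero crossings differ by at most one.
#' @export
is_imf <- function(x) {
  ext <- find_extrema(x)
  n_ext <- length(ext$maxima) + length(ext$minima)
  abs(n_ext - count_zero_crossings(x)) <= 1L
}

#' Tidy an IMF set into a long tibble
#'
#' @param x An `imf_set`.
#' @param ... Unused.
#' @return Tibble with columns `component` (`imf_0`, ..., `residue`),
#'   `t` and `value`.
#' @export
tidy.imf_set <- function(x, ...) {
  comps <- c(x$imfs, list(x$residue))
  names(comps) <- c(paste0("imf_", seq_along(x$imfs) - 1L), "residue")
  purrr::imap(comps, function(v, nm) {
    tibble(component = nm, t = seq_along(v), value = v)
  }) %>%
    bind_rows() %>%
    mutate(component = factor(.data$component, levels = names(comps)))
}

#' One-row summary of an IMF set
#'
#' @param x An `imf_set`.
#' @param ... Unused.
#' @return One-row tibble: method, number of IMFs, source length and
#'   relative reconstruction error.
#' @export
glance.imf_set <- function(x, ...) {
  tibble(
    method = x$method,
    n_imfs = length(x$imfs),
    source_length = x$source_length,
    reconstruction_error = x$reconstruction_error
  )
}
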