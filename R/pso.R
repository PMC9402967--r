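#' Particle swarm optimizer configuration
#'
#' @param swarm_size Number of particles (default 20).
#' @param iterations Number of velocity/position updates (default 30).
#' @param inertia Inertia weight omega in `(0, 1]` (default 0.8).
#' @param c1,c2 Cognitive and social acceleration coefficients (default 2).
#' @param bounds Numeric matrix with one row per dimension and columns
#'   `low`, `high` (`low < high`).
#' @param velocity_clamp Maximum absolute velocity as a fraction of each
#'   dimension's range (default 0.5).
#' @param seed Integer seed.
#' @param legacy_update Use the textbook-divergent printed update (minus
#'   sign on the first stochastic term, pbest/gbest roles swapped) instead
#'   of the canonical Kennedy--Eberhart form.  For comparison only.
#' @return List of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 20L, iterations = 30L, inertia = 0.8,
                       c1 = 2, c2 = 2, bounds, velocity_clamp = 0.5,
                       seed = 1L, legacy_update = FALSE) {
  if (missing(bounds) || is.null(bounds) || !is.matrix(bounds) || ncol(bounds) != 2L ||
      nrow(bounds) < 1L) {
    abort("`bounds` must be a matrix with one row per dimension and columns low, high.")
  }
  if (any(bounds[, 1] >= bounds[, 2])) abort("each bound must satisfy low < high.")
  if (inertia <= 0 || inertia > 1) abort("`inertia` must lie in (0, 1].")
  if (c1 <= 0 || c2 <= 0) abort("`c1` and `c2` must be > 0.")
  structure(
    list(
      swarm_size = as.integer(swarm_size), iterations = as.integer(iterations),
      inertia = inertia, c1 = c1, c2 = c2, bounds = bounds,
      velocity_clamp = velocity_clamp, seed = as.integer(seed),
      legacy_update = isTRUE(legacy_update)
    ),
    class = "pso_config"
  )
}

#' Initialize a particle swarm
#'
#' Positions drawn uniformly inside the bounds, zero velocities, personal
#' bests at the initial (evaluated) positions.
#'
#' @param fitness_fn Function taking a numeric position vector and
#'   returning a scalar fitness (lower is better).  Non-finite values are
#'   treated as `+Inf`.
#' @param config A [pso_config()].
#' @return A `pso_swarm` list: `position`, `velocity` (matrices, particles
#'   by dimensions), `pbest`, `pbest_fit`, `gbest`, `gbest_fit`.
#' @export
pso_init <- function(fitness_fn, config) {
  d <- nrow(config$bounds)
  s <- config$swarm_size
  lo <- config$bounds[, 1]
  hi <- config$bounds[, 2]
  position <- matrix(runif(s * d, rep(lo, each = s), rep(hi, each = s)), s, d)
  velocity <- matrix(0, s, d)
  fit <- apply(position, 1L, function(p) safe_fitness(fitness_fn, p))
  best <- which.min(fit)
  structure(
    list(
      position = position, velocity = velocity,
      pbest = position, pbest_fit = fit,
      gbest = position[best, ], gbest_fit = fit[best]
    ),
    class = "pso_swarm"
  )
}

safe_fitness <- function(fitness_fn, p) {
  val <- tryCatch(fitness_fn(p), error = function(e) {
    warn(paste0("fitness evaluation failed (", conditionMessage(e),
                "); particle marked invalid"))
    Inf
  })
  if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
    if (!identical(val, Inf)) {
      inform("non-finite fitness; particle marked invalid (+Inf)")
    }
    val <- Inf
  }
  val
}

#' Advance a particle swarm by one step
#'
#' Canonical update `V <- w V + c1 r1 (pbest - x) + c2 r2 (gbest - x)`,
#' `x <- x + V`, with positions clipped to the bounds and velocities to
#' `velocity_clamp` times each dimension's range.  Bests are replaced only
#' on strict improvement (ties keep the incumbent).
#'
#' @param swarm A `pso_swarm` from [pso_init()].
#' @inheritParams pso_init
#' @return The updated `pso_swarm`.
#' @export
pso_step <- function(swarm, fitness_fn, config) {
  d <- nrow(config$bounds)
  s <- config$swarm_size
  lo <- config$bounds[, 1]
  hi <- config$bounds[, 2]
  vmax <- config$velocity_clamp * (hi - lo)
  r1 <- matrix(runif(s * d), s, d)
  r2 <- matrix(runif(s * d), s, d)
  gb <- matrix(swarm$gbest, s, d, byrow = TRUE)
  if (config$legacy_update) {
    # printed form: minus on the global-best term, roles swapped
    v <- config$inertia * swarm$velocity -
      config$c1 * r1 * (gb - swarm$position) +
      config$c2 * r2 * (swarm$pbest - swarm$position)
  } else {
    v <- config$inertia * swarm$velocity +
      config$c1 * r1 * (swarm$pbest - swarm$position) +
      config$c2 * r2 * (gb - swarm$position)
  }
  v <- pmin(pmax(v, matrix(-vmax, s, d, byrow = TRUE)),
            matrix(vmax, s, d, byrow = TRUE))
  x <- swarm$position + v
  x <- pmin(pmax(x, matrix(lo, s, d, byrow = TRUE)),
            matrix(hi, s, d, byrow = TRUE))
  fit <- apply(x, 1L, function(p) safe_fitness(fitness_fn, p))
  improved <- fit < swarm$pbest_fit
  swarm$pbest[improved, ] <- x[improved, , drop = FALSE]
  swarm$pbest_fit[improved] <- fit[improved]
  swarm$position <- x
  swarm$velocity <- v
  best <- which.min(swarm$pbest_fit)
  if (swarm$pbest_fit[best] < swarm$gbest_fit) {
    swarm$gbest <- swarm$pbest[best, ]
    swarm$gbest_fit <- swarm$pbest_fit[best]
  }
  swarm
}

#' Minimize a fitness function with particle swarm optimization
#'
#' @inheritParams pso_init
#' @return List of class `pso_result`: `par` (best position), `value`
#'   (best fitness), `history` (tibble `iteration`, `best_fitness`;
#'   iteration 0 is the initial evaluation) and the final `swarm`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' cfg <- pso_config(bounds = cbind(c(-5, -5), c(5, 5)), seed = 1)
#' res <- pso_optimize(sphere, cfg)
#' res$value
#' @export
pso_optimize <- function(fitness_fn, config) {
  if (config$iterations < 1L) abort("`iterations` must be >= 1.")
  restore <- set_local_seed(config$seed)
  on.exit(restore(), add = TRUE)
  swarm <- pso_init(fitness_fn, config)
  history <- numeric(config$iterations + 1L)
  history[1] <- swarm$gbest_fit
  for (it in seq_len(config$iterations)) {
    swarm <- pso_step(swarm, fitness_fn, config)
    history[it + 1L] <- swarm$gbest_fit
  }
  structure(
    list(
      par = swarm$gbest, value = swarm$gbest_fit,
      history = tibble(iteration = 0:config$iterations, best_fitness = history),
      swarm = swarm
    ),
    class = "pso_result"
  )
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("<pso_result: best fitness %.6g at (%s)>\n", x$value,
              paste(signif(x$par, 6), collapse = ", ")))
  invisible(x)
}

#' Tidy the convergence history of a PSO run
#'
#' @param x A `pso_result`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `best_fitness`.
#' @export
tidy.pso_result <- function(x, ...) x$history

#' Decode a continuous PSO position into forecaster hyperparameters
#'
#' Rounds to the nearest integer and clips to the search box used for the
#' forecaster: window length `n` in `[1, 20]` and LSTM `cells` in
#' `[1, 100]`.
#'
#' @param position Numeric vector `(n, cells)`.
#' @return Named list with integers `n` and `cells`.
#' @examples
#' encode_hyperparameters(c(3.6, 41.2))
#' @export
encode_hyperparameters <- function(position) {
  stopifnot(length(position) == 2L)
  list(
    n = as.integer(min(20L, max(1L, round(position[1])))),
    cells = as.integer(min(100L, max(1L, round(position[2]))))
  )
}

#' Default PSO search box for the forecaster hyperparameters
#'
#' @return 2 x 2 bounds matrix: window length 1--20, cells 1--100.
#' @export
hyperparameter_bounds <- function() {
  matrix(c(1, 1, 20, 100), nrow = 2L,
         dimnames = list(c("n", "cells"), c("low", "high")))
}
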