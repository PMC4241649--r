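# Iteration of the stochastic difference equation X[t+1] = f(X[t], xi[t]) X[t],
# trajectory containers, occupation measures, run classification, and the
# ensemble protocols behind the persistence-curve and scatter experiments.

CLAMP_ZERO <- 1e-300   # densities below this underflow to the absorbing state 0

check_fitness_ <- function(fx, x, xi) {
  bad <- is.nan(fx) | fx < 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "fitness evaluated to %s at density x=%.6g, environment (%s)",
      if (is.nan(fx[i])) "NaN" else "a negative value",
      x[i],
      paste(colnames(xi), signif(xi[min(i, nrow(xi)), ], 6),
            sep = "=", collapse = ", ")), call. = FALSE)
  }
}

#' Simulate one trajectory of the stochastic difference equation
#'
#' Iterates \eqn{X_{t+1} = f(X_t, \xi_t) X_t} for `T` steps from `x0` with
#' i.i.d. environment draws. Zero is absorbing; densities that underflow
#' below `1e-300` are clamped to zero (the number of clamped steps is
#' recorded), and a trajectory that overflows to `Inf` stays there.
#'
#' @param model a `fitness_model`.
#' @param x0 initial density (>= 0).
#' @param T number of time steps (>= 1).
#' @param seed integer seed (ignored when `env_draws` is supplied).
#' @param record_env keep the environment draws in the result.
#' @param env_draws optional matrix of environment states (rows = steps) to
#'   drive the recursion with, e.g. for common-random-number comparisons or
#'   replay; overrides `seed`.
#' @return An object of class `trajectory`: list with `x0`, `densities`
#'   (length `T + 1`, `densities[1] == x0`), `T`, `seed`, `model_id`,
#'   optional `env_draws`, and `n_clamped`.
#' @examples
#' m <- build_model("ricker", params = list(a = 1),
#'                  env = list(r = env_dist("point_mass", value = log(2))))
#' iterate(m, x0 = 1, T = 3, seed = 1)$densities  # 1 2 4 8 (f constant = 2)
#' @export
iterate <- function(model, x0, T, seed = 1, record_env = FALSE,
                    env_draws = NULL) {
  stopifnot(x0 >= 0, T >= 1)
  if (is.null(env_draws)) {
    env_draws <- sample_env(model$env, T, seed)
  } else {
    env_draws <- as.matrix(env_draws)
    if (nrow(env_draws) < T) stop("env_draws has fewer than T rows")
  }
  dens <- numeric(T + 1)
  dens[1] <- x0
  x <- x0
  n_clamped <- 0L
  for (t in seq_len(T)) {
    if (x == 0 || is.infinite(x)) {
      dens[t + 1] <- x
      next
    }
    xi <- env_draws[t, , drop = FALSE]
    fx <- model$eval(x, xi)
    check_fitness_(fx, x, xi)
    x <- fx * x
    if (is.nan(x)) x <- Inf    # Inf * 0-fitness corner: treat as explosion
    if (x < CLAMP_ZERO && x > 0) { x <- 0; n_clamped <- n_clamped + 1L }
    dens[t + 1] <- x
  }
  structure(list(x0 = x0, densities = dens, T = T, seed = seed,
                 model_id = model$model_id,
                 env_draws = if (record_env) env_draws[seq_len(T), , drop = FALSE],
                 n_clamped = n_clamped),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s: x0=%.4g, T=%d, final=%.4g>\n",
              x$model_id, x$x0, x$T, x$densities[x$T + 1]))
  invisible(x)
}

# Vectorized ensemble: n replicate trajectories evolved in lock-step, each
# with independent noise. Replicates are absorbed at 0 and Inf. Internal
# workhorse for the curve / scatter / probe protocols; called inside an
# RNG context positioned by the caller (with_seed / with_stream).
simulate_ensemble_ <- function(model, x0, T, n_reps,
                               keep_paths = FALSE, track_min = FALSE,
                               track_range = FALSE) {
  if (track_range) track_min <- TRUE
  x <- if (length(x0) == 1L) rep.int(x0, n_reps) else {
    stopifnot(length(x0) == n_reps); as.numeric(x0)
  }
  paths <- if (keep_paths) {
    p <- matrix(NA_real_, T + 1, n_reps); p[1, ] <- x; p
  }
  mins <- if (track_min) x
  maxs <- if (track_range) x
  for (t in seq_len(T)) {
    alive <- which(x > 0 & is.finite(x))
    if (length(alive)) {
      xi <- sample_env_raw_(model$env, length(alive))
      fx <- model$eval(x[alive], xi)
      check_fitness_(fx, x[alive], xi)
      xn <- fx * x[alive]
      xn[is.nan(xn)] <- Inf
      xn[xn < CLAMP_ZERO & xn > 0] <- 0
      x[alive] <- xn
    }
    if (keep_paths) paths[t + 1, ] <- x
    if (track_min) mins <- pmin(mins, x)
    if (track_range) maxs <- pmax(maxs, x)
  }
  list(final = x, paths = paths, mins = mins, maxs = maxs)
}

#' Simulate an ensemble of replicate trajectories
#'
#' Evolves `n_reps` trajectories in lock-step, each with independent noise,
#' absorbing replicates at 0 and at `Inf`. This is the vectorized engine
#' behind [persistence_curve()] and the scatter experiments; it is exposed
#' for ensemble summaries that only need final densities or path extremes
#' (keeping full paths for long horizons is memory-hungry).
#'
#' @param model a `fitness_model`.
#' @param x0 initial density: a scalar (shared by all replicates) or a
#'   vector of length `n_reps`.
#' @param T number of time steps.
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param keep_paths also return the full `(T+1) x n_reps` density matrix.
#' @param track_min also return each replicate's running minimum.
#' @param track_range also return running minima and maxima.
#' @return list with `final` (length `n_reps`) and, when requested,
#'   `paths`, `mins`, `maxs`.
#' @export
simulate_ensemble <- function(model, x0, T, n_reps, seed,
                              keep_paths = FALSE, track_min = FALSE,
                              track_range = FALSE) {
  with_seed(seed, simulate_ensemble_(model, x0, T, n_reps,
                                     keep_paths = keep_paths,
                                     track_min = track_min,
                                     track_range = track_range))
}

#' Empirical occupation measure of a trajectory
#'
#' The fraction of time the population spends in each density interval —
#' the binned finite-time analogue of the process's empirical measures.
#'
#' @param traj a `trajectory`.
#' @param bin_edges strictly increasing breakpoints; an overflow bin
#'   `[max(bin_edges), Inf)` is appended if the trajectory exceeds the last
#'   edge, and a `[0, bin_edges[1])` bin is prepended if needed.
#' @return Object of class `empirical_measure`: `bin_edges` (possibly
#'   extended), `weights` (sum to 1), and `t` (number of time points).
#' @export
empirical_measure <- function(traj, bin_edges) {
  stopifnot(inherits(traj, "trajectory"), all(diff(bin_edges) > 0))
  d <- traj$densities
  if (min(d) < bin_edges[1]) bin_edges <- c(min(0, min(d)), bin_edges)
  if (max(d) >= bin_edges[length(bin_edges)]) bin_edges <- c(bin_edges, Inf)
  idx <- findInterval(d, bin_edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  structure(list(bin_edges = bin_edges,
                 weights = counts / length(d),
                 t = length(d)),
            class = "empirical_measure")
}

#' @export
print.empirical_measure <- function(x, ...) {
  cat(sprintf("<empirical_measure over %d time points, %d bins>\n",
              x$t, length(x$weights)))
  invisible(x)
}

#' Classify the outcome of a finite run
#'
#' Finite-horizon proxy for the asymptotic limits \eqn{X_t \to 0} /
#' \eqn{X_t \to \infty}: the verdict is read off the final density alone,
#' mirroring the "final density" protocol of the persistence-curve
#' experiment.
#'
#' @param traj a `trajectory`, or a numeric vector of final densities.
#' @param delta_ext extinction cutoff (default `1e-8`).
#' @param M_big explosion cutoff (default `1e8`).
#' @return For a trajectory, an object of class `run_classification`
#'   (`verdict` in EXTINCT / EXPLODED / INTERIOR plus the thresholds); for
#'   a numeric vector, a factor of verdicts.
#' @export
classify_run <- function(traj, delta_ext = 1e-8, M_big = 1e8) {
  stopifnot(delta_ext > 0, M_big > delta_ext)
  finals <- if (inherits(traj, "trajectory"))
    traj$densities[traj$T + 1] else as.numeric(traj)
  v <- ifelse(finals < delta_ext, "EXTINCT",
              ifelse(finals > M_big, "EXPLODED", "INTERIOR"))
  v <- factor(v, levels = c("EXTINCT", "INTERIOR", "EXPLODED"))
  if (inherits(traj, "trajectory"))
    structure(list(verdict = as.character(v),
                   thresholds = c(delta_ext = delta_ext, M_big = M_big)),
              class = "run_classification")
  else v
}

#' Persistence probability as a function of initial density
#'
#' For each initial density, runs `n_reps` independent trajectories and
#' reports the fraction whose *final* density exceeds `threshold`, with a
#' Clopper-Pearson binomial confidence interval. Replicate ensembles use
#' independent RNG substreams spawned deterministically from `seed`.
#'
#' @param model a `fitness_model`.
#' @param x0_grid initial densities.
#' @param T horizon (time steps).
#' @param n_reps replicates per initial density.
#' @param threshold persistence cutoff on the final density.
#' @param seed integer seed.
#' @param conf confidence level for the interval (default 0.95).
#' @return data.frame with columns `x0`, `phat`, `lo`, `hi`, `n_reps`.
#' @export
persistence_curve <- function(model, x0_grid, T, n_reps, threshold, seed,
                              conf = 0.95) {
  stopifnot(n_reps >= 1, threshold > 0)
  streams <- rng_substreams(seed, length(x0_grid))
  rows <- lapply(seq_along(x0_grid), function(i) {
    fin <- with_stream(streams[[i]],
                       simulate_ensemble_(model, x0_grid[i], T, n_reps))$final
    k <- sum(fin > threshold)
    ci <- stats::binom.test(k, n_reps, conf.level = conf)$conf.int
    data.frame(x0 = x0_grid[i], phat = k / n_reps, lo = ci[1], hi = ci[2],
               n_reps = n_reps)
  })
  do.call(rbind, rows)
}

#' Final-points scatter over a parameter grid
#'
#' For each value of a scanned parameter and each initial density, one
#' trajectory of length `T` is simulated and its last `n_keep` densities
#' are emitted — the asymptotic-dynamics scatter protocol (a stochastic
#' bifurcation-style diagram).
#'
#' @param model_family function mapping a parameter value to a
#'   `fitness_model`.
#' @param param_grid numeric vector of scanned parameter values.
#' @param x0_set initial densities (default: geometric grid of 8 points on
#'   `[1e-2, 10]`).
#' @param T trajectory length.
#' @param n_keep number of final points kept per trajectory (`<= T`).
#' @param seed integer seed.
#' @return Tidy data.frame with columns `param`, `x0`, `t`, `density`
#'   (one row per kept point).
#' @export
final_points_scatter <- function(model_family, param_grid,
                                 x0_set = 10^seq(-2, 1, length.out = 8),
                                 T = 10000, n_keep = 1000, seed = 1) {
  stopifnot(n_keep <= T)
  streams <- rng_substreams(seed, length(param_grid))
  keep_idx <- (T + 1 - n_keep + 1):(T + 1)
  rows <- lapply(seq_along(param_grid), function(i) {
    model <- model_family(param_grid[i])
    sim <- with_stream(streams[[i]],
                       simulate_ensemble_(model, x0_set, T, length(x0_set),
                                          keep_paths = TRUE))
    kept <- sim$paths[keep_idx, , drop = FALSE]
    data.frame(param = param_grid[i],
               x0 = rep(x0_set, each = n_keep),
               t = rep(keep_idx - 1L, times = length(x0_set)),
               density = as.vector(kept))
  })
  do.call(rbind, rows)
}

#' Probability of the running minimum falling below a level
#'
#' Monte-Carlo estimate of \eqn{P[\min_{t \le T} X_t \le \gamma]} — a
#' finite-horizon proxy for accessibility of the extinction state (the
#' population density getting arbitrarily small with positive probability).
#'
#' @param model a `fitness_model`.
#' @param x0 initial density.
#' @param T horizon.
#' @param n_reps replicates.
#' @param gamma density level (> 0).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with `prob`, `lo`, `hi`, `n_reps`.
#' @export
min_density_probe <- function(model, x0, T, n_reps, gamma, seed, conf = 0.95) {
  stopifnot(gamma > 0)
  sim <- simulate_ensemble(model, x0, T, n_reps, seed, track_min = TRUE)
  k <- sum(sim$mins <= gamma)
  ci <- stats::binom.test(k, n_reps, conf.level = conf)$conf.int
  list(prob = k / n_reps, lo = ci[1], hi = ci[2], n_reps = n_reps)
}
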