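# End-to-end ensemble experiments: the persistence-probability curve for the
# mate-limitation model, the asymptotic-dynamics scatters for the
# mate-limitation-Ricker and predator-saturation-Ricker models, a regime map
# over parameter grids, and seeded golden fixtures for regression tests.

derive_seeds_ <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Mate-limitation model constructor used by the figure experiments
#'
#' @param sigma log-scale standard deviation of the daughters-per-mated
#'   female parameter `lambda` (`sigma = 0` gives the deterministic point
#'   mass `exp(log_mean)`).
#' @param log_mean log-scale mean of `lambda` (default 0.1).
#' @param h half-saturation constant (default 10).
#' @return a `fitness_model`.
#' @export
mate_limitation_model <- function(sigma, log_mean = 0.1, h = 10) {
  lam <- if (sigma == 0) env_dist("point_mass", value = exp(log_mean))
         else env_dist("lognormal", logmean = log_mean, logsd = sigma)
  build_model("mate_limitation", params = list(h = h),
              env = list(lambda = lam))
}

#' Persistence-probability curves for the stochastic mate-limitation model
#'
#' For each noise level `sigma`, simulates `n_reps` runs per initial
#' density and reports the fraction whose final density exceeds
#' `threshold`. The deterministic (`sigma = 0`) curve is a step at the
#' Allee threshold \eqn{h / (\lambda - 1)}; positive noise makes the curve
#' sigmoidal and lifts the persistence probability of populations starting
#' below the threshold.
#'
#' @param sigma_grid noise levels (default `c(0, 0.25, 0.5, 1)`).
#' @param x0_grid initial densities.
#' @param T horizon in time steps (default 1000; the curve is insensitive
#'   to doubling it).
#' @param n_reps replicates per grid point (default 1000; the full-size
#'   protocol uses 10000).
#' @param threshold final-density persistence cutoff (default 100).
#' @param log_mean,h mate-limitation parameters (defaults 0.1 and 10).
#' @param seed integer seed.
#' @return data.frame with columns `sigma`, `x0`, `phat`, `lo`, `hi`,
#'   `n_reps`.
#' @export
run_figure1 <- function(sigma_grid = c(0, 0.25, 0.5, 1),
                        x0_grid = c(1, 10, 25, 50, 70, 85, 95, 105, 120,
                                    150, 200, 300),
                        T = 1000, n_reps = 1000, threshold = 100,
                        log_mean = 0.1, h = 10, seed = 1) {
  stopifnot(length(sigma_grid) >= 1)
  seeds <- derive_seeds_(seed, length(sigma_grid))
  rows <- lapply(seq_along(sigma_grid), function(i) {
    model <- mate_limitation_model(sigma_grid[i], log_mean, h)
    curve <- persistence_curve(model, x0_grid, T, n_reps, threshold, seeds[i])
    cbind(sigma = sigma_grid[i], curve)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(experiment = "figure1", sigma_grid = sigma_grid,
                              x0_grid = x0_grid, T = T, n_reps = n_reps,
                              threshold = threshold, log_mean = log_mean,
                              h = h, seed = seed)
  out
}

#' Asymptotic-dynamics scatter for the mate-limitation-Ricker model
#'
#' Fitness \eqn{\exp(r - a x)\, x/(h + x)} with `r` uniform on
#' `[r_center - eps, r_center + eps]`. For each noise half-width `eps`, one
#' trajectory per initial density is run for `T` steps and the last
#' `n_keep` densities are emitted. Small `eps` keeps orbits inside the
#' skeleton's positive attractor; `eps` approaching `r_center` drives every
#' orbit extinct.
#'
#' @param eps_grid noise half-widths, inside `[0, r_center)`.
#' @param x0_set initial densities.
#' @param T,n_keep trajectory length and number of kept final points
#'   (defaults 10000 and 1000, the full-size protocol).
#' @param r_center center of the uniform growth-rate noise (default 4.5).
#' @param a,h competition strength and half-saturation (defaults 1 and 10).
#' @param seed integer seed.
#' @return Tidy data.frame `param` (= eps), `x0`, `t`, `density`.
#' @export
run_figure2 <- function(eps_grid = seq(0, 4.4, length.out = 12),
                        x0_set = 10^seq(-2, 1, length.out = 8),
                        T = 10000, n_keep = 1000,
                        r_center = 4.5, a = 1, h = 10, seed = 1) {
  stopifnot(all(eps_grid >= 0), all(eps_grid < r_center))
  fam <- function(eps)
    build_model("mate_limitation_ricker", params = list(a = a, h = h),
                env = list(r = env_dist("uniform", center = r_center,
                                        halfwidth = eps)))
  out <- final_points_scatter(fam, eps_grid, x0_set, T, n_keep, seed)
  attr(out, "config") <- list(experiment = "figure2", eps_grid = eps_grid,
                              x0_set = x0_set, T = T, n_keep = n_keep,
                              r_center = r_center, a = a, h = h, seed = seed)
  out
}

#' Asymptotic-dynamics scatter for the predator-saturation-Ricker model
#'
#' Fitness \eqn{\exp(4 - 4x - P_t/(1/12 + x))} with `P` uniform on
#' `Pbar * [1 - eps, 1 + eps]`, scanned over the mean predation intensity
#' `Pbar`. Below `Pbar = 1/3` the zero-density geometric mean
#' \eqn{G(0) = \exp(4 - 12\,\bar P)} exceeds one and the population
#' persists from every start; at intermediate `Pbar` noise drives every
#' orbit extinct; at higher `Pbar` conditional persistence returns for
#' starts inside the attractor basin.
#'
#' @param Pbar_grid mean predation intensities (default: 8 values spanning
#'   the persistence, extinction-window and conditional-persistence
#'   regimes).
#' @param eps relative noise half-width (default 0.2).
#' @param x0_set initial densities (default `c(0.05, 0.5, 2, 5)`).
#' @param T,n_keep trajectory length and kept final points (defaults 10000
#'   and 1000).
#' @param r,a,h fitness constants (defaults 4, 4, 1/12).
#' @param seed integer seed.
#' @return Tidy data.frame `param` (= Pbar), `x0`, `t`, `density`.
#' @export
run_figure3 <- function(Pbar_grid = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.85, 1.0),
                        eps = 0.2, x0_set = c(0.05, 0.5, 2, 5),
                        T = 10000, n_keep = 1000,
                        r = 4, a = 4, h = 1 / 12, seed = 1) {
  stopifnot(all(Pbar_grid > 0), eps >= 0, eps < 1)
  fam <- function(Pbar)
    build_model("predator_saturation_ricker",
                params = list(r = r, a = a, h = h),
                env = list(P = env_dist("uniform", lower = Pbar * (1 - eps),
                                        upper = Pbar * (1 + eps))))
  out <- final_points_scatter(fam, Pbar_grid, x0_set, T, n_keep, seed)
  attr(out, "config") <- list(experiment = "figure3", Pbar_grid = Pbar_grid,
                              eps = eps, x0_set = x0_set, T = T,
                              n_keep = n_keep, r = r, a = a, h = h,
                              seed = seed)
  out
}

#' Per-cell outcome summary of a final-points scatter
#'
#' Reduces a [final_points_scatter()] table to one row per
#' `(param, x0)` cell with the final density, its run classification, and
#' the range of kept points.
#'
#' @param scatter data.frame from a scatter experiment.
#' @param delta_ext,M_big classification cutoffs.
#' @return data.frame with `param`, `x0`, `final`, `verdict`, `kept_min`,
#'   `kept_max`.
#' @export
scatter_cell_summary <- function(scatter, delta_ext = 1e-8, M_big = 1e8) {
  key <- interaction(scatter$param, scatter$x0, drop = TRUE)
  rows <- lapply(split(scatter, key), function(d) {
    fin <- d$density[which.max(d$t)]
    data.frame(param = d$param[1], x0 = d$x0[1], final = fin,
               verdict = as.character(classify_run(fin, delta_ext, M_big)),
               kept_min = min(d$density), kept_max = max(d$density))
  })
  out <- do.call(rbind, rows)
  out[order(out$param, out$x0), , drop = FALSE]
}

#' Regime map over a two-parameter grid
#'
#' For each grid cell, builds the model, classifies the regime by the
#' geometric-mean criteria, classifies the deterministic skeleton, and
#' (optionally) corroborates with a small simulated ensemble.
#'
#' @param model_family function `(p1, p2) -> fitness_model`.
#' @param p1_grid,p2_grid parameter grids.
#' @param x0 ensemble start density.
#' @param T,n_reps ensemble controls (`n_reps = 0` skips the ensemble).
#' @param delta_ext,M_big run-classification cutoffs.
#' @param seed integer seed.
#' @return Tidy data.frame with one row per cell: `p1`, `p2`, `regime`,
#'   `skeleton`, `frac_extinct`, `frac_interior`, `frac_exploded`,
#'   `error` (message for cells that failed, else `NA`).
#' @export
regime_map <- function(model_family, p1_grid, p2_grid, x0 = 1,
                       T = 2000, n_reps = 20, delta_ext = 1e-8, M_big = 1e8,
                       seed = 1) {
  cells <- expand.grid(p1 = p1_grid, p2 = p2_grid)
  seeds <- derive_seeds_(seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p1 <- cells$p1[i]; p2 <- cells$p2[i]
    out <- data.frame(p1 = p1, p2 = p2, regime = NA_character_,
                      skeleton = NA_character_, frac_extinct = NA_real_,
                      frac_interior = NA_real_, frac_exploded = NA_real_,
                      error = NA_character_)
    tryCatch({
      model <- model_family(p1, p2)
      out$regime <- classify_regime(model, seed = seeds[i])$regime
      out$skeleton <- tryCatch(classify_skeleton(model)$verdict,
                               error = function(e) NA_character_)
      if (n_reps > 0) {
        fin <- simulate_ensemble(model, x0, T, n_reps, seeds[i])$final
        v <- classify_run(fin, delta_ext, M_big)
        out$frac_extinct <- mean(v == "EXTINCT")
        out$frac_interior <- mean(v == "INTERIOR")
        out$frac_exploded <- mean(v == "EXPLODED")
      }
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  do.call(rbind, rows)
}

# Canonical catalogue parameterizations used by the fixture generator.
fixture_models_ <- function() {
  list(
    ricker = build_model("ricker", params = list(a = 1),
                         env = list(r = env_dist("normal", mean = 0.3, sd = 0.5))),
    beverton_holt = build_model("beverton_holt", params = list(b = 0.5),
                                env = list(a = env_dist("lognormal",
                                                        logmean = 0.4, logsd = 0.3))),
    mate_limitation = mate_limitation_model(0.5),
    predator_saturation = build_model("predator_saturation",
                                      params = list(r = 1, h = 1),
                                      env = list(P = env_dist("uniform",
                                                              center = 0.8,
                                                              halfwidth = 0.2))),
    mate_limitation_ricker = build_model("mate_limitation_ricker",
                                         params = list(a = 1, h = 10),
                                         env = list(r = env_dist("uniform",
                                                                 center = 4.5,
                                                                 halfwidth = 0.5))),
    predator_saturation_ricker = build_model("predator_saturation_ricker",
                                             params = list(r = 4, a = 4, h = 1 / 12),
                                             env = list(P = env_dist("uniform",
                                                                     lower = 0.4,
                                                                     upper = 0.6))),
    liebhold_bascompte = build_model("liebhold_bascompte",
                                     params = list(gamma_lb = 0.1, c_lb = 5),
                                     env = list(xi = env_dist("normal",
                                                              mean = 0, sd = 0.3)))
  )
}

#' Generate golden seeded fixtures
#'
#' Writes one short reference trajectory per catalogue model (CSV) plus a
#' JSON manifest of the seeds and model specifications. Regeneration with
#' the same seed is bit-identical, which is what the regression tests
#' check.
#'
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @param T trajectory length.
#' @return Invisibly, the manifest list.
#' @export
generate_fixtures <- function(seed, dir, T = 50) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  models <- fixture_models_()
  seeds <- derive_seeds_(seed, length(models))
  manifest <- list(seed = seed, T = T, models = list())
  for (i in seq_along(models)) {
    nm <- names(models)[i]
    traj <- iterate(models[[i]], x0 = 1, T = T, seed = seeds[i])
    df <- data.frame(t = 0:T, density = traj$densities)
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    manifest$models[[nm]] <- list(seed = seeds[i],
                                  spec = model_to_list(models[[i]]))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# ---- config files -----------------------------------------------------------

#' Run an experiment from a config list or YAML file
#'
#' The config dialect is YAML. Required field: `experiment` (one of
#' `figure1`, `figure2`, `figure3`, `regime_map_ricker`); remaining fields
#' override the experiment's defaults (see the corresponding `run_*`
#' functions).
#'
#' @param config a named list, or path to a YAML file.
#' @return The experiment's result data.frame, with the resolved config in
#'   `attr(, "config")`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  exp <- config$experiment
  if (is.null(exp)) stop("config is missing the 'experiment' field")
  args <- config[setdiff(names(config), "experiment")]
  switch(exp,
    figure1 = do.call(run_figure1, args),
    figure2 = do.call(run_figure2, args),
    figure3 = do.call(run_figure3, args),
    regime_map_ricker = {
      fam <- function(mu, sigma)
        build_model("ricker", params = list(a = 1),
                    env = list(r = env_dist("normal", mean = mu, sd = sigma)))
      do.call(regime_map, c(list(model_family = fam), args))
    },
    stop("unknown experiment '", exp, "'"))
}

#' Write experiment results with a metadata sidecar
#'
#' Writes `results.csv` and `metadata.json` (resolved config, seeds,
#' package version) into `dir`.
#'
#' @param result data.frame from a `run_*` function.
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_experiment_output <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result, file.path(dir, "results.csv"), row.names = FALSE)
  meta <- list(config = attr(result, "config"),
               package_version = as.character(utils::packageVersion("stochallee")),
               written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
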