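# Geometric-mean fitness G(x) = exp(E[log f(x, xi)]) and the regime
# classification it drives: the low-density invasion criterion G(0) vs 1,
# the high-density criterion G(Inf) vs 1, and the decision rules for
# decreasing, increasing and mixed density dependence.

#' Geometric-mean fitness at a density
#'
#' Computes \eqn{G(x) = \exp(E[\log f(x, \xi)])}, the growth-relevant
#' average of fitness under multiplicative dynamics. `G(0) > 1` is the
#' invasion criterion at low density; for models with positive density
#' dependence `G(Inf)` (the limit of `G` at infinite density) governs the
#' fate of large populations. `G = 0` is returned when the log-fitness
#' expectation is `-Inf` (e.g. mate limitation at `x = 0`).
#'
#' @param model a `fitness_model`.
#' @param x density (>= 0), or `Inf` for the high-density limit (requires
#'   the model to declare `infinity_limit`).
#' @param method `"auto"` (closed form when registered, else quadrature),
#'   `"closed_form"`, `"quadrature"` or `"monte_carlo"`.
#' @param budget Monte-Carlo sample size.
#' @param n_nodes quadrature nodes per environmental coordinate.
#' @param seed seed (Monte Carlo only).
#' @return Object of class `geo_mean_result`: `x`, `G`, `log_G`, `method`,
#'   `error` (on the log scale; 0 for closed form).
#' @examples
#' m <- build_model("ricker", params = list(a = 1),
#'                  env = list(r = env_dist("normal", mean = 0.5, sd = 0.2)))
#' geo_mean_fitness(m, 0)$G  # exp(0.5)
#' @export
geo_mean_fitness <- function(model, x,
                             method = c("auto", "closed_form", "quadrature",
                                        "monte_carlo"),
                             budget = 1e5, n_nodes = 128, seed = 1) {
  method <- match.arg(method)

  if (is.infinite(x)) {
    if (method %in% c("auto", "closed_form") && !is.null(model$log_g_inf)) {
      lg <- model$log_g_inf
      return(structure(list(x = Inf, G = exp(lg), log_G = lg,
                            method = "closed_form", error = 0),
                       class = "geo_mean_result"))
    }
    if (is.null(model$infinity_limit))
      stop("G(Inf) requested but the model declares no infinity_limit")
    if (method == "closed_form")
      stop("no closed form registered for G(Inf) of this model")
    g <- function(m) log(model$infinity_limit(m))
    e <- expectation_of(model$env, g,
                        method = if (method == "monte_carlo") "monte_carlo"
                                 else "quadrature",
                        budget = budget, n_nodes = n_nodes, seed = seed)
    return(structure(list(x = Inf, G = exp(e$estimate), log_G = e$estimate,
                          method = e$method, error = e$error),
                     class = "geo_mean_result"))
  }

  stopifnot(x >= 0)
  if (method %in% c("auto", "closed_form") &&
      !is.null(model$log_fitness_closed_form)) {
    lg <- model$log_fitness_closed_form(x)
    return(structure(list(x = x, G = exp(lg), log_G = lg,
                          method = "closed_form", error = 0),
                     class = "geo_mean_result"))
  }
  if (method == "closed_form")
    stop("no closed form registered for E[log f] of this model")
  g <- function(m) log(model$eval(x, m))
  e <- expectation_of(model$env, g,
                      method = if (method == "monte_carlo") "monte_carlo"
                               else "quadrature",
                      budget = budget, n_nodes = n_nodes, seed = seed)
  structure(list(x = x, G = exp(e$estimate), log_G = e$estimate,
                 method = e$method, error = e$error),
            class = "geo_mean_result")
}

#' @export
print.geo_mean_result <- function(x, ...) {
  cat(sprintf("<G(%s) = %.6g  [%s, log-scale error %.3g]>\n",
              format(x$x), x$G, x$method,
              if (is.na(x$error)) NA else x$error))
  invisible(x)
}

# TRUE when log G is within the indeterminacy band around 0 (G within
# error of 1): classification at criticality is not meaningful.
near_one_ <- function(gm) {
  err <- if (is.na(gm$error)) 0 else gm$error
  is.finite(gm$log_G) && abs(gm$log_G) <= max(3 * err, 1e-6)
}

# G(Inf) with the declared-limit route when available, else matched
# evaluations at two very large densities (1e6, 1e8); NULL if they disagree.
g_inf_ <- function(model, budget, n_nodes, seed) {
  if (!is.null(model$log_g_inf) || !is.null(model$infinity_limit))
    return(geo_mean_fitness(model, Inf, budget = budget, n_nodes = n_nodes,
                            seed = seed))
  g1 <- geo_mean_fitness(model, 1e6, budget = budget, n_nodes = n_nodes,
                         seed = seed)
  g2 <- geo_mean_fitness(model, 1e8, budget = budget, n_nodes = n_nodes,
                         seed = seed)
  tol <- max(3 * (g1$error + g2$error), 1e-6, 1e-6 * abs(g1$log_G))
  if (!isTRUE(abs(g1$log_G - g2$log_G) <= tol)) return(NULL)
  g2
}

#' Check the low-density extinction assumptions and related conditions
#'
#' Numerically checks, with the evidence attached:
#' \itemize{
#'   \item `A1`: geometric-mean fitness below one at zero density
#'     (\eqn{G(0) < 1}) — a strong stochastic Allee effect at the origin;
#'   \item `A2`: fitness increasing near zero density for every sampled
#'     environment (positive density dependence on a prefix
#'     \eqn{[0, \gamma)});
#'   \item `tail`: a candidate pivot density `x_c` (the maximizer of
#'     \eqn{E \log f} on the grid) with \eqn{f} decreasing beyond it and
#'     tail geometric mean below one — the sufficient form of the
#'     mixed-density-dependence persistence condition;
#'   \item `boundedness`: a grid heuristic for
#'     \eqn{\sup_x x f(x, \bar\xi) < \infty}.
#' }
#'
#' @param model a `fitness_model`.
#' @param grid density grid covering (0, x_max] densely enough to catch the
#'   model's turning point (caller's responsibility).
#' @param n_env sampled environments for the monotonicity checks.
#' @param seed integer seed.
#' @param budget,n_nodes expectation controls.
#' @return list with entries `A1`, `A2`, `tail`, `boundedness`, each a list
#'   carrying a logical `holds` plus numeric evidence.
#' @export
check_assumptions <- function(model, grid = c(0, 10^seq(-3, log10(50), length.out = 160)),
                              n_env = 32, seed = 1, budget = 1e5, n_nodes = 128) {
  G0 <- geo_mean_fitness(model, 0, budget = budget, n_nodes = n_nodes,
                         seed = seed)
  probe <- monotonicity_probe(model, grid = grid, n_env = n_env, seed = seed)

  # E[log f] along the positive grid
  pos <- grid[grid > 0]
  logG <- if (!is.null(model$log_fitness_closed_form))
    model$log_fitness_closed_form(pos)
  else
    vapply(pos, function(xx)
      geo_mean_fitness(model, xx, n_nodes = min(n_nodes, 64))$log_G,
      numeric(1))
  imax <- which.max(logG)

  # pivot x_c: smallest grid point at or beyond the E[log f] maximizer such
  # that f is decreasing beyond it for *every* sampled environment
  # (individual environments can turn later than the mean does)
  xis <- sample_env(model$env, n_env, seed)
  last_up <- imax
  for (i in seq_len(nrow(xis))) {
    fx <- model$eval(pos, xis[rep(i, length(pos)), , drop = FALSE])
    up <- which(diff(fx) > 1e-12)
    if (length(up)) last_up <- max(last_up, up[length(up)] + 1L)
  }
  tail_dec <- last_up < length(pos)
  x_c <- if (tail_dec) pos[last_up] else NA_real_
  G_tail <- geo_mean_fitness(model, max(pos) * 10, budget = budget,
                             n_nodes = min(n_nodes, 64), seed = seed)
  tail_holds <- tail_dec && G_tail$G < 1 && exp(logG[imax]) > 1

  # boundedness of x * f(x, xi_bar): unbounded forms grow ~ linearly at the
  # tail (slope of log(x f) vs log x near 1), bounded forms decay
  xi_bar <- env_mean(model$env)
  xb <- 10^seq(log10(max(pos)), log10(max(pos)) + 4, length.out = 60)
  xim <- matrix(rep(xi_bar, each = length(xb)), nrow = length(xb),
                dimnames = list(NULL, names(xi_bar)))
  xf <- xb * model$eval(xb, xim)
  slope <- diff(log(pmax(xf, 1e-320)))[length(xb) - 1] /
    diff(log(xb))[length(xb) - 1]
  bounded <- is.finite(max(xf)) && slope < 0.5 && xf[length(xb)] <= max(xf)

  list(
    A1 = list(holds = G0$G < 1 && !near_one_(G0), G0 = G0),
    A2 = list(holds = probe$increasing_near_zero,
              gamma_prefix = probe$gamma_prefix),
    tail = list(holds = tail_holds, x_c = if (tail_holds) x_c else NA_real_,
                G_at_xc = exp(logG[imax]), G_tail = G_tail$G,
                decreasing_beyond = tail_dec),
    boundedness = list(holds = bounded, tail_slope = slope,
                       sup_xf = max(xf))
  )
}

#' Classify the persistence/extinction regime of a model
#'
#' Applies the geometric-mean-fitness decision rules:
#' \itemize{
#'   \item decreasing fitness (only negative density dependence):
#'     \eqn{G(0) < 1} gives unconditional extinction, \eqn{G(\infty) > 1}
#'     unbounded growth, \eqn{G(0) > 1 > G(\infty)} stochastic persistence;
#'   \item increasing fitness (only positive density dependence):
#'     \eqn{G(\infty) < 1} gives unconditional extinction, \eqn{G(0) > 1}
#'     unbounded growth, \eqn{G(0) < 1 < G(\infty)} conditional persistence
#'     (a strong stochastic Allee effect);
#'   \item mixed density dependence: \eqn{G(0) > 1} together with a
#'     decreasing tail whose geometric mean falls below one gives stochastic
#'     persistence; with \eqn{G(0) < 1}, multiplicatively unbounded noise
#'     (lognormal/gamma) plus bounded \eqn{x f(x, \xi)} gives unconditional
#'     extinction (the extinction state is accessible from everywhere),
#'     while compact small noise defers to the deterministic skeleton:
#'     a positive attractor supports conditional persistence, essential or
#'     global extinction of the skeleton gives unconditional extinction.
#' }
#' Any criterion within numerical error of \eqn{G = 1} yields
#' `INDETERMINATE`.
#'
#' @param model a `fitness_model`.
#' @param x_max density range for assumption checks and skeleton analysis.
#' @param budget,n_nodes,seed expectation controls.
#' @return Object of class `regime_report`: `regime` (one of
#'   `UNCONDITIONAL_EXTINCTION`, `UNBOUNDED_GROWTH`,
#'   `STOCHASTIC_PERSISTENCE`, `CONDITIONAL_PERSISTENCE`,
#'   `INDETERMINATE`), `criterion` (which decision rule fired), and
#'   `evidence` (G(0), G(Inf), x_c, noise-support flags, skeleton verdict
#'   where consulted).
#' @export
classify_regime <- function(model, x_max = 50, budget = 1e5, n_nodes = 128,
                            seed = 1) {
  mono <- model$monotonicity
  G0 <- geo_mean_fitness(model, 0, budget = budget, n_nodes = n_nodes,
                         seed = seed)
  Ginf <- g_inf_(model, budget, n_nodes, seed)
  ev <- list(G0 = G0, Ginf = Ginf, x_c = NULL,
             noise_support_unbounded = mult_noise_unbounded_(model),
             noise_support_bounded = env_bounded_support(model$env),
             skeleton_verdict = NULL)
  report <- function(regime, criterion)
    structure(list(regime = regime, criterion = criterion, evidence = ev),
              class = "regime_report")

  if (mono == "decreasing") {
    if (is.null(Ginf))
      return(report("INDETERMINATE", "G(Inf) could not be pinned down"))
    if (near_one_(G0) || near_one_(Ginf))
      return(report("INDETERMINATE", "G within error of 1"))
    if (G0$G < 1)
      return(report("UNCONDITIONAL_EXTINCTION",
                    "decreasing-fitness trichotomy: G(0) < 1"))
    if (Ginf$G > 1)
      return(report("UNBOUNDED_GROWTH",
                    "decreasing-fitness trichotomy: G(Inf) > 1"))
    return(report("STOCHASTIC_PERSISTENCE",
                  "decreasing-fitness trichotomy: G(0) > 1 > G(Inf)"))
  }

  if (mono == "increasing") {
    if (is.null(Ginf))
      return(report("INDETERMINATE", "G(Inf) could not be pinned down"))
    if (near_one_(G0) || near_one_(Ginf))
      return(report("INDETERMINATE", "G within error of 1"))
    if (Ginf$G < 1)
      return(report("UNCONDITIONAL_EXTINCTION",
                    "increasing-fitness trichotomy: G(Inf) < 1"))
    if (G0$G > 1)
      return(report("UNBOUNDED_GROWTH",
                    "increasing-fitness trichotomy: G(0) > 1"))
    return(report("CONDITIONAL_PERSISTENCE",
                  "increasing-fitness trichotomy: G(0) < 1 < G(Inf)"))
  }

  # mixed density dependence
  if (near_one_(G0))
    return(report("INDETERMINATE", "G(0) within error of 1"))
  chk <- check_assumptions(model,
                           grid = c(0, 10^seq(-3, log10(x_max), length.out = 160)),
                           seed = seed, budget = budget, n_nodes = n_nodes)
  ev$x_c <- chk$tail$x_c
  if (G0$G > 1) {
    if (chk$tail$holds)
      return(report("STOCHASTIC_PERSISTENCE",
                    "mixed: G(0) > 1 with decreasing tail, tail G < 1"))
    return(report("INDETERMINATE",
                  "mixed: G(0) > 1 but no qualifying decreasing tail found"))
  }
  # G(0) < 1
  if (ev$noise_support_unbounded && chk$boundedness$holds)
    return(report("UNCONDITIONAL_EXTINCTION",
                  "mixed: G(0) < 1, large-noise accessibility (unbounded multiplicative noise, bounded x*f)"))
  if (ev$noise_support_bounded) {
    sk <- tryCatch(classify_skeleton(model, x_max = x_max),
                   error = function(e) NULL)
    if (!is.null(sk)) {
      ev$skeleton_verdict <- sk$verdict
      if (sk$verdict == "POSITIVE_ATTRACTOR")
        return(report("CONDITIONAL_PERSISTENCE",
                      "mixed: G(0) < 1, small compact noise, skeleton has a positive attractor"))
      if (sk$verdict %in% c("ESSENTIAL_EXTINCTION", "GLOBAL_EXTINCTION"))
        return(report("UNCONDITIONAL_EXTINCTION",
                      "mixed: G(0) < 1, small compact noise, skeleton has no positive attractor"))
    }
  }
  report("INDETERMINATE", "mixed: G(0) < 1, no accessibility route established")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("<regime_report: %s>\n  rule: %s\n", x$regime, x$criterion))
  if (!is.null(x$evidence$G0))
    cat(sprintf("  G(0)   = %.6g\n", x$evidence$G0$G))
  if (!is.null(x$evidence$Ginf))
    cat(sprintf("  G(Inf) = %.6g\n", x$evidence$Ginf$G))
  if (!is.null(x$evidence$skeleton_verdict))
    cat(sprintf("  skeleton: %s\n", x$evidence$skeleton_verdict))
  invisible(x)
}

#' Arithmetic-geometric gap of fitness at a density
#'
#' Computes the arithmetic mean \eqn{E[f(x, \xi)]}, the geometric mean
#' \eqn{G(x)}, and their gap. By the AM-GM inequality the gap is
#' non-negative, and it quantifies how environmental fluctuation alone can
#' push the growth-relevant (geometric) mean below one while the arithmetic
#' mean stays above one — shifting a weak Allee effect to a strong one.
#'
#' @param model a `fitness_model`.
#' @param x density.
#' @param budget,n_nodes,seed expectation controls.
#' @param method `"quadrature"` or `"monte_carlo"`.
#' @return list with `arithmetic_mean`, `geometric_mean`, `gap`.
#' @export
jensen_gap <- function(model, x, budget = 1e5, n_nodes = 128, seed = 1,
                       method = c("quadrature", "monte_carlo")) {
  method <- match.arg(method)
  am <- expectation_of(model$env, function(m) model$eval(x, m),
                       method = method, budget = budget, n_nodes = n_nodes,
                       seed = seed)
  gm <- geo_mean_fitness(model, x, method = method, budget = budget,
                         n_nodes = n_nodes, seed = seed)
  list(arithmetic_mean = am$estimate, geometric_mean = gm$G,
       gap = am$estimate - gm$G)
}
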