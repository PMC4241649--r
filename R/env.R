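# Environmental noise: i.i.d. environment distributions, sampling, and the
# expectation engine E[g(xi)] that underlies the geometric-mean fitness.

#' Construct an environmental noise distribution
#'
#' Represents the i.i.d. environmental driver \eqn{\xi_t} of the stochastic
#' difference equation \eqn{X_{t+1} = f(X_t, \xi_t) X_t}. A distribution is
#' one scalar coordinate of the environment; several coordinates (e.g.
#' \eqn{\xi = (r, a)}) are composed with [env_product()].
#'
#' Supported families and their parameters:
#' \describe{
#'   \item{`point_mass`}{`value` — degenerate, no fluctuation.}
#'   \item{`normal`}{`mean`, `sd` (sd > 0).}
#'   \item{`lognormal`}{`logmean`, `logsd` (logsd > 0); strictly positive
#'     support, used for multiplicative vital rates.}
#'   \item{`uniform`}{either `lower`/`upper` or `center`/`halfwidth`
#'     (halfwidth >= 0; a zero halfwidth degenerates to a point mass on the
#'     support but keeps the uniform bookkeeping).}
#'   \item{`gamma`}{`shape`, `rate` (both > 0).}
#' }
#'
#' @param family one of `"point_mass"`, `"normal"`, `"lognormal"`,
#'   `"uniform"`, `"gamma"`.
#' @param ... named family parameters (see Details).
#' @return An object of class `env_dist` with fields `family`, `params`,
#'   `support` (length-2 numeric, possibly infinite) and `dim = 1`.
#' @examples
#' env_dist("uniform", center = 4.5, halfwidth = 0.5)   # support [4, 5]
#' env_dist("lognormal", logmean = 0.1, logsd = 0.5)    # support (0, Inf)
#' @export
env_dist <- function(family = c("point_mass", "normal", "lognormal",
                                "uniform", "gamma"), ...) {
  family <- match.arg(family)
  p <- list(...)
  need <- function(nm) {
    v <- p[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("env_dist('%s'): parameter '%s' missing or not a finite scalar",
                   family, nm), call. = FALSE)
    v
  }
  params <- switch(family,
    point_mass = list(value = need("value")),
    normal = {
      sd <- need("sd")
      if (sd <= 0) stop("env_dist('normal'): 'sd' must be > 0", call. = FALSE)
      list(mean = need("mean"), sd = sd)
    },
    lognormal = {
      logsd <- need("logsd")
      if (logsd <= 0) stop("env_dist('lognormal'): 'logsd' must be > 0", call. = FALSE)
      list(logmean = need("logmean"), logsd = logsd)
    },
    uniform = {
      if (!is.null(p$center) || !is.null(p$halfwidth)) {
        hw <- need("halfwidth")
        if (hw < 0) stop("env_dist('uniform'): 'halfwidth' must be >= 0", call. = FALSE)
        ctr <- need("center")
        list(lower = ctr - hw, upper = ctr + hw)
      } else {
        lo <- need("lower"); up <- need("upper")
        if (up < lo) stop("env_dist('uniform'): 'upper' must be >= 'lower'", call. = FALSE)
        list(lower = lo, upper = up)
      }
    },
    gamma = {
      shape <- need("shape"); rate <- need("rate")
      if (shape <= 0) stop("env_dist('gamma'): 'shape' must be > 0", call. = FALSE)
      if (rate <= 0) stop("env_dist('gamma'): 'rate' must be > 0", call. = FALSE)
      list(shape = shape, rate = rate)
    })
  support <- switch(family,
    point_mass = c(params$value, params$value),
    normal     = c(-Inf, Inf),
    lognormal  = c(0, Inf),
    uniform    = c(params$lower, params$upper),
    gamma      = c(0, Inf))
  structure(list(family = family, params = params, support = support, dim = 1L),
            class = "env_dist")
}

#' Compose independent environmental coordinates into a product distribution
#'
#' The environment \eqn{\xi} of a fitness model is in general a vector
#' (e.g. \eqn{(r, a)} for the Ricker map); each coordinate fluctuates
#' independently.
#'
#' @param ... named `env_dist` objects, one per coordinate.
#' @return An object of class `env_product` with `components` (named list),
#'   `dim`, and a `support` matrix (coordinates in rows).
#' @examples
#' env_product(r = env_dist("normal", mean = 0.3, sd = 0.5),
#'             a = env_dist("point_mass", value = 1))
#' @export
env_product <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && is.list(comps[[1]]) && !inherits(comps[[1]], "env_dist"))
    comps <- comps[[1]]
  if (length(comps) == 0L) stop("env_product(): at least one coordinate required")
  nm <- names(comps)
  if (is.null(nm) || any(nm == ""))
    stop("env_product(): every coordinate must be named")
  ok <- vapply(comps, inherits, logical(1), what = "env_dist")
  if (!all(ok)) stop("env_product(): all coordinates must be env_dist objects")
  support <- t(vapply(comps, function(d) d$support, numeric(2)))
  colnames(support) <- c("lower", "upper")
  structure(list(components = comps, dim = length(comps), support = support),
            class = "env_product")
}

# Coerce a bare env_dist to a one-coordinate product with the given name.
as_env_product <- function(env, name = "xi") {
  if (inherits(env, "env_product")) return(env)
  if (inherits(env, "env_dist")) {
    out <- list(components = stats::setNames(list(env), name),
                dim = 1L,
                support = matrix(env$support, 1, 2,
                                 dimnames = list(name, c("lower", "upper"))))
    class(out) <- "env_product"
    return(out)
  }
  stop("expected an env_dist or env_product")
}

#' @export
print.env_dist <- function(x, ...) {
  ps <- paste(names(x$params), signif(unlist(x$params), 6), sep = "=",
              collapse = ", ")
  cat(sprintf("<env_dist %s(%s), support [%s, %s]>\n", x$family, ps,
              format(x$support[1]), format(x$support[2])))
  invisible(x)
}

#' @export
print.env_product <- function(x, ...) {
  cat(sprintf("<env_product, %d coordinate(s)>\n", x$dim))
  for (nm in names(x$components)) {
    cat(" ", nm, ": ", sep = "")
    print(x$components[[nm]])
  }
  invisible(x)
}

# ---- sampling ---------------------------------------------------------------

sample_env_dist_ <- function(dist, n) {
  p <- dist$params
  switch(dist$family,
    point_mass = rep.int(p$value, n),
    normal     = stats::rnorm(n, p$mean, p$sd),
    lognormal  = stats::rlnorm(n, p$logmean, p$logsd),
    uniform    = if (p$upper == p$lower) rep.int(p$lower, n)
                 else stats::runif(n, p$lower, p$upper),
    gamma      = stats::rgamma(n, shape = p$shape, rate = p$rate))
}

#' Draw i.i.d. environment states
#'
#' @param env an `env_dist` or `env_product`.
#' @param n number of draws (>= 1).
#' @param seed integer seed; identical `(env, n, seed)` gives bit-identical
#'   output.
#' @return A numeric matrix with `n` rows and one named column per
#'   environmental coordinate.
#' @examples
#' sample_env(env_dist("uniform", lower = 4, upper = 5), 3, seed = 1)
#' @export
sample_env <- function(env, n, seed) {
  stopifnot(n >= 1)
  env <- as_env_product(env)
  with_seed(seed, {
    cols <- lapply(env$components, sample_env_dist_, n = n)
    m <- do.call(cbind, cols)
    colnames(m) <- names(env$components)
    m
  })
}

# Draw without touching seed bookkeeping (RNG state already positioned).
sample_env_raw_ <- function(env, n) {
  cols <- lapply(env$components, sample_env_dist_, n = n)
  m <- do.call(cbind, cols)
  colnames(m) <- names(env$components)
  m
}

# ---- moments ----------------------------------------------------------------

#' Mean of each environmental coordinate
#'
#' Closed-form coordinatewise expectation; this is the reference environment
#' \eqn{\bar\xi} used by the deterministic skeleton.
#'
#' @param env an `env_dist` or `env_product`.
#' @return Named numeric vector of coordinate means.
#' @export
env_mean <- function(env) {
  env <- as_env_product(env)
  vapply(env$components, function(d) {
    p <- d$params
    switch(d$family,
      point_mass = p$value,
      normal     = p$mean,
      lognormal  = exp(p$logmean + p$logsd^2 / 2),
      uniform    = (p$lower + p$upper) / 2,
      gamma      = p$shape / p$rate)
  }, numeric(1))
}

# E[log xi] per coordinate, closed form; errors where undefined.
env_log_mean <- function(env) {
  env <- as_env_product(env)
  vapply(env$components, function(d) {
    p <- d$params
    switch(d$family,
      point_mass = {
        if (p$value < 0) stop("E[log xi] undefined: negative point mass")
        log(p$value)
      },
      normal = stop("E[log xi] undefined for a normal coordinate (negative support)"),
      lognormal = p$logmean,
      uniform = {
        if (p$lower < 0) stop("E[log xi] undefined: uniform support includes negatives")
        lo <- p$lower; up <- p$upper
        if (up == lo) log(lo)
        else (up * log(up) - ifelse(lo == 0, 0, lo * log(lo)) - (up - lo)) / (up - lo)
      },
      gamma = digamma(p$shape) - log(p$rate))
  }, numeric(1))
}

env_bounded_support <- function(env) {
  env <- as_env_product(env)
  all(is.finite(env$support))
}

# ---- quadrature nodes per coordinate ---------------------------------------

# Returns list(nodes, weights) such that E[g(X)] ~= sum(w * g(nodes)).
# Gauss-Legendre on bounded supports, Gauss-Hermite for normal (exact
# weight match) and lognormal (on the log scale), generalized Gauss-Laguerre
# for gamma.
quad_rule_ <- function(dist, n_nodes) {
  p <- dist$params
  switch(dist$family,
    point_mass = list(nodes = p$value, weights = 1),
    uniform = {
      if (p$upper == p$lower) return(list(nodes = p$lower, weights = 1))
      gl <- pracma::gaussLegendre(n_nodes, p$lower, p$upper)
      list(nodes = gl$x, weights = gl$w / (p$upper - p$lower))
    },
    normal = {
      gh <- pracma::gaussHermite(n_nodes)
      list(nodes = p$mean + sqrt(2) * p$sd * gh$x, weights = gh$w / sqrt(pi))
    },
    lognormal = {
      gh <- pracma::gaussHermite(n_nodes)
      list(nodes = exp(p$logmean + sqrt(2) * p$logsd * gh$x),
           weights = gh$w / sqrt(pi))
    },
    gamma = {
      gl <- pracma::gaussLaguerre(n_nodes, p$shape - 1)
      list(nodes = gl$x / p$rate, weights = gl$w / gamma(p$shape))
    })
}

quad_grid_ <- function(env, n_nodes) {
  rules <- lapply(env$components, quad_rule_, n_nodes = n_nodes)
  nodes <- lapply(rules, `[[`, "nodes")
  grid <- as.matrix(expand.grid(nodes, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- names(env$components)
  wlist <- lapply(rules, `[[`, "weights")
  wgrid <- as.matrix(expand.grid(wlist, KEEP.OUT.ATTRS = FALSE))
  list(nodes = grid, weights = apply(wgrid, 1, prod))
}

# ---- expectation engine -----------------------------------------------------

#' Expectation of a function of the environment
#'
#' Computes \eqn{E[g(\xi)]} for a scalar function `g` of the environment by
#' closed form (registered templates only), deterministic quadrature, or
#' Monte Carlo. This is the engine underneath the geometric-mean fitness
#' \eqn{G(x) = \exp(E[\log f(x,\xi)])}.
#'
#' `g` may evaluate to `-Inf` on part of the support (e.g. \eqn{\log f} for
#' mate limitation at zero density); the expectation is then reported as
#' `-Inf` rather than an error.
#'
#' @param env an `env_dist` or `env_product`.
#' @param g either a function taking an environment matrix (rows = draws,
#'   named columns = coordinates) and returning a numeric vector, or one of
#'   the closed-form templates `"identity"` / `"log"` (scalar coordinate
#'   only).
#' @param method `"closed_form"`, `"quadrature"` or `"monte_carlo"`.
#'   Closed form is only available for the registered templates; requesting
#'   it otherwise is an error (no silent fallback).
#' @param budget Monte-Carlo sample size (default 1e5).
#' @param n_nodes quadrature nodes per coordinate (default 128).
#' @param seed seed for `method = "monte_carlo"`.
#' @return list with `estimate`, `error` (0 for closed form, a node-doubling
#'   difference for quadrature, the standard error for Monte Carlo) and
#'   `method`.
#' @examples
#' d <- env_dist("lognormal", logmean = 0.1, logsd = 0.5)
#' expectation_of(d, "log", method = "closed_form")$estimate  # 0.1 exactly
#' @export
expectation_of <- function(env, g,
                           method = c("quadrature", "closed_form", "monte_carlo"),
                           budget = 1e5, n_nodes = 128, seed = 1) {
  method <- match.arg(method)
  envp <- as_env_product(env)

  if (is.character(g)) {
    template <- match.arg(g, c("identity", "log"))
    if (method == "closed_form") {
      if (envp$dim != 1L)
        stop("no closed form registered for template '", template,
             "' on a product environment")
      est <- switch(template,
                    identity = unname(env_mean(envp)),
                    log = unname(env_log_mean(envp)))
      return(list(estimate = est, error = 0, method = "closed_form"))
    }
    g <- switch(template,
                identity = function(m) m[, 1L],
                log = function(m) log(m[, 1L]))
  } else if (method == "closed_form") {
    stop("no closed form registered for an arbitrary function; ",
         "use method = 'quadrature' or 'monte_carlo'")
  }

  if (method == "quadrature") {
    one_pass <- function(nn) {
      q <- quad_grid_(envp, nn)
      v <- g(q$nodes)
      if (any(is.nan(v))) stop("g returned NaN at a quadrature node")
      neg <- !is.finite(v) & v < 0
      if (any(neg & q$weights > 0)) return(-Inf)
      sum(q$weights * v)
    }
    e1 <- one_pass(n_nodes)
    if (identical(e1, -Inf))
      return(list(estimate = -Inf, error = 0, method = "quadrature"))
    e2 <- one_pass(max(n_nodes + 16L, ceiling(1.5 * n_nodes)))
    return(list(estimate = e2, error = abs(e2 - e1), method = "quadrature"))
  }

  # monte_carlo
  draws <- sample_env(envp, budget, seed)
  v <- g(draws)
  if (any(is.nan(v))) stop("g returned NaN at a sampled environment")
  if (any(!is.finite(v) & v < 0))
    return(list(estimate = -Inf, error = NA_real_, method = "monte_carlo"))
  list(estimate = mean(v), error = stats::sd(v) / sqrt(budget),
       method = "monte_carlo")
}

# ---- serialization ----------------------------------------------------------

#' Serialize / deserialize environment specifications
#'
#' Environment distributions round-trip through plain named lists so they
#' can live in YAML config files and be echoed verbatim in reports.
#'
#' @param env an `env_dist` or `env_product`.
#' @return `env_to_list()`: a plain list; `env_from_list()`: the rebuilt
#'   object.
#' @export
env_to_list <- function(env) {
  if (inherits(env, "env_dist"))
    return(c(list(family = env$family), env$params))
  if (inherits(env, "env_product"))
    return(list(family = "product",
                components = lapply(env$components, env_to_list)))
  stop("not an environment object")
}

#' @rdname env_to_list
#' @param spec a list as produced by `env_to_list()` (or parsed from YAML).
#' @export
env_from_list <- function(spec) {
  if (identical(spec$family, "product")) {
    comps <- lapply(spec$components, env_from_list)
    return(env_product(comps))
  }
  do.call(env_dist, c(list(family = spec$family),
                      spec[setdiff(names(spec), "family")]))
}
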