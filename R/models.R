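# Catalogue of fitness functions f(x, xi) for the stochastic difference
# equation X[t+1] = f(X[t], xi[t]) X[t], with monotonicity metadata,
# zero/infinite-density limits, and closed-form E[log f(x, .)] where the
# noise placement admits one.

FORMULA_PARAMS <- list(
  ricker                    = c("r", "a"),
  beverton_holt             = c("a", "b"),
  mate_limitation           = c("lambda", "h"),
  predator_saturation       = c("r", "P", "h"),
  mate_limitation_ricker    = c("r", "a", "h"),
  predator_saturation_ricker = c("r", "a", "P", "h"),
  liebhold_bascompte        = c("gamma_lb", "c_lb", "xi")
)

# Resolve parameter nm per draw: environment coordinate if random, else the
# constant from params.
par_of_ <- function(nm, xi, params) {
  if (is.matrix(xi) && nm %in% colnames(xi)) return(unname(xi[, nm]))
  if (!is.matrix(xi) && !is.null(names(xi)) && nm %in% names(xi)) return(xi[[nm]])
  if (nm %in% names(params)) return(params[[nm]])
  stop(sprintf("parameter '%s' found neither in the environment nor in params", nm),
       call. = FALSE)
}

is_const_coord_ <- function(env, params, nm) {
  if (!nm %in% names(env$components)) return(nm %in% names(params))
  env$components[[nm]]$family == "point_mass"
}

const_val_ <- function(env, params, nm) {
  if (nm %in% names(env$components)) env$components[[nm]]$params$value
  else params[[nm]]
}

coord_mean_ <- function(env, params, nm) {
  if (nm %in% names(env$components)) unname(env_mean(env$components[[nm]]))
  else params[[nm]]
}

coord_log_mean_ <- function(env, params, nm) {
  if (nm %in% names(env$components)) unname(env_log_mean(env$components[[nm]]))
  else {
    v <- params[[nm]]
    if (v < 0) stop("negative constant has no log mean")
    log(v)
  }
}

#' Build a fitness model from the catalogue
#'
#' Constructs the map \eqn{f(x, \xi)} for one of the catalogue forms, or a
#' user-defined form. Which parameters fluctuate and which are constant is
#' part of the model specification: any formula parameter named in `env`
#' is drawn from its distribution each time step, the rest are constants
#' from `params`.
#'
#' Catalogue forms (all densities \eqn{x \ge 0}):
#' \describe{
#'   \item{`ricker`}{\eqn{f = e^{r - a x}} — negative density dependence
#'     (decreasing in \eqn{x}).}
#'   \item{`beverton_holt`}{\eqn{f = a / (1 + b x)} — decreasing.}
#'   \item{`mate_limitation`}{\eqn{f = \lambda x / (h + x)} — positive
#'     density dependence (increasing); \eqn{f(0) = 0};
#'     \eqn{f \to \lambda} as \eqn{x \to \infty}. `h` is the male density at
#'     which half the females find a mate, `lambda` the number of daughters
#'     per mated female.}
#'   \item{`predator_saturation`}{\eqn{f = e^{r - P/(h + x)}} — increasing;
#'     predation risk dilutes as density grows. `r` is the intrinsic growth
#'     rate, `P` the predation intensity, `h` the predator's half-saturation
#'     constant.}
#'   \item{`mate_limitation_ricker`}{\eqn{f = e^{r - a x}\, x/(h + x)} —
#'     mixed (Allee effect plus overcompensating competition).}
#'   \item{`predator_saturation_ricker`}{\eqn{f = e^{r - a x - P/(h + x)}}
#'     — mixed.}
#'   \item{`liebhold_bascompte`}{\eqn{f = e^{\gamma (x - C) + \xi}} with
#'     \eqn{\xi} normal, mean zero — an increasing form with deterministic
#'     Allee threshold `c_lb` and intrinsic rate `gamma_lb`, reconstructed
#'     from its qualitative properties (\eqn{G(0) < 1 < G(\infty)}); see the
#'     methods vignette.}
#'   \item{`user_defined`}{supply `eval`, `monotonicity`, `zero_limit`,
#'     `infinity_limit` in `params`.}
#' }
#'
#' @param name catalogue name (see Details).
#' @param params named list of constant parameters.
#' @param env optional noise specification: an `env_product`, a named list
#'   of `env_dist` (names = fluctuating parameters), or `NULL` for a fully
#'   deterministic model.
#' @return An object of class `fitness_model` with fields `name`, `params`,
#'   `env`, `monotonicity` (`"decreasing"`, `"increasing"` or `"mixed"`),
#'   `eval(x, xi)`, `zero_limit(xi)`, `infinity_limit(xi)` (may return
#'   `Inf`), and, when registered, `log_fitness_closed_form(x)` giving
#'   \eqn{E[\log f(x, \xi)]} and `log_g_inf`, the closed-form
#'   \eqn{E[\log \lim_{x\to\infty} f]}.
#' @examples
#' m <- build_model("ricker", params = list(a = 1),
#'                  env = list(r = env_dist("normal", mean = 0.3, sd = 0.5)))
#' m$eval(1, cbind(r = 0.3))  # exp(0.3 - 1)
#' @export
build_model <- function(name, params = list(), env = NULL) {
  name <- match.arg(name, c(names(FORMULA_PARAMS), "user_defined"))

  if (name == "user_defined")
    return(build_user_model_(params, env))

  need <- FORMULA_PARAMS[[name]]
  # normalize env to an env_product over fluctuating parameters
  if (is.null(env)) {
    env <- env_product(stats::setNames(
      list(env_dist("point_mass", value = params[[need[1]]] %||%
                      stop("missing parameter '", need[1], "'"))),
      need[1]))
  } else if (inherits(env, "env_dist")) {
    stop("ambiguous environment: pass a *named* list, e.g. env = list(r = ...)")
  } else if (!inherits(env, "env_product")) {
    env <- env_product(env)
  }
  extra <- setdiff(names(env$components), need)
  if (length(extra))
    stop("environment coordinate(s) ", paste(extra, collapse = ", "),
         " are not parameters of model '", name, "'")
  missing <- setdiff(need, union(names(env$components), names(params)))
  # the Liebhold-Bascompte additive noise defaults to a zero point mass
  if (name == "liebhold_bascompte" && "xi" %in% missing) {
    params$xi <- 0
    missing <- setdiff(missing, "xi")
  }
  if (length(missing))
    stop("model '", name, "' is missing parameter(s): ",
         paste(missing, collapse = ", "))

  P <- params
  ev <- switch(name,
    ricker = function(x, xi)
      exp(par_of_("r", xi, P) - par_of_("a", xi, P) * x),
    beverton_holt = function(x, xi)
      par_of_("a", xi, P) / (1 + par_of_("b", xi, P) * x),
    mate_limitation = function(x, xi)
      par_of_("lambda", xi, P) * x / (par_of_("h", xi, P) + x),
    predator_saturation = function(x, xi)
      exp(par_of_("r", xi, P) - par_of_("P", xi, P) / (par_of_("h", xi, P) + x)),
    mate_limitation_ricker = function(x, xi)
      exp(par_of_("r", xi, P) - par_of_("a", xi, P) * x) *
        x / (par_of_("h", xi, P) + x),
    predator_saturation_ricker = function(x, xi)
      exp(par_of_("r", xi, P) - par_of_("a", xi, P) * x -
            par_of_("P", xi, P) / (par_of_("h", xi, P) + x)),
    liebhold_bascompte = function(x, xi)
      exp(par_of_("gamma_lb", xi, P) * (x - par_of_("c_lb", xi, P)) +
            par_of_("xi", xi, P)))

  zero_limit <- switch(name,
    ricker = function(xi) exp(par_of_("r", xi, P)),
    beverton_holt = function(xi) par_of_("a", xi, P),
    mate_limitation = function(xi) 0 * par_of_("lambda", xi, P),
    predator_saturation = function(xi)
      exp(par_of_("r", xi, P) - par_of_("P", xi, P) / par_of_("h", xi, P)),
    mate_limitation_ricker = function(xi) 0 * par_of_("r", xi, P),
    predator_saturation_ricker = function(xi) 0 * par_of_("r", xi, P),
    liebhold_bascompte = function(xi)
      exp(-par_of_("gamma_lb", xi, P) * par_of_("c_lb", xi, P) +
            par_of_("xi", xi, P)))

  infinity_limit <- switch(name,
    ricker = function(xi) {
      a <- par_of_("a", xi, P)
      ifelse(a > 0, 0, exp(par_of_("r", xi, P)))
    },
    beverton_holt = function(xi) {
      b <- par_of_("b", xi, P)
      ifelse(b > 0, 0, par_of_("a", xi, P))
    },
    mate_limitation = function(xi) par_of_("lambda", xi, P),
    predator_saturation = function(xi) exp(par_of_("r", xi, P)),
    mate_limitation_ricker = function(xi) {
      a <- par_of_("a", xi, P)
      ifelse(a > 0, 0, exp(par_of_("r", xi, P)))
    },
    predator_saturation_ricker = function(xi) {
      a <- par_of_("a", xi, P)
      ifelse(a > 0, 0, exp(par_of_("r", xi, P)))
    },
    liebhold_bascompte = function(xi) rep(Inf, max(1L, NROW(xi))))

  # constants resolved from params are scalars; recycle limit values to one
  # per environment row so limits align with eval() output
  bcast <- function(f) {
    force(f)
    function(xi) rep_len(f(xi), if (is.matrix(xi)) nrow(xi) else 1L)
  }
  zero_limit <- bcast(zero_limit)
  infinity_limit <- bcast(infinity_limit)

  monotonicity <- switch(name,
    ricker = , beverton_holt = "decreasing",
    mate_limitation = , predator_saturation = ,
    liebhold_bascompte = "increasing",
    mate_limitation_ricker = , predator_saturation_ricker = "mixed")

  cf <- register_closed_form_(name, params, env)

  structure(list(
    name = name, params = params, env = env,
    monotonicity = monotonicity,
    eval = ev, zero_limit = zero_limit, infinity_limit = infinity_limit,
    log_fitness_closed_form = cf$logf,
    log_g_inf = cf$log_g_inf,
    model_id = model_id_(name, params, env)
  ), class = "fitness_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

model_id_ <- function(name, params, env) {
  pstr <- paste(names(params), vapply(params, function(v)
    if (is.numeric(v)) format(v, digits = 8) else "<fn>", ""),
    sep = "=", collapse = ",")
  estr <- paste(names(env$components),
                vapply(env$components, function(d) d$family, ""),
                sep = "~", collapse = ",")
  paste0(name, "(", pstr, "; ", estr, ")")
}

# Closed-form E[log f(x,.)] (a function of a density vector x) and
# E[log lim_{x->inf} f], registered only where the noise placement admits
# them; NULL otherwise (criteria then fall back to quadrature/Monte Carlo).
register_closed_form_ <- function(name, params, env) {
  cm <- function(nm) coord_mean_(env, params, nm)
  clm <- function(nm) tryCatch(coord_log_mean_(env, params, nm),
                               error = function(e) NULL)
  hconst <- is_const_coord_(env, params, "h") ||
    !"h" %in% FORMULA_PARAMS[[name]]
  hval <- if ("h" %in% FORMULA_PARAMS[[name]] && hconst)
    const_val_(env, params, "h")
  out <- list(logf = NULL, log_g_inf = NULL)

  if (name == "ricker") {
    Er <- cm("r"); Ea <- cm("a")
    out$logf <- function(x) Er - Ea * x
    out$log_g_inf <- if (Ea > 0) -Inf else Er
  } else if (name == "beverton_holt") {
    Ela <- clm("a")
    if (!is.null(Ela) && is_const_coord_(env, params, "b")) {
      b <- const_val_(env, params, "b")
      out$logf <- function(x) Ela - log(1 + b * x)
      out$log_g_inf <- if (b > 0) -Inf else Ela
    }
  } else if (name == "mate_limitation") {
    Ell <- clm("lambda")
    if (!is.null(Ell) && hconst) {
      out$logf <- function(x) ifelse(x == 0, -Inf, Ell + log(x / (hval + x)))
      out$log_g_inf <- Ell
    }
  } else if (name == "predator_saturation") {
    if (hconst) {
      Er <- cm("r"); EP <- cm("P")
      out$logf <- function(x) Er - EP / (hval + x)
      out$log_g_inf <- Er
    }
  } else if (name == "mate_limitation_ricker") {
    if (hconst) {
      Er <- cm("r"); Ea <- cm("a")
      out$logf <- function(x)
        ifelse(x == 0, -Inf, Er - Ea * x + log(x / (hval + x)))
      out$log_g_inf <- if (Ea > 0) -Inf else NULL
    }
  } else if (name == "predator_saturation_ricker") {
    if (hconst) {
      Er <- cm("r"); Ea <- cm("a"); EP <- cm("P")
      out$logf <- function(x) Er - Ea * x - EP / (hval + x)
      out$log_g_inf <- if (Ea > 0) -Inf else NULL
    }
  } else if (name == "liebhold_bascompte") {
    g <- const_val_(env, params, "gamma_lb")
    C <- const_val_(env, params, "c_lb")
    Exi <- if ("xi" %in% names(env$components))
      unname(env_mean(env$components[["xi"]])) else params$xi %||% 0
    out$logf <- function(x) g * (x - C) + Exi
    out$log_g_inf <- Inf
  }
  out
}

build_user_model_ <- function(params, env) {
  for (fld in c("eval", "monotonicity"))
    if (is.null(params[[fld]]))
      stop("user_defined model requires '", fld, "' in params")
  if (is.null(env)) stop("user_defined model requires an env")
  env <- if (inherits(env, "env_product")) env else env_product(env)
  mono <- match.arg(params$monotonicity, c("decreasing", "increasing", "mixed"))
  structure(list(
    name = "user_defined",
    params = params[setdiff(names(params),
                            c("eval", "monotonicity", "zero_limit",
                              "infinity_limit", "log_fitness_closed_form"))],
    env = env, monotonicity = mono,
    eval = params$eval,
    zero_limit = params$zero_limit %||% function(xi) params$eval(0, xi),
    infinity_limit = params$infinity_limit,
    log_fitness_closed_form = params$log_fitness_closed_form,
    log_g_inf = NULL,
    model_id = "user_defined"
  ), class = "fitness_model")
}

#' @export
print.fitness_model <- function(x, ...) {
  cat(sprintf("<fitness_model %s, %s>\n", x$name, x$monotonicity))
  if (length(x$params)) {
    num <- vapply(x$params, is.numeric, logical(1))
    cat("  constants:",
        paste(names(x$params)[num], signif(unlist(x$params[num]), 6),
              sep = "=", collapse = ", "), "\n")
  }
  cat("  environment:\n")
  for (nm in names(x$env$components)) {
    cat("    ", nm, " ~ ", sep = "")
    print(x$env$components[[nm]])
  }
  invisible(x)
}

#' The model catalogue
#'
#' @return data.frame of catalogue model names, formulas and monotonicity,
#'   for display (e.g. by the command-line `models` subcommand).
#' @export
model_catalogue <- function() {
  data.frame(
    name = c("ricker", "beverton_holt", "mate_limitation",
             "predator_saturation", "mate_limitation_ricker",
             "predator_saturation_ricker", "liebhold_bascompte"),
    formula = c("exp(r - a*x)", "a / (1 + b*x)", "lambda * x / (h + x)",
                "exp(r - P/(h + x))", "exp(r - a*x) * x/(h + x)",
                "exp(r - a*x - P/(h + x))", "exp(gamma_lb*(x - c_lb) + xi)"),
    monotonicity = c("decreasing", "decreasing", "increasing", "increasing",
                     "mixed", "mixed", "increasing"),
    stringsAsFactors = FALSE)
}

#' Numerically probe the monotonicity of a fitness model in density
#'
#' Finite-difference check of \eqn{x \mapsto f(x, \xi)} over sampled
#' environments, including the "increasing near zero" property (positive
#' density dependence on an initial prefix \eqn{[0, \gamma)} of the grid).
#'
#' @param model a `fitness_model`.
#' @param grid strictly increasing density grid (should start at or near 0).
#' @param n_env number of sampled environments.
#' @param seed integer seed.
#' @param tol slack for finite-difference sign tests.
#' @return list with logical `is_decreasing`, `is_increasing`,
#'   `increasing_near_zero`, the density `gamma_prefix` up to which `f` is
#'   increasing for every sampled environment, and a data.frame of
#'   `violation_points`.
#' @export
monotonicity_probe <- function(model, grid = c(0, 10^seq(-3, 1.3, length.out = 120)),
                               n_env = 32, seed = 1, tol = 1e-12) {
  stopifnot(length(grid) >= 3, all(diff(grid) > 0), n_env >= 1)
  xis <- sample_env(model$env, n_env, seed)
  dec <- TRUE; inc <- TRUE
  prefix_len <- length(grid)   # grid index up to which f increases for all xi
  viol <- list()
  for (i in seq_len(n_env)) {
    xi <- xis[i, , drop = FALSE]
    fx <- model$eval(grid, xi[rep(1, length(grid)), , drop = FALSE])
    d <- diff(fx)
    if (any(d > tol)) dec <- FALSE
    if (any(d < -tol)) inc <- FALSE
    firstdown <- which(d < -tol)
    if (length(firstdown)) {
      prefix_len <- min(prefix_len, firstdown[1])
      viol[[length(viol) + 1]] <-
        data.frame(env_row = i, x = grid[firstdown[1] + 1],
                   direction = "decrease")
    }
  }
  list(is_decreasing = dec,
       is_increasing = inc,
       increasing_near_zero = prefix_len > 1,
       gamma_prefix = grid[prefix_len],
       violation_points = if (length(viol)) do.call(rbind, viol) else
         data.frame(env_row = integer(), x = numeric(), direction = character()))
}

# TRUE when the model's fitness factors as xi * g(x) with a multiplicative
# factor whose support reaches down to 0 — the "large noise" case in which
# the log population can drop by an arbitrary amount in one step. For the
# catalogue, plain multipliers (lambda, Beverton-Holt a) qualify when
# lognormal or gamma; rates inside an exponential (r, the additive
# Liebhold-Bascompte noise) qualify when normal, since exp(r) is then
# lognormal. Falls back to the coordinate families for user-defined models.
mult_noise_unbounded_ <- function(model) {
  comps <- model$env$components
  plain <- switch(model$name,
                  mate_limitation = "lambda", beverton_holt = "a", character())
  expo <- switch(model$name,
                 ricker = , predator_saturation = , mate_limitation_ricker = ,
                 predator_saturation_ricker = "r",
                 liebhold_bascompte = "xi", character())
  if (model$name == "user_defined")
    return(any(vapply(comps, function(d)
      d$family %in% c("lognormal", "gamma"), logical(1))))
  for (nm in names(comps)) {
    fam <- comps[[nm]]$family
    if (nm %in% plain && fam %in% c("lognormal", "gamma")) return(TRUE)
    if (nm %in% expo && fam == "normal") return(TRUE)
  }
  FALSE
}

#' Serialize / deserialize a catalogue model specification
#'
#' @param model a catalogue `fitness_model` (not `user_defined`).
#' @return `model_to_list()`: plain list (YAML-ready); `model_from_list()`:
#'   the rebuilt model.
#' @export
model_to_list <- function(model) {
  if (model$name == "user_defined")
    stop("user_defined models are not serializable")
  list(name = model$name,
       params = model$params,
       env = env_to_list(model$env))
}

#' @rdname model_to_list
#' @param spec list as produced by `model_to_list()`.
#' @export
model_from_list <- function(spec) {
  envspec <- spec$env
  env <- if (is.null(envspec)) NULL else env_from_list(envspec)
  build_model(spec$name, params = spec$params, env = env)
}
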