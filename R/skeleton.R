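# Deterministic skeleton analysis: the noise-free map F0(x) = x f(x, xi_bar)
# at the mean environment. Its smallest positive fixed point M and critical
# point C drive the dichotomy F0(F0(C)) > M (positive attractor) versus
# F0(F0(C)) < M (essential extinction), and small-noise invariant intervals
# certify conditional persistence for compactly supported perturbations.

#' Deterministic skeleton of a stochastic fitness model
#'
#' Builds the unperturbed map \eqn{F_0(x) = x f(x, \bar\xi)} where
#' \eqn{\bar\xi} is the coordinatewise mean of the environment distribution
#' (for the uniform noise families this is the natural center of the noise
#' interval).
#'
#' @param model a `fitness_model` whose environment has finite coordinate
#'   means.
#' @return list of class `skeleton_map`: `F0` (vectorized map), `fbar`
#'   (fitness at the reference environment), `xi_bar` (named vector).
#' @export
skeleton_map <- function(model) {
  xi_bar <- env_mean(model$env)
  if (any(!is.finite(xi_bar)))
    stop("environment coordinate(s) with undefined mean: ",
         paste(names(xi_bar)[!is.finite(xi_bar)], collapse = ", "))
  fbar <- function(x) {
    m <- matrix(rep(xi_bar, each = length(x)), nrow = length(x),
                dimnames = list(NULL, names(xi_bar)))
    model$eval(x, m)
  }
  structure(list(F0 = function(x) x * fbar(x), fbar = fbar, xi_bar = xi_bar),
            class = "skeleton_map")
}

#' Smallest positive fixed point of a deterministic map
#'
#' Brackets sign changes of \eqn{F_0(x) - x} on a log-spaced grid and
#' refines the smallest bracketed root by bisection.
#'
#' @param F0 vectorized map (or a `skeleton_map`).
#' @param x_max upper end of the search range; `F0(x) < x` must hold there
#'   (checked).
#' @param grid_n number of log-spaced grid points.
#' @param x_min lower end of the search range.
#' @return The smallest positive fixed point, or `NULL` when `F0(x) - x`
#'   never changes sign on the grid.
#' @export
smallest_positive_fixed_point <- function(F0, x_max = 50, grid_n = 1000,
                                          x_min = 1e-10) {
  if (inherits(F0, "skeleton_map")) F0 <- F0$F0
  if (!(F0(x_max) < x_max))
    stop("x_max insufficient: F0(x_max) >= x_max; enlarge the search range")
  xs <- exp(seq(log(x_min), log(x_max), length.out = grid_n))
  d <- F0(xs) - xs
  sc <- which(d[-1] * d[-length(d)] < 0)
  exact <- which(d == 0 & xs > 0)
  if (length(exact) && (!length(sc) || exact[1] <= sc[1]))
    return(xs[exact[1]])
  if (!length(sc)) return(NULL)
  i <- sc[1]
  stats::uniroot(function(x) F0(x) - x, c(xs[i], xs[i + 1]),
                 tol = 1e-10 * max(1, xs[i]))$root
}

#' Critical point (maximizer) of a unimodal deterministic map
#'
#' Locates the maximizer of \eqn{F_0} on `(0, x_max]` by bracketed scalar
#' maximization, after verifying unimodality on a probe grid.
#'
#' @param F0 vectorized map (or a `skeleton_map`).
#' @param x_max upper end of the range.
#' @param grid_n probe grid size for the unimodality check.
#' @return The critical point `C`. If `F0` is still increasing at `x_max`
#'   (no interior maximum), returns `x_max` with attribute
#'   `boundary = TRUE`. Multiple interior local maxima raise an error.
#' @export
critical_point <- function(F0, x_max = 50, grid_n = 4000) {
  if (inherits(F0, "skeleton_map")) F0 <- F0$F0
  xs <- exp(seq(log(1e-8), log(x_max), length.out = grid_n))
  v <- F0(xs)
  d <- diff(v)
  # indices where the finite difference turns from + to -
  turns <- which(d[-1] < 0 & d[-length(d)] > 0)
  if (length(turns) > 1) {
    # tolerate numerically flat wiggles, fail on genuine multimodality
    peaks <- xs[turns + 1]
    vals <- v[turns + 1]
    keep <- vals > max(vals) * (1 - 1e-9)
    if (sum(!keep) != length(keep) - 1 && length(unique(signif(peaks, 6))) > 1 &&
        any(!keep))
      peaks <- peaks[keep]
    if (length(peaks) > 1)
      stop("multiple local maxima detected (unimodality violated) near x = ",
           paste(signif(peaks, 6), collapse = ", "))
  }
  if (!length(turns)) {
    if (d[length(d)] > 0) {
      C <- x_max
      attr(C, "boundary") <- TRUE
      return(C)
    }
    # decreasing from the start: maximum at the lower end
    turns <- 1L
  }
  i <- turns[1]
  lo <- xs[max(1, i - 1)]; hi <- xs[min(length(xs), i + 2)]
  C <- stats::optimize(F0, c(lo, hi), maximum = TRUE,
                       tol = 1e-9 * max(1, lo))$maximum
  # optimize() stalls at sqrt(machine-eps) accuracy on a flat maximum;
  # refine via the sign change of a central-difference derivative
  h <- 1e-6 * max(1, abs(C))
  dF <- function(x) F0(x + h) - F0(x - h)
  lo2 <- C - 64 * h; hi2 <- C + 64 * h
  if (lo2 > 0 && dF(lo2) > 0 && dF(hi2) < 0)
    C <- stats::uniroot(dF, c(lo2, hi2), tol = 1e-12 * max(1, C))$root
  C
}

#' Full deterministic-skeleton classification
#'
#' Computes the smallest positive fixed point `M`, the critical point `C`,
#' `FC = F0(C)`, `FFC = F0(F0(C))` and applies the dichotomy: `FFC > M`
#' means a positive attractor in `(M, Inf)`, `FFC < M` means essential
#' extinction (asymptotic extinction from Lebesgue-almost-every start).
#' Two shortcut branches precede it: fitness above one at zero density
#' (`f(0, xi_bar) > 1`) gives a positive attractor whose basin is all
#' positive densities (no Allee threshold), and fitness below one at every
#' density gives global extinction.
#'
#' @param model a `fitness_model`.
#' @param x_max search range for fixed points and the critical point.
#' @param boundary_tol half-width of the `|FFC - M|` band inside which the
#'   verdict is `BOUNDARY` (classification numerically meaningless).
#' @return Object of class `skeleton_report`: `M`, `C`, `FC`, `FFC`,
#'   `verdict` (`POSITIVE_ATTRACTOR`, `ESSENTIAL_EXTINCTION`,
#'   `NO_ALLEE_PERSISTENCE`, `GLOBAL_EXTINCTION`, `BOUNDARY`),
#'   `attractor_interval` (orbit hull, when an attractor exists),
#'   `xi_bar`, `f0` (zero-density skeleton fitness).
#' @export
classify_skeleton <- function(model, x_max = 50, boundary_tol = 1e-8) {
  sk <- skeleton_map(model)
  f0 <- sk$fbar(0)
  xs <- exp(seq(log(1e-8), log(x_max), length.out = 4000))

  orbit_hull <- function(start) {
    x <- start
    for (i in 1:1000) x <- sk$F0(x)          # burn-in
    orb <- numeric(2000)
    for (i in 1:2000) { x <- sk$F0(x); orb[i] <- x }
    range(orb)
  }

  finish <- function(verdict, M = NULL, C = NULL, FC = NULL, FFC = NULL,
                     hull = NULL)
    structure(list(M = M, C = C, FC = FC, FFC = FFC, verdict = verdict,
                   attractor_interval = hull, xi_bar = sk$xi_bar, f0 = f0),
              class = "skeleton_report")

  if (f0 > 1) {
    M <- tryCatch(smallest_positive_fixed_point(sk$F0, x_max),
                  error = function(e) NULL)
    C <- tryCatch(critical_point(sk$F0, x_max), error = function(e) NULL)
    FC <- if (!is.null(C)) sk$F0(as.numeric(C))
    FFC <- if (!is.null(FC)) sk$F0(FC)
    start <- if (!is.null(C)) as.numeric(C) else 1
    return(finish("NO_ALLEE_PERSISTENCE", M, C, FC, FFC, orbit_hull(start)))
  }

  if (all(sk$fbar(xs) < 1))
    return(finish("GLOBAL_EXTINCTION"))

  M <- smallest_positive_fixed_point(sk$F0, x_max)
  if (is.null(M))
    return(finish("GLOBAL_EXTINCTION"))
  C <- critical_point(sk$F0, x_max)
  FC <- sk$F0(as.numeric(C))
  FFC <- sk$F0(FC)
  if (abs(FFC - M) <= boundary_tol * max(1, M))
    return(finish("BOUNDARY", M, C, FC, FFC))
  if (FFC > M)
    return(finish("POSITIVE_ATTRACTOR", M, C, FC, FFC,
                  orbit_hull(as.numeric(C))))
  finish("ESSENTIAL_EXTINCTION", M, C, FC, FFC)
}

#' @export
print.skeleton_report <- function(x, ...) {
  cat(sprintf("<skeleton_report: %s>\n", x$verdict))
  if (!is.null(x$M)) cat(sprintf("  M   = %.8g\n", x$M))
  if (!is.null(x$C)) cat(sprintf("  C   = %.8g\n", as.numeric(x$C)))
  if (!is.null(x$FC)) cat(sprintf("  F(C)    = %.8g\n", x$FC))
  if (!is.null(x$FFC)) cat(sprintf("  F(F(C)) = %.8g\n", x$FFC))
  if (!is.null(x$attractor_interval))
    cat(sprintf("  attractor hull = [%.6g, %.6g]\n",
                x$attractor_interval[1], x$attractor_interval[2]))
  invisible(x)
}

#' Certify a positive invariant interval under bounded noise
#'
#' Searches for an interval \eqn{[\alpha, \beta]} containing the skeleton's
#' attractor hull such that \eqn{F(x, \xi) = f(x, \xi) x} stays inside
#' \eqn{[\alpha, \beta]} for every grid density in it and every extreme of
#' the (bounded) noise support — a numerical certificate that trajectories
#' started inside never leave, hence conditional persistence under small
#' compact noise. Extremes are the corners of the support box, which bound
#' `F` for the catalogue models because fitness is monotone in each
#' environmental coordinate; absence of a certificate is reported as
#' `NULL`, not as a claim of non-existence.
#'
#' @param model a `fitness_model` with bounded-support noise.
#' @param report a `skeleton_report` with verdict `POSITIVE_ATTRACTOR` (or
#'   `NO_ALLEE_PERSISTENCE`).
#' @param n_grid density grid resolution of the certificate.
#' @param max_expand maximum number of interval-expansion sweeps.
#' @return list with `interval` (`c(alpha, beta)`), `n_grid` and the noise
#'   `corners` used, or `NULL` if no certificate was found.
#' @export
invariant_interval <- function(model, report, n_grid = 4000, max_expand = 200) {
  if (!env_bounded_support(model$env))
    stop("invariant_interval requires bounded-support noise")
  if (!report$verdict %in% c("POSITIVE_ATTRACTOR", "NO_ALLEE_PERSISTENCE"))
    stop("invariant_interval requires a skeleton verdict with a positive attractor")
  if (is.null(report$attractor_interval))
    stop("skeleton report carries no attractor interval")

  sup <- as_env_product(model$env)$support
  corners <- as.matrix(expand.grid(lapply(seq_len(nrow(sup)), function(i)
    unique(sup[i, ]))))
  colnames(corners) <- rownames(sup)

  al <- report$attractor_interval[1]
  be <- report$attractor_interval[2]
  floorM <- if (!is.null(report$M)) report$M else 0
  for (sweep in seq_len(max_expand)) {
    xg <- seq(al, be, length.out = n_grid)
    lo <- Inf; hi <- -Inf
    for (k in seq_len(nrow(corners))) {
      xi <- corners[rep(k, n_grid), , drop = FALSE]
      Fx <- xg * model$eval(xg, xi)
      lo <- min(lo, min(Fx)); hi <- max(hi, max(Fx))
    }
    if (lo >= al && hi <= be)
      return(list(interval = c(al, be), n_grid = n_grid, corners = corners,
                  sweeps = sweep))
    al <- min(al, lo); be <- max(be, hi)
    if (al <= floorM) return(NULL)   # would dip to/below the Allee fixed point
  }
  NULL
}

#' Small-noise unconditional-extinction check
#'
#' When the skeleton has no positive attractor (essential or global
#' extinction), the noise has bounded support, the low-density assumptions
#' hold (strong stochastic Allee effect `A1`, positive density dependence
#' near zero `A2`), and the skeleton is numerically dissipative (a compact
#' interval absorbs every start), small compactly supported noise forces
#' asymptotic extinction from every initial density. This check reports
#' that conclusion or `NO_CONCLUSION` with the failing precondition.
#'
#' @param model a `fitness_model`.
#' @param report a `skeleton_report`.
#' @param assumptions optional result of [check_assumptions()]; computed if
#'   missing.
#' @param x_max range for the dissipativity probe.
#' @param T_diss iterations of the dissipativity probe.
#' @return list with `verdict` (`"UNCONDITIONAL_EXTINCTION_SMALL_NOISE"` or
#'   `"NO_CONCLUSION"`) and `reasons` (character).
#' @export
small_noise_extinction_check <- function(model, report, assumptions = NULL,
                                         x_max = 50, T_diss = 100) {
  reasons <- character()
  if (!env_bounded_support(model$env))
    reasons <- c(reasons, "noise support unbounded (not epsilon-small)")
  if (!report$verdict %in% c("ESSENTIAL_EXTINCTION", "GLOBAL_EXTINCTION"))
    reasons <- c(reasons, "skeleton has a positive attractor (or is at boundary)")
  if (length(reasons))
    return(list(verdict = "NO_CONCLUSION", reasons = reasons))

  if (is.null(assumptions))
    assumptions <- check_assumptions(model)
  if (!assumptions$A1$holds)
    reasons <- c(reasons, "A1 fails: G(0) not below 1")
  if (!assumptions$A2$holds)
    reasons <- c(reasons, "A2 fails: fitness not increasing near zero density")

  # dissipativity: every start in (0, x_max] is drawn into a compact
  # interval bounded by the map's maximum after a few iterations
  sk <- skeleton_map(model)
  starts <- exp(seq(log(1e-6), log(x_max), length.out = 200))
  x <- starts
  for (i in seq_len(T_diss)) x <- sk$F0(x)
  bound <- max(sk$F0(exp(seq(log(1e-8), log(x_max), length.out = 4000))))
  dissipative <- all(is.finite(x)) && max(x) <= max(bound, 1) + 1e-9
  if (!dissipative)
    reasons <- c(reasons, "dissipativity not confirmed numerically")

  if (length(reasons))
    return(list(verdict = "NO_CONCLUSION", reasons = reasons))
  list(verdict = "UNCONDITIONAL_EXTINCTION_SMALL_NOISE",
       reasons = "no positive attractor + A1 + A2 + dissipative skeleton + bounded noise")
}
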