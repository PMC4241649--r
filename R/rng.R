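# Seeded RNG plumbing. Every stochastic operation in the package takes an
# explicit integer seed; nothing relies on (or perturbs) the caller's global
# RNG state. Replicated operations draw independent L'Ecuyer-CMRG streams
# spawned deterministically from the seed, so sub-ensembles never collide
# the way seed+i arithmetic can.

#' Evaluate an expression under a local, seeded RNG state
#'
#' Saves the caller's `.Random.seed`, switches to the L'Ecuyer-CMRG
#' generator seeded with `seed`, evaluates `code`, and restores the previous
#' state on exit. All randomness inside the package funnels through this
#' helper (or [rng_substreams()]), which is what makes every exported
#' stochastic operation bit-reproducible for a fixed seed.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  suppressWarnings(set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG"))
  force(code)
}

#' Spawn independent RNG substreams from one seed
#'
#' Returns `n` L'Ecuyer-CMRG stream states derived deterministically from
#' `seed` via `parallel::nextRNGStream()`. Stream `i` is always the same for
#' a given `(seed, i)` regardless of how many streams are requested.
#'
#' @param seed integer scalar seed.
#' @param n number of streams.
#' @return list of `n` `.Random.seed`-compatible integer vectors.
#' @keywords internal
rng_substreams <- function(seed, n) {
  with_seed(seed, {
    s <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    streams <- vector("list", n)
    for (i in seq_len(n)) {
      s <- parallel::nextRNGStream(s)
      streams[[i]] <- s
    }
    streams
  })
}

#' Evaluate an expression with the RNG positioned on a given stream state
#' @keywords internal
#' @noRd
with_stream <- function(stream, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  assign(".Random.seed", stream, envir = env)
  force(code)
}
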