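# Shared model builders and independent oracles used across the suite.

ricker_normal <- function(mean, sd, a = 1) {
  build_model("ricker", params = list(a = a),
              env = list(r = env_dist("normal", mean = mean, sd = sd)))
}

mlr_point <- function(r, a = 1, h = 10) {
  build_model("mate_limitation_ricker", params = list(a = a, h = h),
              env = list(r = env_dist("point_mass", value = r)))
}

mlr_uniform <- function(center, eps, a = 1, h = 10) {
  build_model("mate_limitation_ricker", params = list(a = a, h = h),
              env = list(r = env_dist("uniform", center = center,
                                      halfwidth = eps)))
}

psr_fig <- function(Pbar, eps = 0.2, r = 4, a = 4, h = 1 / 12) {
  build_model("predator_saturation_ricker", params = list(r = r, a = a, h = h),
              env = list(P = env_dist("uniform", lower = Pbar * (1 - eps),
                                      upper = Pbar * (1 + eps))))
}

# Independent brute-force skeleton oracle: dense grid + stats root/optimum
# refinement applied directly to a supplied scalar map, bypassing the
# package's skeleton code path.
skeleton_oracle <- function(F0, x_max = 50, n_grid = 1e4) {
  xs <- exp(seq(log(1e-8), log(x_max), length.out = n_grid))
  d <- vapply(xs, F0, numeric(1)) - xs
  sc <- which(d[-1] * d[-length(d)] < 0)
  M <- if (length(sc))
    stats::uniroot(function(x) F0(x) - x, c(xs[sc[1]], xs[sc[1] + 1]),
                   tol = 1e-14)$root else NULL
  C0 <- xs[which.max(vapply(xs, F0, numeric(1)))]
  h <- 2e-6 * max(1, C0)
  C <- stats::uniroot(function(x) F0(x + h) - F0(x - h),
                      c(C0 * 0.9, C0 * 1.1), tol = 1e-13)$root
  FC <- F0(C)
  FFC <- F0(FC)
  list(M = M, C = C, FC = FC, FFC = FFC)
}
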