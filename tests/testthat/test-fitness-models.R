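test_that("catalogue formulas evaluate correctly at spot-check points", {
  ml <- build_model("mate_limitation", params = list(h = 10),
                    env = list(lambda = env_dist("point_mass", value = exp(0.1))))
  expect_equal(ml$eval(10, cbind(lambda = exp(0.1))), exp(0.1) * 10 / 20)
  expect_equal(ml$zero_limit(cbind(lambda = exp(0.1))), 0)
  expect_equal(ml$infinity_limit(cbind(lambda = exp(0.1))), exp(0.1))

  psr <- psr_fig(0.5, eps = 0)
  for (P in c(0.2, 0.5, 1))
    expect_equal(psr$eval(0, cbind(P = P)), exp(4 - 12 * P))

  bh <- build_model("beverton_holt", params = list(b = 0.5),
                    env = list(a = env_dist("point_mass", value = 2)))
  expect_equal(bh$eval(2, cbind(a = 2)), 2 / (1 + 1))
})

test_that("zero and infinity limits agree with eval at the extremes", {
  models <- list(
    ricker_normal(0.3, 0.5),
    build_model("predator_saturation", params = list(r = 1, h = 1),
                env = list(P = env_dist("uniform", center = 0.8, halfwidth = 0.2))),
    mate_limitation_model(0.5),
    mlr_uniform(4.5, 0.5))
  for (m in models) {
    xi <- sample_env(m$env, 8, seed = 21)
    expect_equal(m$eval(0, xi), m$zero_limit(xi), tolerance = 1e-12)
    expect_equal(m$eval(1e8, xi), m$infinity_limit(xi), tolerance = 1e-6)
  }
})

test_that("combined models reduce to their pure limits", {
  # predator-saturation-Ricker with P = 0 is the Ricker map
  psr0 <- build_model("predator_saturation_ricker",
                      params = list(a = 1, h = 1 / 12),
                      env = list(r = env_dist("point_mass", value = 2),
                                 P = env_dist("point_mass", value = 0)))
  rk <- build_model("ricker", params = list(a = 1),
                    env = list(r = env_dist("point_mass", value = 2)))
  x <- seq(0, 10, length.out = 101)
  expect_equal(psr0$eval(x, cbind(r = 2, P = 0)), rk$eval(x, cbind(r = 2)))

  # mate-limitation-Ricker with a = 0 and r = log(lambda) is mate limitation
  mlr0 <- build_model("mate_limitation_ricker", params = list(a = 0, h = 10),
                      env = list(r = env_dist("point_mass", value = 0.1)))
  ml <- build_model("mate_limitation", params = list(h = 10),
                    env = list(lambda = env_dist("point_mass", value = exp(0.1))))
  expect_equal(mlr0$eval(x, cbind(r = 0.1)), ml$eval(x, cbind(lambda = exp(0.1))))
})

test_that("closed-form E[log f] matches quadrature on a density grid", {
  models <- list(
    ricker_normal(0.3, 0.5),
    build_model("beverton_holt", params = list(b = 0.5),
                env = list(a = env_dist("lognormal", logmean = 0.4, logsd = 0.3))),
    mate_limitation_model(0.5),
    build_model("predator_saturation", params = list(r = 1, h = 1),
                env = list(P = env_dist("uniform", center = 0.8, halfwidth = 0.2))),
    mlr_uniform(4.5, 0.5),
    psr_fig(0.5))
  grid <- 10^seq(-2, 1.2, length.out = 50)
  for (m in models) {
    expect_false(is.null(m$log_fitness_closed_form), info = m$name)
    for (x in grid[c(1, 17, 34, 50)]) {
      q <- geo_mean_fitness(m, x, method = "quadrature")
      expect_lt(abs(m$log_fitness_closed_form(x) - q$log_G), 1e-8)
    }
  }
})

test_that("monotonicity probe recovers the known shapes", {
  rk <- monotonicity_probe(ricker_normal(0.3, 0.5), seed = 2)
  expect_true(rk$is_decreasing)
  expect_false(rk$is_increasing)
  expect_false(rk$increasing_near_zero)

  ml <- monotonicity_probe(mate_limitation_model(0.5), seed = 2)
  expect_true(ml$is_increasing)
  expect_false(ml$is_decreasing)
  expect_true(ml$increasing_near_zero)

  # mixed: increasing near 0, turning at the root of 1/x - 1/(x+h) = a,
  # i.e. x* = (-h + sqrt(h^2 + 4h)) / 2 ~ 0.9161 for a = 1, h = 10
  mx <- monotonicity_probe(mlr_uniform(4.5, 0.5),
                           grid = c(0, 10^seq(-3, 1, length.out = 400)),
                           seed = 2)
  expect_false(mx$is_increasing)
  expect_false(mx$is_decreasing)
  expect_true(mx$increasing_near_zero)
  xstar <- (-10 + sqrt(100 + 40)) / 2
  expect_lt(abs(mx$gamma_prefix - xstar) / xstar, 0.05)
})

test_that("builder rejects malformed specifications", {
  expect_error(build_model("nonesuch", params = list()), "arg")
  expect_error(build_model("ricker", params = list(a = 1)), "missing parameter")
  expect_error(build_model("ricker", params = list(r = 1, a = 1),
                           env = list(h = env_dist("point_mass", value = 1))),
               "not parameters")
})

test_that("model specs round-trip through plain lists", {
  m <- mlr_uniform(4.5, 0.5)
  back <- model_from_list(model_to_list(m))
  x <- c(0, 0.5, 2, 10)
  xi <- sample_env(m$env, 4, seed = 9)
  expect_equal(back$eval(x, xi), m$eval(x, xi))
  expect_identical(back$monotonicity, m$monotonicity)
})
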