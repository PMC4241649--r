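test_that("geometric-mean fitness: closed forms and sentinel cases", {
  rk <- build_model("ricker", params = list(a = 1),
                    env = list(r = env_dist("normal", mean = 0.5, sd = 0.2)))
  expect_equal(geo_mean_fitness(rk, 0)$G, exp(0.5))

  ml <- mate_limitation_model(0.5)
  expect_identical(geo_mean_fitness(ml, 0)$G, 0)            # f(0,.) = 0
  expect_equal(geo_mean_fitness(ml, Inf)$G, exp(0.1))       # E[log lambda]

  f3 <- psr_fig(1 / 3)
  expect_equal(geo_mean_fitness(f3, 0)$G, 1)                # exp(4 - 12 Pbar)
  ud <- build_model("user_defined",
                    params = list(eval = function(x, xi) exp(xi[, "r"] - x),
                                  monotonicity = "decreasing"),
                    env = list(r = env_dist("normal", mean = 0, sd = 1)))
  expect_error(geo_mean_fitness(ud, Inf), "infinity_limit")
})

test_that("Monte-Carlo and quadrature G agree within 4 standard errors", {
  models <- list(ricker_normal(0.3, 0.5), mlr_uniform(4.5, 0.5), psr_fig(0.5))
  for (m in models) {
    for (x in c(0.1, 1, 5)) {
      q <- geo_mean_fitness(m, x, method = "quadrature")
      mc <- geo_mean_fitness(m, x, method = "monte_carlo", budget = 2e4,
                             seed = 19)
      expect_lt(abs(mc$log_G - q$log_G), 4 * mc$error)
    }
  }
})

test_that("G is monotone in density according to the model's monotonicity", {
  grid <- 10^seq(-2, 1.5, length.out = 40)
  dec <- ricker_normal(0.3, 0.5)
  Gd <- vapply(grid, function(x) geo_mean_fitness(dec, x)$log_G, numeric(1))
  expect_true(all(diff(Gd) <= 1e-12))

  inc <- mate_limitation_model(0.5)
  Gi <- vapply(grid, function(x) geo_mean_fitness(inc, x)$log_G, numeric(1))
  expect_true(all(diff(Gi) >= -1e-12))
})

test_that("regime classification follows the trichotomies", {
  expect_equal(classify_regime(ricker_normal(0.3, 0.5))$regime,
               "STOCHASTIC_PERSISTENCE")
  expect_equal(classify_regime(ricker_normal(-0.2, 0.5))$regime,
               "UNCONDITIONAL_EXTINCTION")
  expect_equal(classify_regime(mate_limitation_model(0.5))$regime,
               "CONDITIONAL_PERSISTENCE")
  expect_equal(classify_regime(mate_limitation_model(0.5, log_mean = -0.1))$regime,
               "UNCONDITIONAL_EXTINCTION")

  # unbounded growth: predator saturation with G(0) > 1
  ps_up <- build_model("predator_saturation", params = list(r = 1, h = 2),
                       env = list(P = env_dist("uniform", center = 0.5,
                                               halfwidth = 0.1)))
  expect_equal(classify_regime(ps_up)$regime, "UNBOUNDED_GROWTH")

  # mixed with G(0) > 1 and decreasing tail: stochastic persistence
  f3lo <- psr_fig(0.25)
  rep_lo <- classify_regime(f3lo)
  expect_equal(rep_lo$regime, "STOCHASTIC_PERSISTENCE")
  expect_match(rep_lo$criterion, "decreasing tail")

  # mixed, G(0) < 1, small compact noise: skeleton decides
  expect_equal(classify_regime(mlr_uniform(4.5, 0.05))$regime,
               "CONDITIONAL_PERSISTENCE")
  expect_equal(classify_regime(mlr_uniform(7, 0.05))$regime,
               "UNCONDITIONAL_EXTINCTION")

  # mixed, G(0) < 1, unbounded multiplicative noise: large-noise extinction
  mlr_ln <- build_model("mate_limitation_ricker", params = list(a = 1, h = 10),
                        env = list(r = env_dist("normal", mean = 4.5, sd = 0.5)))
  rep_ln <- classify_regime(mlr_ln)
  expect_equal(rep_ln$regime, "UNCONDITIONAL_EXTINCTION")
  expect_match(rep_ln$criterion, "large-noise")

  # criticality: G(0) = 1 exactly is indeterminate
  expect_equal(classify_regime(psr_fig(1 / 3))$regime, "INDETERMINATE")
})

test_that("regime verdicts are corroborated by simulated ensembles", {
  cases <- list(
    list(m = ricker_normal(0.3, 0.5), x0 = 1, want = "INTERIOR", frac = 0.95),
    list(m = ricker_normal(-0.3, 0.5), x0 = 1, want = "EXTINCT", frac = 0.95),
    list(m = mlr_uniform(7, 0.05), x0 = 1, want = "EXTINCT", frac = 0.95))
  for (cs in cases) {
    fin <- simulate_ensemble(cs$m, cs$x0, 2000, 200, seed = 23)$final
    expect_gte(mean(classify_run(fin) == cs$want), cs$frac)
  }
  # conditional persistence: both fates occur from an interior start
  ml <- mate_limitation_model(0.5)
  v <- classify_run(simulate_ensemble(ml, 95, 2000, 200, seed = 23)$final)
  expect_gt(sum(v == "EXTINCT"), 0)
  expect_gt(sum(v == "EXPLODED"), 0)
})

test_that("assumption checks report A1/A2/tail/boundedness with evidence", {
  chk <- check_assumptions(mlr_point(4.5))
  expect_true(chk$A1$holds)           # G(0) = 0 < 1
  expect_true(chk$A2$holds)
  expect_gt(chk$A2$gamma_prefix, 0.5) # increasing prefix up to ~0.916
  expect_true(chk$boundedness$holds)

  rk <- check_assumptions(ricker_normal(0.3, 0.5))
  expect_false(rk$A2$holds)           # decreasing everywhere

  ps <- check_assumptions(
    build_model("predator_saturation", params = list(r = 1, h = 2),
                env = list(P = env_dist("uniform", center = 0.5, halfwidth = 0.1))))
  expect_false(ps$A1$holds)           # G(0) = exp(1 - 0.25) > 1

  # mixed model with G(0) > 1: tail pivot found beyond the log-f maximizer
  tl <- check_assumptions(psr_fig(0.25))
  expect_true(tl$tail$holds)
  expect_true(is.finite(tl$tail$x_c))
})

test_that("arithmetic-geometric gap is zero without noise, positive with it", {
  det <- mlr_point(4.5)
  j0 <- jensen_gap(det, 2)
  expect_equal(j0$gap, 0, tolerance = 1e-12)

  # fluctuating predator half-saturation: Jensen shifts G(0) down
  ps_h <- build_model("predator_saturation", params = list(r = 1, P = 1),
                      env = list(h = env_dist("lognormal", logmean = 0,
                                              logsd = 0.6)))
  G0 <- geo_mean_fitness(ps_h, 0, method = "quadrature")$G
  expect_lt(G0, exp(1 - 1 / exp(0 + 0.6^2 / 2)))  # below fitness at mean h
  j <- jensen_gap(ps_h, 0)
  expect_gt(j$gap, 0)

  # AM-GM across catalogue models and densities
  for (m in list(ricker_normal(0.3, 0.5), mate_limitation_model(0.5),
                 psr_fig(0.5))) {
    for (x in c(0.5, 2, 8))
      expect_gte(jensen_gap(m, x)$gap, -1e-10)
  }
})
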