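test_that("skeleton map evaluates at the mean environment", {
  m <- build_model("ricker", params = list(a = 1),
                   env = list(r = env_dist("uniform", lower = 4, upper = 5)))
  sk <- skeleton_map(m)
  expect_equal(unname(sk$xi_bar["r"]), 4.5)
  x <- c(0, 0.5, 1, 3)
  expect_equal(sk$F0(x), x * exp(4.5 - x))
  expect_identical(sk$F0(0), 0)

  # point-mass environment: skeleton coincides with the stochastic map
  det <- mlr_point(4.5)
  skd <- skeleton_map(det)
  expect_equal(skd$F0(2), 2 * det$eval(2, cbind(r = 4.5)))
})

test_that("smallest positive fixed point: closed forms and absence", {
  F_r <- function(r) function(x) x * exp(r - x)
  expect_equal(smallest_positive_fixed_point(F_r(0.5)), 0.5,
               tolerance = 1e-9)                     # r / a
  expect_null(smallest_positive_fixed_point(F_r(-1)))
  expect_error(smallest_positive_fixed_point(function(x) x * 2, x_max = 50),
               "x_max insufficient")
})

test_that("critical point: closed form, boundary flag, multimodality error", {
  expect_equal(critical_point(function(x) x * exp(4.5 - x)), 1,
               tolerance = 1e-8)                     # C = 1/a for Ricker
  Cb <- critical_point(function(x) x / (10 + x) * 10, x_max = 50)
  expect_true(isTRUE(attr(Cb, "boundary")))
  expect_equal(as.numeric(Cb), 50)
  bimodal <- function(x) x * (exp(-(x - 1)^2) + 1.5 * exp(-(x - 8)^2 / 4))
  expect_error(critical_point(bimodal, x_max = 20), "local maxima")
})

test_that("skeleton quantities match the brute-force oracle to 1e-8", {
  for (r in c(4.5, 7)) {
    m <- mlr_point(r)
    rep <- classify_skeleton(m)
    orc <- skeleton_oracle(function(x) x * exp(r - x) * x / (10 + x))
    expect_lt(abs(rep$M - orc$M) / orc$M, 1e-8)
    expect_lt(abs(as.numeric(rep$C) - orc$C) / orc$C, 1e-8)
    expect_lt(abs(rep$FC - orc$FC) / orc$FC, 1e-8)
    expect_lt(abs(rep$FFC - orc$FFC) / max(orc$FFC, 1e-20), 1e-6)
    # internal consistency: M is fixed, C is a critical point
    sk <- skeleton_map(m)
    expect_lt(abs(sk$F0(rep$M) - rep$M), 1e-8 * max(1, rep$M))
  }
  expect_equal(classify_skeleton(mlr_point(4.5))$verdict, "POSITIVE_ATTRACTOR")
  expect_equal(classify_skeleton(mlr_point(7))$verdict, "ESSENTIAL_EXTINCTION")
})

test_that("skeleton shortcut branches: no-Allee persistence, global extinction", {
  expect_equal(classify_skeleton(psr_fig(0.25))$verdict, "NO_ALLEE_PERSISTENCE")
  expect_equal(classify_skeleton(psr_fig(1.4))$verdict, "GLOBAL_EXTINCTION")
  expect_equal(classify_skeleton(mlr_point(-1))$verdict, "GLOBAL_EXTINCTION")
})

test_that("attractor hull is consistent with noiseless ensembles", {
  rep <- classify_skeleton(mlr_point(4.5))
  hull <- rep$attractor_interval
  expect_true(hull[1] > rep$M)
  traj <- iterate(mlr_point(4.5), x0 = as.numeric(rep$C), T = 3000, seed = 1)
  tailpts <- traj$densities[1001:3001]
  expect_true(all(tailpts >= hull[1] - 1e-9 & tailpts <= hull[2] + 1e-9))
})

test_that("invariant interval certificates exist for small noise and are sound", {
  m_small <- mlr_uniform(4.5, 0.05)
  rep <- classify_skeleton(m_small)
  cert <- invariant_interval(m_small, rep)
  expect_false(is.null(cert))
  al <- cert$interval[1]; be <- cert$interval[2]
  expect_true(al > rep$M)

  # simulated trajectories started inside never leave
  sim <- simulate_ensemble(m_small, x0 = rep(seq(al, be, length.out = 20), 2),
                           T = 2000, n_reps = 40, seed = 3,
                           keep_paths = TRUE)
  expect_true(all(sim$paths >= al - 1e-9 & sim$paths <= be + 1e-9))

  # zero noise: the attractor hull itself certifies
  det <- mlr_uniform(4.5, 0)
  cert0 <- invariant_interval(det, classify_skeleton(det))
  expect_false(is.null(cert0))

  # large noise: no certificate, and low densities become reachable
  m_big <- mlr_uniform(4.5, 4.2)
  expect_null(invariant_interval(m_big, classify_skeleton(m_big)))
  probe <- min_density_probe(m_big, x0 = 2, T = 500, n_reps = 100,
                             gamma = rep$M, seed = 5)
  expect_gt(probe$prob, 0)
})

test_that("small-noise extinction check fires only when all conditions hold", {
  m7 <- mlr_uniform(7, 0.05)
  chk <- small_noise_extinction_check(m7, classify_skeleton(m7))
  expect_equal(chk$verdict, "UNCONDITIONAL_EXTINCTION_SMALL_NOISE")

  m45 <- mlr_uniform(4.5, 0.05)
  expect_equal(small_noise_extinction_check(m45, classify_skeleton(m45))$verdict,
               "NO_CONCLUSION")

  # unbounded noise family fails the epsilon-smallness precondition
  m_ln <- build_model("mate_limitation_ricker", params = list(a = 1, h = 10),
                      env = list(r = env_dist("normal", mean = 7, sd = 0.1)))
  chk_ln <- small_noise_extinction_check(m_ln, classify_skeleton(m7))
  expect_equal(chk_ln$verdict, "NO_CONCLUSION")
  expect_match(paste(chk_ln$reasons, collapse = " "), "unbounded")
})
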