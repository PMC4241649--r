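test_that("persistence-curve experiment: step at the deterministic threshold,
           sigmoidal lift below it, insensitive to doubling the horizon", {
  thr <- 10 / (exp(0.1) - 1)   # deterministic Allee threshold ~95.08
  res <- run_figure1(sigma_grid = c(0, 0.5), x0_grid = c(25, 90, 100, 200),
                     T = 500, n_reps = 200, seed = 41)
  det <- subset(res, sigma == 0)
  expect_equal(det$phat, c(0, 0, 1, 1))   # step across thr

  sto <- subset(res, sigma == 0.5)
  expect_gt(sto$phat[sto$x0 == 25], 0)    # noise lifts persistence below thr
  expect_lt(sto$phat[sto$x0 == 25], sto$phat[sto$x0 == 200])

  # doubling T leaves the curve inside the binomial CIs
  res2 <- run_figure1(sigma_grid = 0.5, x0_grid = c(25, 90, 100, 200),
                      T = 1000, n_reps = 200, seed = 43)
  for (i in seq_len(nrow(res2)))
    expect_true(res2$phat[i] >= sto$lo[i] - 0.05 &&
                res2$phat[i] <= sto$hi[i] + 0.05)
})

test_that("noise ordering of persistence resolves at low initial density", {
  # below the Allee threshold, stronger noise gives more escapes; at x0 = 25
  # the ordering separates cleanly
  res <- run_figure1(sigma_grid = c(0.25, 0.5, 1), x0_grid = 25,
                     T = 1000, n_reps = 1000, seed = 47)
  res <- res[order(res$sigma), ]
  expect_true(all(diff(res$phat) > 0))
  expect_gt(res$phat[3], res$hi[1])   # sigma 1 vs 0.25 beyond CI
})

test_that("mate-limitation-Ricker scatter: deterministic orbit, attractor band,
           extinction at large noise", {
  res <- run_figure2(eps_grid = c(0, 0.25, 4.3), x0_set = c(2, 5),
                     T = 2000, n_keep = 200, seed = 11)
  expect_equal(nrow(res), 3 * 2 * 200)
  expect_true(all(res$density >= 0))

  # eps = 0 from a basin start reproduces the deterministic skeleton orbit
  det <- subset(res, param == 0 & x0 == 2)
  m <- mlr_point(4.5)
  traj <- iterate(m, 2, 2000, seed = 99)      # noise-free: seed irrelevant
  expect_equal(det$density, traj$densities[det$t + 1], tolerance = 1e-12)

  # small noise keeps kept points above the skeleton fixed point M
  sk <- classify_skeleton(mlr_point(4.5))
  small <- subset(res, param == 0.25)
  expect_true(all(small$density > sk$M))

  # noise near the growth rate kills every orbit
  big <- subset(res, param == 4.3)
  expect_true(all(big$density < 1e-8))
})

test_that("predator-saturation scatter reproduces the predation-window pattern", {
  res <- run_figure3(Pbar_grid = c(0.2, 0.5, 0.85), T = 2000, n_keep = 100,
                     seed = 13)
  cells <- scatter_cell_summary(res)
  expect_equal(nrow(cells), 3 * 4)
  low <- subset(cells, param == 0.2)
  expect_true(all(low$verdict == "INTERIOR"))       # G(0) > 1: persists
  mid <- subset(cells, param == 0.5)
  expect_true(all(mid$verdict == "EXTINCT"))        # extinction window
  high <- subset(cells, param == 0.85)
  expect_true(any(high$verdict == "INTERIOR"))      # conditional persistence
})

test_that("regime map over the Ricker mean-growth grid finds the E[r]=0 boundary", {
  fam <- function(mu, sigma)
    build_model("ricker", params = list(a = 1),
                env = list(r = env_dist("normal", mean = mu, sd = sigma)))
  map <- regime_map(fam, p1_grid = c(-0.4, 0.4), p2_grid = c(0.3, 0.6),
                    n_reps = 10, T = 1000, seed = 29)
  expect_true(all(is.na(map$error)))
  expect_true(all(map$regime[map$p1 < 0] == "UNCONDITIONAL_EXTINCTION"))
  expect_true(all(map$regime[map$p1 > 0] == "STOCHASTIC_PERSISTENCE"))
  expect_true(all(map$frac_extinct[map$p1 < 0] >= 0.9))
})

test_that("fixtures regenerate bit-identically and match the replay oracle", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  man <- generate_fixtures(101, d1, T = 30)
  generate_fixtures(101, d2, T = 30)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_setequal(names(man$models),
                  c("ricker", "beverton_holt", "mate_limitation",
                    "predator_saturation", "mate_limitation_ricker",
                    "predator_saturation_ricker", "liebhold_bascompte"))

  # golden Ricker trajectory agrees with an independent replay
  gold <- utils::read.csv(file.path(d1, "ricker.csv"))
  spec <- man$models$ricker
  m <- model_from_list(spec$spec)
  traj <- iterate(m, 1, 30, seed = spec$seed, record_env = TRUE)
  x <- 1
  for (t in 1:30) x <- x * m$eval(x, traj$env_draws[t, , drop = FALSE])
  expect_equal(gold$density, traj$densities)
  expect_equal(traj$densities[31], x)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("experiments run from YAML configs and write sidecar metadata", {
  cfg <- file.path(tempdir(), "exp.yaml")
  writeLines(c("experiment: figure1",
               "sigma_grid: [0.0]",
               "x0_grid: [50.0, 200.0]",
               "T: 200", "n_reps: 5", "seed: 3"), cfg)
  res <- run_experiment(cfg)
  expect_equal(res$phat, c(0, 1))
  out <- file.path(tempdir(), "expout")
  write_experiment_output(res, out)
  expect_true(file.exists(file.path(out, "results.csv")))
  meta <- jsonlite::read_json(file.path(out, "metadata.json"))
  expect_equal(meta$config$experiment, "figure1")
  expect_equal(meta$config$seed, 3)
  unlink(c(cfg, out), recursive = TRUE)
})
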