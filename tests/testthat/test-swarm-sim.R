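# Orchestration: growth, collisions, scenario invariants, sweeps.

test_that("growth timers double the population deterministically at tau_dbl", {
  # initial timers ~ U(0, tau): every founder divides exactly once within
  # one doubling time and no daughter divides before it, so N(tau) = 2 N0
  cfg <- scenario_config("isotropic", n_agents = c(bacteria = 100L),
                         growth = "full", duration = 43 * 60,
                         dx = 50, record_every = 60,
                         qs = qs_params(A1 = 0, A2 = 0),
                         static = TRUE, dt = 1, couple_every = 1L,
                         stop_at_activation = FALSE, plateau_window = Inf,
                         seed = 6)
  res <- run_scenario(cfg)
  n <- res$counts[, "bacteria"]
  expect_equal(n[1L], 100L)
  expect_equal(tail(n, 1L), 200L)
  expect_true(all(diff(n) >= 0))
})

test_that("growth off keeps the population constant", {
  cfg <- tiny_scenario("isotropic", n_agents = c(bacteria = 20L),
                       growth = "off", seed = 2)
  res <- run_scenario(cfg)
  expect_true(all(res$counts[, "bacteria"] == 20L))
})

test_that("BacteriaBot daughters are free-swimming bacteria", {
  bb <- generate_library(preset_track_spec("bacteriabots", seed = 2))
  cfg <- scenario_config("isotropic", n_agents = c(bacteriabots = 10L),
                         growth = "full", duration = 121 * 60,
                         dx = 50, record_every = 60,
                         qs = qs_params(A1 = 0, A2 = 0),
                         static = TRUE, dt = 1, couple_every = 1L,
                         stop_at_activation = FALSE, bb_library = bb,
                         plateau_window = Inf, seed = 3)
  res <- run_scenario(cfg)
  expect_true(all(res$counts[, "bacteriabots"] == 10L))
  # each of the 10 mothers sheds exactly one free bacterium within one
  # biohybrid doubling time; those daughters then divide at the (faster)
  # bacterial rate, so the final bacterial count is at least 10
  nb_final <- tail(res$counts[, "bacteria"], 1L)
  expect_gte(nb_final, 10L)
  expect_lte(nb_final, 60L)
  expect_equal(tail(res$agents$kind[res$agents$kind != "bacteriabots"], 1L),
               "bacteria")
})

test_that("collision resolution never leaves overlapping pairs (brute force)", {
  set.seed(9)
  n <- 400
  x <- runif(n, 0, 120)
  y <- runif(n, 0, 120)
  r <- rep(1, n)
  # separate any initially overlapping pairs by construction: jitter moves
  nx <- x + runif(n, -2, 2)
  ny <- y + runif(n, -2, 2)
  acc <- resolve_collisions(x, y, nx, ny, r)
  fx <- ifelse(acc, nx, x)
  fy <- ifelse(acc, ny, y)
  d <- as.matrix(dist(cbind(fx, fy)))
  diag(d) <- Inf
  started_apart <- as.matrix(dist(cbind(x, y)))
  diag(started_apart) <- Inf
  # every pair that started separated must remain separated
  expect_true(all(d[started_apart >= 2] >= 2 - 1e-9))
})

test_that("collision rule: clear moves accepted, overlapping moves pause", {
  acc <- resolve_collisions(x = c(0, 10), y = c(0, 0),
                            nx = c(-1, 11), ny = c(0, 0), radius = c(1, 1))
  expect_true(all(acc))
  acc2 <- resolve_collisions(x = c(0, 4), y = c(0, 0),
                             nx = c(1.2, 2.7), ny = c(0, 0),
                             radius = c(1, 1))
  expect_false(all(acc2)) # at least one must pause to avoid 1.5 um gap
})

test_that("scenarios are reproducible byte-for-byte given the seed", {
  cfg <- tiny_scenario("isotropic", n_agents = c(bacteria = 15L), seed = 11)
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$mean_gm, r2$mean_gm)
  expect_identical(r1$agents, r2$agents)
  expect_identical(r1$grid$Q, r2$grid$Q)
})

test_that("QS disabled decouples motility from gene expression", {
  cfg <- tiny_scenario("isotropic", n_agents = c(bacteria = 25L),
                       qs = qs_params(A1 = 0, A2 = 0), seed = 4)
  res <- run_scenario(cfg)
  expect_true(all(res$mean_gm == 0))
  expect_true(all(res$mean_q == 0))
  expect_true(is.na(res$activation[["all"]]))
})

test_that("agents never leave the motility domain", {
  nb <- small_mixed_library(n_tracks = 10, seed = 2)
  cfg <- scenario_config("isotropic",
                         n_agents = c(bacteria = 10L, nanobeads = 10L),
                         duration = 120, dx = 50, record_every = 30,
                         nb_library = nb, seed = 13)
  res <- run_scenario(cfg)
  expect_true(all(res$agents$x >= 0 & res$agents$x <= 1000))
  expect_true(all(res$agents$y >= 0 & res$agents$y <= 1000))
})

test_that("equivalent-concentration bookkeeping equates total bacteria", {
  expect_equal(agents_from_concentration(4.8e7), 48)
  expect_equal(agents_from_concentration(2e7), 20)
  expect_equal(agents_from_concentration(0.3e7, domain = c(4000, 4000)), 48)
  # 48 NanoBEADS cells == 4 BacteriaBots x 12 attached cells
  expect_equal(agents_from_concentration(4.8e7) / 12,
               agents_from_concentration(0.4e7))
})

test_that("config validation rejects inconsistent scenarios", {
  expect_error(scenario_config("isotropic", n_agents = c(algae = 5L)),
               "unknown agent kind")
  expect_error(scenario_config("isotropic",
                               n_agents = c(nanobeads = 5L)),
               "nb_library")
  lib <- small_mixed_library(n_tracks = 4, seed = 1)
  expect_error(scenario_config("gradient", n_agents = c(nanobeads = 5L),
                               nb_library = lib),
               "partitioned")
  expect_error(scenario_config("two_population",
                               n_agents = c(nanobeads = 10L),
                               split = c(5L, 6L)),
               "sum")
  expect_error(scenario_config("isotropic", n_agents = c(bacteria = 5L),
                               dt = 0.2), "dt")
})

test_that("activation sweep: replicates=1 gives zero SD; more eta, faster", {
  cfg <- scenario_config("isotropic", n_agents = c(bacteria = 60L),
                         duration = 2.5 * 3600, dx = 50,
                         record_every = 60, seed = 21)
  sw <- activation_sweep(cfg, eta_grid = c(0.7, 1.0), replicates = 1L)
  expect_equal(dim(sw$mean), c(2L, 1L))
  expect_true(all(sw$sd[!is.na(sw$sd)] == 0))
  act <- sw$mean[, 1L]
  if (!anyNA(act)) expect_lte(act["1"], act["0.7"])
})

test_that("two-population control: dense site activates, sparse site lags", {
  cfg <- scenario_config("two_population", n_agents = c(nanobeads = 48L),
                         split = c(44L, 4L), separation = 2700,
                         domain = c(4000, 4000), dx = 100, dt = 2,
                         couple_every = 1L, duration = 6 * 3600,
                         record_every = 120, seed = 8)
  res <- run_scenario(cfg)
  a <- res$activation
  expect_false(is.na(a[["A"]]))
  # the minority either never activates or strictly follows the majority
  if (!is.na(a[["B"]])) expect_gt(a[["B"]], a[["A"]])
})
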