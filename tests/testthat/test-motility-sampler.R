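# In-sequence replay engine, group partitioning and bias calibration.

test_that("a single-track library is replayed exactly", {
  tr <- straight_track(n = 3, dt = 1, speed = 1)
  lib <- trajectory_library(list(tr, tr), "toy")
  sim <- simulate_sampler(lib, 1, duration = 2, seed = 1,
                          record_positions = TRUE,
                          init = list(x = 0, y = 500, heading = 0))
  expect_equal(sim$xs[, 1L], c(0, 1, 2))
  expect_equal(sim$ys[, 1L], rep(500, 3))
})

test_that("in-sequence replay preserves the source persistence curve", {
  lib <- small_mixed_library(n_tracks = 8, seed = 31)
  # most persistent source track
  n_h <- length(lib$tracks[[1L]]$speeds)
  src_i <- which.max(persistence_profile(lib, n_h))
  src <- lib$tracks[[src_i]]
  one <- trajectory_library(list(src), "toy")
  sim <- simulate_sampler(one, 1, duration = n_h * src$frame_interval,
                          seed = 4, record_positions = TRUE,
                          init = list(x = 500, y = 500,
                                      heading = src$heading0))
  sim_tr <- extract_kinematics(track("sim", src$frame_interval,
                                     cbind(sim$xs[, 1L], sim$ys[, 1L])))
  for (h in unique(c(1L, 5L, n_h %/% 2L, n_h))) {
    expect_equal(persistence(sim_tr, h), persistence(src, h),
                 tolerance = 1e-8)
  }
  # and the replayed kinematic sequence matches element-for-element
  expect_equal(sim_tr$speeds, src$speeds, tolerance = 1e-8)
  expect_equal(sim_tr$turn_rates, src$turn_rates, tolerance = 1e-8)
})

test_that("random-order sampling destroys the persistent subpopulation", {
  lib <- small_mixed_library(n_tracks = 20, seed = 13)
  horizon <- 6
  n_h <- round(horizon / 0.07) - 1L
  p_of <- function(mode) {
    sim <- simulate_sampler(lib, 40, duration = horizon, mode = mode,
                            seed = 17, record_positions = TRUE,
                            domain = c(1e6, 1e6))
    mean(vapply(seq_len(40), function(a) {
      persistence(extract_kinematics(
        track("s", 0.07, cbind(sim$xs[, a], sim$ys[, a]))), n_h)
    }, numeric(1)))
  }
  expect_gt(p_of("insequence"), p_of("random"))
})

test_that("displacement per frame never exceeds max library speed x dt", {
  lib <- small_mixed_library(n_tracks = 6, seed = 23)
  sim <- simulate_sampler(lib, 20, duration = 3, seed = 2,
                          record_positions = TRUE, y_periodic = FALSE)
  vmax <- max(unlist(lapply(lib$tracks, `[[`, "speeds")))
  steps <- sqrt(diff(sim$xs)^2 + diff(sim$ys)^2)
  expect_lte(max(steps), vmax * 0.07 + 1e-9)
})

test_that("isotropic sampling keeps CPC near zero", {
  lib <- small_mixed_library(n_tracks = 20, seed = 19)
  sim <- simulate_sampler(lib, 500, duration = 60, seed = 8)
  expect_lt(abs(tail(sim$cpc, 1L)), 4 / sqrt(500))
})

test_that("partition_library makes equal (up to one) random covers", {
  set.seed(1)
  for (n in c(26L, 154L, 3L)) {
    lib <- generate_library(track_gen_spec(
      "toy", n_tracks = n, duration = 0.3, frame_interval = 0.1,
      speed_mean = 5, speed_sd = 1, seed = 2))
    part <- partition_library(lib)
    expect_equal(sort(c(part$group_pos, part$group_neg)), seq_len(n))
    expect_lte(abs(length(part$group_pos) - length(part$group_neg)), 1L)
  }
  expect_equal(length(partition_library(generate_library(
    preset_track_spec("bacteriabots")))$group_pos), 13L)
})

test_that("calibration finds a partition matching an attainable target", {
  # library with drifted (+x) and mirrored (-x) subsets: the ideal split is
  # group-separable, so calibration against the ideal split's own CPC curve
  # must find a partition at least close to it
  mk <- function(bias, seed) generate_library(track_gen_spec(
    "toy", n_tracks = 10, duration = 6, frame_interval = 0.07,
    speed_mean = 23, speed_sd = 5,
    persistence_mixture = list(c(1, 60)), drift_bias = bias, seed = seed))
  pos <- mk(0.9, 1)$tracks
  neg <- mk(-0.9, 2)$tracks
  lib <- trajectory_library(c(pos, neg), "toy")
  ideal <- trajectory_library(c(pos, neg), "toy",
                              group_pos = 1:10, group_neg = 11:20)
  t_pts <- c(30, 60)
  ideal_sim <- simulate_sampler(ideal, 300, 60, gradient = c(1, 0),
                                seed = 5, record_every = 30)
  target <- data.frame(t = t_pts,
                       cpc = ideal_sim$cpc[match(t_pts,
                                                 round(ideal_sim$times))])
  cal <- calibrate_bias(lib, target, n_pools = 25, n_agents = 200, seed = 3)
  expect_s3_class(cal, "bias_calibration")
  expect_lt(cal$error, sum((target$cpc)^2)) # far better than no bias
  expect_gt(mean(cal$achieved), 0.5 * mean(target$cpc))
})

test_that("degenerate calibrations behave as documented", {
  lib <- small_mixed_library(n_tracks = 10, seed = 3)
  target0 <- data.frame(t = 30, cpc = 0)
  cal <- calibrate_bias(lib, target0, n_pools = 4, n_agents = 100, seed = 2)
  expect_lt(cal$error, 0.05)
  cal1 <- calibrate_bias(lib, data.frame(t = 30, cpc = 0.9),
                         n_pools = 1, n_agents = 50, seed = 2)
  expect_equal(cal1$winning_pool, 1L)
  expect_warning(
    calibrate_bias(lib, data.frame(t = 30, cpc = 0.9),
                   n_pools = 1, n_agents = 50, seed = 2, tol = 1e-6),
    "tolerance")
})

test_that("the migration-bias ladder is monotone and anchored at zero", {
  mk <- function(bias, seed, n) generate_library(track_gen_spec(
    "toy", n_tracks = n, duration = 6, frame_interval = 0.07,
    speed_mean = 23, speed_sd = 5,
    persistence_mixture = list(c(1, 60)), drift_bias = bias, seed = seed))
  lib <- trajectory_library(c(mk(0.9, 1, 8)$tracks, mk(-0.9, 2, 8)$tracks),
                            "toy")
  rungs <- suppressWarnings(migration_bias_ladder(
    lib, n_levels = 3, n_pools = 8, n_agents = 120, duration = 120,
    window = 60, seed = 6, record_every = 30, tol = 0.5))
  expect_gte(length(rungs), 2L)
  expect_equal(rungs[[1L]]$bias, 0)
  expect_equal(rungs[[1L]]$achieved_cpc, 0)
  ach <- vapply(rungs, `[[`, numeric(1), "achieved_cpc")
  expect_true(all(diff(ach) >= -1e-9))
})
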