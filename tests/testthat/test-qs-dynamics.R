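# Circuit kinetics, the signal field solver, perception and activation.

test_that("production rate obeys the Hill limits", {
  p <- qs_params()
  expect_equal(production_rate(0, p), 3.19)
  expect_equal(production_rate(p$Q0, p), p$A1 + p$A2 / 2) # 120.19
  p55 <- qs_params(eta = 0.55)
  expect_equal(production_rate(1e9, p55), 0.55 * (3.19 + 234),
               tolerance = 1e-6)
  q <- c(0, 10^seq(-3, 3, by = 0.5))
  pr <- production_rate(q, p)
  expect_true(all(diff(pr) >= 0))
  expect_gte(min(pr), p$eta * p$A1)
  expect_lte(max(pr), p$eta * (p$A1 + p$A2))
  # alternative eta placement: basal term unscaled
  palt <- qs_params(eta = 0.5, eta_scales_basal = FALSE)
  expect_equal(production_rate(0, palt), 3.19)
  expect_equal(production_rate(1e9, palt), 3.19 + 0.5 * 234,
               tolerance = 1e-6)
})

test_that("GFP kinetics: fixed point, steady state vs root-finder oracle", {
  p <- qs_params()
  st <- gfp_step(0, 0, 0, dt = 1, p)
  expect_equal(st$Gi, 0)
  expect_equal(st$Gm, 0)

  # saturated induction (Q >> Q0), no growth: integrate to steady state
  integrate_to_ss <- function(mu, dt = 2, tmax = 2e5) {
    gi <- 0; gm <- 0
    for (i in seq_len(tmax / dt)) {
      st <- gfp_step(gi, gm, 1e6, dt, p, mu = mu)
      if (abs(st$Gi - gi) < 1e-10 && abs(st$Gm - gm) < 1e-10) break
      gi <- st$Gi; gm <- st$Gm
    }
    c(gi, gm)
  }
  ss <- integrate_to_ss(0)

  # independent algebraic oracle: at steady state with hill = 1,
  #   Gi* = ktr / (kGm + kdeg/(S+Km)),  Gm* = kGm Gi* (S+Km)/kdeg,
  # solved for the total S = Gi* + Gm* by 1D root bracketing
  res_fun <- function(S) {
    gi <- p$ktr / (p$kGm + p$kdeg / (S + p$Km))
    gm <- p$kGm * gi * (S + p$Km) / p$kdeg
    gi + gm - S
  }
  S_star <- uniroot(res_fun, c(1, 1e6), tol = 1e-10)$root
  gi_star <- p$ktr / (p$kGm + p$kdeg / (S_star + p$Km))
  gm_star <- S_star - gi_star
  expect_lt(abs(ss[1] - gi_star) / gi_star, 1e-3)
  expect_lt(abs(ss[2] - gm_star) / gm_star, 1e-3)
  # the activated steady state is detectable
  expect_gt(gm_star, p$gfp_threshold)

  # growth dilution strictly lowers the mature pool
  ss_mu <- integrate_to_ss(log(2) / (43 * 60))
  expect_lt(ss_mu[2], ss[2])
})

test_that("Euler integration converges at first order (Richardson)", {
  p <- qs_params()
  run_dt <- function(dt) {
    gi <- 0; gm <- 0
    for (i in seq_len(600 / dt)) {
      st <- gfp_step(gi, gm, 10, dt, p)
      gi <- st$Gi; gm <- st$Gm
    }
    gm
  }
  g1 <- run_dt(1)
  g05 <- run_dt(0.5)
  g025 <- run_dt(0.25)
  # halving dt should roughly halve the error (ratio near 2 for Euler)
  ratio <- (g1 - g05) / (g05 - g025)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3)
})

test_that("uniform field decays exponentially at the degradation rate", {
  p <- qs_params(Dsignal = 0) # isolate the reaction term
  g <- signal_grid(c(0, 100), c(0, 100), dx = 10)
  g$Q[] <- 10
  for (i in 1:60) g <- field_step(g, 60, p)
  expect_equal(max(g$Q), 10 * exp(-0.108), tolerance = 1e-6)
  expect_equal(min(g$Q), 10 * exp(-0.108), tolerance = 1e-6)
})

test_that("deposition converts molecules to concentration correctly", {
  g <- signal_grid(c(0, 100), c(0, 100), dx = 10, depth = 1)
  g <- deposit(g, 55, 35, 3.19)
  # 3.19 molecules in a 10 x 10 x 1 um^3 = 1e-13 L cell
  expected_nM <- 3.19 / (6.02214076e23 * 1e-13) * 1e9
  expect_equal(max(g$Q), expected_nM, tolerance = 1e-9)
  expect_equal(sum(g$Q > 0), 1L)
  expect_equal(perceive(g, 55, 35), expected_nM)
  expect_error(deposit(g, 150, 50, 1), "outside")
})

test_that("pure diffusion conserves mass and matches the heat kernel", {
  p <- qs_params(Rd_per_h = 0)
  g <- signal_grid(c(0, 1000), c(0, 1000), dx = 10)
  g <- deposit(g, 505, 505, 1e6)
  m0 <- total_signal(g)
  t_tot <- 0
  for (i in 1:100) {
    g <- field_step(g, 0.046, p)
    t_tot <- t_tot + 0.046
  }
  expect_lt(abs(total_signal(g) - m0) / m0, 1e-6)

  # second moment of the profile: variance per axis = 2 D t (the discrete
  # 5-point stencil propagates second moments exactly)
  xs <- (seq_len(g$nx) - 0.5) * g$dx
  wx <- rowSums(g$Q)
  mu_x <- sum(xs * wx) / sum(wx)
  var_x <- sum((xs - mu_x)^2 * wx) / sum(wx)
  expect_equal(var_x, 2 * p$Dsignal * t_tot, tolerance = 0.01)
})

test_that("the transport operator is linear and non-negative", {
  p <- qs_params()
  g0 <- signal_grid(c(0, 300), c(0, 300), dx = 20)
  set.seed(4)
  ga <- gb <- g0
  ga$Q[] <- runif(length(ga$Q))
  gb$Q[] <- runif(length(gb$Q))
  gsum <- g0
  gsum$Q <- ga$Q + 2 * gb$Q
  fa <- field_step(ga, 1, p)
  fb <- field_step(gb, 1, p)
  fsum <- field_step(gsum, 1, p)
  expect_equal(fsum$Q, fa$Q + 2 * fb$Q, tolerance = 1e-12)
  expect_true(all(fa$Q >= 0))
  gz <- field_step(g0, 5, p)
  expect_true(all(gz$Q == 0))
})

test_that("perception uses the deposition cell and the lower-edge tie rule", {
  g <- signal_grid(c(0, 100), c(0, 100), dx = 10)
  g$Q[] <- 5
  expect_equal(perceive(g, 1, 1), 5)
  expect_equal(perceive(g, 99, 99), 5)
  g2 <- deposit(g, 15, 15, 1e4)
  expect_gt(perceive(g2, 15, 15), 5)
  # a position exactly on the edge x = 10 belongs to cell 1 (lower index)
  g3 <- deposit(signal_grid(c(0, 100), c(0, 100), dx = 10), 10, 5, 1e4)
  expect_gt(perceive(g3, 5, 5), 0)
  expect_equal(perceive(g3, 15, 5), 0)
  expect_error(perceive(g, -5, 50), "outside")
})

test_that("activation_time interpolates the threshold crossing", {
  expect_equal(activation_time(c(0, 10), c(219, 230), threshold = 218), 0)
  expect_true(is.na(activation_time(0:10 * 10, rep(50, 11),
                                    threshold = 218)))
  # synthetic ramp: crossing of 218 between samples is interpolated
  tt <- seq(0, 200, by = 10)
  gm <- 2 * tt # crosses 218 at t = 109
  expect_equal(activation_time(tt, gm, threshold = 218), 109)
  expect_error(activation_time(numeric(0), numeric(0)), "empty")
})

test_that("activation is number-density dependent", {
  # one isolated cell cannot raise its surroundings anywhere near the
  # upregulation threshold; a dense cluster of 100 cells can
  p <- qs_params()
  g <- signal_grid(c(0, 1000), c(0, 1000), dx = 25)
  single_q <- NA
  for (i in 1:600) { # 10 min of basal production, quasi-steady well before
    g <- field_step(g, 1, p,
                    sources = list(x = 500, y = 500, molecules = p$A1))
    single_q <- perceive(g, 500, 500)
  }
  expect_lt(single_q, 0.1 * p$Q0)

  cfg <- scenario_config("two_population", n_agents = c(nanobeads = 100L),
                         split = c(99L, 1L), separation = 400,
                         domain = c(1000, 1000), dx = 25, dt = 1,
                         couple_every = 1L, duration = 2 * 3600,
                         diffusion_factor = 1, record_every = 60,
                         seed = 2)
  res <- run_scenario(cfg)
  expect_false(is.na(res$activation[["A"]]))
})
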