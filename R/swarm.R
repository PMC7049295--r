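# Whole-simulation orchestration: agent lifecycle, motility <-> QS <-> field
# coupling, and the scenario families (isotropic / gradient activation,
# sensitivity sweeps, two-population decentralized control).
#
# Global clock: 0.07 s (the NanoBEADS frame rate). BacteriaBot kinematics
# update every 11th step (0.77 s, their frame rate); free bacteria update
# every step. The intracellular circuit and field deposition advance on a
# coarser coupling cadence (default 0.35 s; the circuit's fastest timescale
# is minutes), and the diffusion PDE is substepped inside each coupling
# interval under its own stability bound.

KIND_BACTERIUM <- 1L
KIND_NANOBEADS <- 2L
KIND_BACTERIABOT <- 3L

kind_code <- function(kind) {
  k <- match(kind, c("bacteria", "nanobeads", "bacteriabots"))
  if (any(is.na(k))) stop("unknown agent kind: ",
                          paste(kind[is.na(k)], collapse = ", "))
  k
}

kind_radius <- function(code) c(1, 1, 3)[code]
kind_ncells <- function(code) c(1L, 1L, 12L)[code]

#' Agent count implied by a volumetric concentration
#'
#' Counts and concentrations are related through the 1-um slab:
#' `count = conc_per_ml * area_um2 * 1e-12`. For example 4.8e7 per ml over
#' a 1000 x 1000 um^2 domain is 48 bacteria.
#'
#' @param conc_per_ml concentration, agents per ml.
#' @param domain `c(width, height)`, um.
#' @param depth slab depth, um.
#' @return agent count (rounded).
#' @export
agents_from_concentration <- function(conc_per_ml, domain = c(1000, 1000),
                                      depth = 1) {
  round(conc_per_ml * domain[1L] * domain[2L] * depth * 1e-12)
}

#' Scenario configuration
#'
#' Validated bundle of everything [run_scenario()] needs. Counts can be
#' given directly (named vector `n_agents`) or via `concentration_per_ml`
#' (total *bacteria* equivalents; BacteriaBot counts are 1/12th of the
#' bacterial count since each carries 12 cells).
#'
#' @param scenario `"isotropic"`, `"gradient"`, or `"two_population"`.
#' @param n_agents named integer vector, e.g. `c(bacteria = 48)` or
#'   `c(nanobeads = 44)`; for `two_population` give the single kind and use
#'   `split` for the two patch counts.
#' @param duration activation horizon, seconds.
#' @param qs a [qs_params()].
#' @param chemo a [chemotaxis_params()].
#' @param growth `"off"`, `"half"`, or `"full"`; half growth doubles both
#'   doubling times (43 -> 86 min for bacteria, 121 -> 242 min for
#'   biohybrid-attached cells).
#' @param domain motility domain `c(width, height)`, um.
#' @param margin extra field extent beyond the motility domain in +/- x, um
#'   (Dirichlet zero at the far edges).
#' @param dx field grid spacing, um.
#' @param y_boundary `"periodic"` or `"dirichlet"` field boundary in y.
#' @param dt global time step, seconds.
#' @param couple_every circuit/field coupling cadence, in global steps.
#' @param record_every recording cadence, seconds.
#' @param nb_library,bb_library trajectory libraries for sampler-driven
#'   kinds (required when those kinds are present); must be partitioned for
#'   the gradient scenario.
#' @param collisions enable inelastic collision pausing.
#' @param static if `TRUE`, agents do not move (colonized populations);
#'   default for `two_population`.
#' @param split for `two_population`: `c(n_large, n_small)` agents in the
#'   two patches.
#' @param separation for `two_population`: patch-center separation, um.
#' @param patch for `two_population`: square patch side, um.
#' @param diffusion_factor multiplier on `Dsignal` (0.75 emulates AHL in
#'   extracellular matrix; applied by default in `two_population`).
#' @param stop_at_activation stop as soon as every population has crossed
#'   the GFP threshold.
#' @param plateau_window,plateau_rtol declare a steady non-activated state
#'   (and stop) when the population means stay below threshold and the
#'   relative rates of change of mean GFP and mean perceived signal stay
#'   below `plateau_rtol` of their running maxima for `plateau_window`
#'   seconds.
#' @param seed integer RNG seed; runs are reproducible given the config.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("isotropic", "gradient",
                                         "two_population"),
                            n_agents = c(bacteria = 48L),
                            duration = 20 * 3600,
                            qs = qs_params(),
                            chemo = chemotaxis_params(),
                            growth = c("off", "half", "full"),
                            domain = c(1000, 1000), margin = 1000,
                            dx = 20, y_boundary = NULL,
                            dt = 0.07, couple_every = 5L,
                            record_every = 30,
                            nb_library = NULL, bb_library = NULL,
                            collisions = TRUE,
                            static = NULL,
                            split = NULL, separation = 2700, patch = 100,
                            diffusion_factor = NULL,
                            stop_at_activation = TRUE,
                            plateau_window = 30 * 60, plateau_rtol = 1e-6,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  growth <- match.arg(growth)
  if (is.null(names(n_agents)) || any(!nzchar(names(n_agents))))
    stop("n_agents must be a named vector")
  codes <- kind_code(names(n_agents))
  if (scenario == "two_population") {
    if (is.null(split)) stop("two_population needs 'split = c(large, small)'")
    if (length(n_agents) != 1L)
      stop("two_population supports a single agent kind")
    if (sum(split) != unname(n_agents))
      stop("split must sum to n_agents")
    if (is.null(static)) static <- TRUE
    if (is.null(y_boundary)) y_boundary <- "dirichlet"
    if (is.null(diffusion_factor)) diffusion_factor <- 0.75
    margin <- 0
  } else {
    if (is.null(static)) static <- FALSE
    if (is.null(y_boundary)) y_boundary <- "periodic"
    if (is.null(diffusion_factor)) diffusion_factor <- 1
  }
  if (!static && dt > 0.07 + 1e-12)
    stop("dt must not exceed 0.07 s when agents move")
  if (KIND_NANOBEADS %in% codes && is.null(nb_library) && !static)
    stop("nanobeads agents need nb_library")
  if (KIND_BACTERIABOT %in% codes && is.null(bb_library) && !static)
    stop("bacteriabots agents need bb_library")
  if (scenario == "gradient") {
    chk <- function(lib, nm) {
      if (!is.null(lib) && is.null(lib$group_pos))
        stop(nm, " must be partitioned (or calibrated) for gradient runs")
    }
    if (KIND_NANOBEADS %in% codes) chk(nb_library, "nb_library")
    if (KIND_BACTERIABOT %in% codes) chk(bb_library, "bb_library")
  }
  structure(
    list(scenario = scenario, n_agents = n_agents, duration = duration,
         qs = qs, chemo = chemo, growth = growth,
         domain = domain, margin = margin, dx = dx,
         y_boundary = y_boundary, dt = dt,
         couple_every = as.integer(couple_every),
         record_every = record_every,
         nb_library = nb_library, bb_library = bb_library,
         collisions = collisions, static = static,
         split = split, separation = separation, patch = patch,
         diffusion_factor = diffusion_factor,
         stop_at_activation = stop_at_activation,
         plateau_window = plateau_window, plateau_rtol = plateau_rtol,
         seed = as.integer(seed)),
    class = "scenario_config")
}

# Doubling times (s) per kind under the configured growth mode; NA = no
# division. Dilution rate mu is ln2 / tau_dbl (0 with growth off).
growth_taus <- function(growth) {
  gp <- growth_params()
  base <- c(gp$tau_dbl_bacteria, gp$tau_dbl_biohybrid, gp$tau_dbl_biohybrid)
  switch(growth,
         off = rep(NA_real_, 3L),
         half = 2 * base,
         full = base)
}

#' Advance growth timers and spawn daughters
#'
#' Each agent carries a timer counting down to its next division (the first
#' timer is uniform on `(0, tau_dbl)` so divisions are desynchronized). On
#' expiry a daughter is created at the mother's position: bacteria and
#' NanoBEADS produce daughters of their own kind, BacteriaBots produce a
#' free-swimming bacterium (which adopts the bacterial doubling time). The
#' mother's timer resets to its own doubling time; the daughter starts a
#' full period. Daughters inherit the mother cell's GFP state (for
#' BacteriaBots, that of one uniformly chosen attached cell).
#'
#' @param sw internal swarm state (list of parallel vectors).
#' @param dt elapsed time, seconds.
#' @param taus doubling times per kind code (NA disables division).
#' @return updated state.
#' @keywords internal
growth_step <- function(sw, dt, taus) {
  sw$timer <- sw$timer - dt
  mothers <- which(!is.na(sw$timer) & sw$timer <= 0)
  for (m in mothers) {
    mkind <- sw$kind[m]
    dkind <- if (mkind == KIND_BACTERIABOT) KIND_BACTERIUM else mkind
    sw$timer[m] <- taus[mkind]
    i <- length(sw$kind) + 1L
    sw$kind[i] <- dkind
    sw$x[i] <- sw$x[m]
    sw$y[i] <- sw$y[m]
    sw$heading[i] <- stats::runif(1, -180, 180)
    sw$tag[i] <- sw$tag[m]
    sw$timer[i] <- taus[dkind]
    sw$trk[i] <- NA_integer_
    sw$cursor[i] <- NA_integer_
    sw$phase[i] <- FALSE
    sw$t_left[i] <- 0 # reorients and draws a run on the next motility step
    mcells <- which(sw$cell_owner == m)
    src <- if (length(mcells) > 1L) sample(mcells, 1L) else mcells
    j <- length(sw$cell_owner) + 1L
    sw$cell_owner[j] <- i
    sw$Gi[j] <- sw$Gi[src]
    sw$Gm[j] <- sw$Gm[src]
  }
  sw
}

#' Resolve proposed moves against the inelastic collision rule
#'
#' Moves are accepted sequentially in a random order; a move is rejected
#' (the agent pauses at its old position) if it would place the agent
#' closer than the sum of radii to any other agent's current position,
#' unless it increases the distance to every such neighbour (so agents that
#' start overlapping can separate rather than deadlock).
#'
#' @param x,y current positions, um.
#' @param nx,ny proposed positions.
#' @param radius agent radii, um.
#' @return logical vector: `TRUE` where the move is accepted.
#' @export
resolve_collisions <- function(x, y, nx, ny, radius) {
  n <- length(x)
  if (n < 2L) return(rep(TRUE, n))
  cx <- x; cy <- y
  accept <- rep(FALSE, n)
  for (i in sample.int(n)) {
    dx <- cx[-i] - nx[i]
    dy <- cy[-i] - ny[i]
    d2 <- dx^2 + dy^2
    rsum <- radius[-i] + radius[i]
    viol <- d2 < rsum^2
    if (!any(viol)) {
      accept[i] <- TRUE
    } else {
      od2 <- (cx[-i] - x[i])^2 + (cy[-i] - y[i])^2
      accept[i] <- all(d2[viol] > od2[viol])
    }
    if (accept[i]) {
      cx[i] <- nx[i]
      cy[i] <- ny[i]
    }
  }
  accept
}

# Candidate collision pairs within a cutoff (recomputed periodically; in
# between, only these pairs can collide given the per-step displacement
# bound). Returns a 2-column index matrix.
collision_candidates <- function(x, y, radius, cutoff_slack) {
  n <- length(x)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  cut <- outer(radius, radius, `+`) + cutoff_slack
  dx <- outer(x, x, `-`)
  dy <- outer(y, y, `-`)
  close <- (dx^2 + dy^2) < cut^2
  close[lower.tri(close, diag = TRUE)] <- FALSE
  which(close, arr.ind = TRUE)
}

#' Run one scenario simulation
#'
#' Advances motility (trajectory replay or run-and-tumble per agent kind),
#' growth, collisions, per-cell circuit kinetics, deposition and signal
#' transport on a common clock, and records population time series. The run
#' ends at the horizon, at activation of every population (when
#' `stop_at_activation`), or when a steady non-activated state is detected.
#'
#' @param config a [scenario_config()].
#' @return object of class `scenario_result`: `times`, `mean_gm` and
#'   `mean_q` (matrices, one column per population), `cpc`, `counts`
#'   (per-kind agent counts), `activation` (named vector of activation
#'   times in seconds, `NA` = not activated), `activated_fraction_cells`,
#'   final agent table, `status` (`"activated"`, `"plateau"`, or
#'   `"horizon"`), and the config echo.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  qs <- config$qs
  if (config$diffusion_factor != 1)
    qs$Dsignal <- qs$Dsignal * config$diffusion_factor
  W <- config$domain[1L]; H <- config$domain[2L]
  grid <- signal_grid(c(-config$margin, W + config$margin), c(0, H),
                      dx = config$dx, depth = qs$depth,
                      y_boundary = config$y_boundary)

  # --- agent setup ------------------------------------------------------
  codes <- kind_code(names(config$n_agents))
  taus <- growth_taus(config$growth)
  sw <- list(kind = integer(0), x = numeric(0), y = numeric(0),
             heading = numeric(0), tag = character(0),
             timer = numeric(0), trk = integer(0), cursor = integer(0),
             phase = logical(0), t_left = numeric(0),
             cell_owner = integer(0), Gi = numeric(0), Gm = numeric(0))
  add_agents <- function(sw, code, n, tag, xs, ys) {
    i0 <- length(sw$kind)
    idx <- i0 + seq_len(n)
    sw$kind[idx] <- code
    sw$x[idx] <- xs
    sw$y[idx] <- ys
    sw$heading[idx] <- stats::runif(n, -180, 180)
    sw$tag[idx] <- tag
    sw$timer[idx] <- if (is.na(taus[code])) NA_real_ else
      stats::runif(n, 0, taus[code])
    sw$trk[idx] <- NA_integer_
    sw$cursor[idx] <- NA_integer_
    # bacteria start in an expired pseudo-tumble: on their first motility
    # step they reorient and draw a run time from the local field
    sw$phase[idx] <- FALSE
    sw$t_left[idx] <- 0
    nc <- kind_ncells(code)
    own <- rep(idx, each = nc)
    j <- length(sw$cell_owner) + seq_along(own)
    sw$cell_owner[j] <- own
    sw$Gi[j] <- 0
    sw$Gm[j] <- 0
    sw
  }
  if (config$scenario == "two_population") {
    code <- codes[1L]
    cx <- W / 2 + c(-1, 1) * config$separation / 2
    for (p in 1:2) {
      n <- config$split[p]
      sw <- add_agents(sw, code, n, c("A", "B")[p],
                       stats::runif(n, cx[p] - config$patch / 2,
                                    cx[p] + config$patch / 2),
                       stats::runif(n, H / 2 - config$patch / 2,
                                    H / 2 + config$patch / 2))
    }
  } else {
    for (k in seq_along(codes)) {
      n <- config$n_agents[k]
      sw <- add_agents(sw, codes[k], n, "all",
                       stats::runif(n, 0, W), stats::runif(n, 0, H))
    }
  }

  gradient_on <- config$scenario == "gradient"
  field <- if (gradient_on) reference_gradient(W, config$chemo)
           else chemo_field_uniform(0)
  grad_dir <- if (gradient_on) c(1, 0) else NULL
  nb_pool <- if (!is.null(config$nb_library)) sampler_pool(config$nb_library)
  bb_pool <- if (!is.null(config$bb_library)) sampler_pool(config$bb_library)
  bb_stride <- if (!is.null(bb_pool)) max(1L, round(bb_pool$dt / config$dt))

  dt <- config$dt
  n_steps <- ceiling(config$duration / dt)
  couple <- config$couple_every
  dt_c <- couple * dt
  rec_stride <- max(couple, round(config$record_every / dt))
  rec_stride <- (rec_stride %/% couple) * couple
  tags <- unique(sw$tag)
  mu_kind <- ifelse(is.na(taus), 0, log(2) / taus)

  n_rec_max <- floor(n_steps / rec_stride) + 1L
  times <- numeric(n_rec_max)
  mean_gm <- matrix(NA_real_, n_rec_max, length(tags),
                    dimnames = list(NULL, tags))
  mean_q <- matrix(NA_real_, n_rec_max, length(tags),
                   dimnames = list(NULL, tags))
  cpc_series <- numeric(n_rec_max)
  counts <- matrix(0L, n_rec_max, 3L,
                   dimnames = list(NULL, c("bacteria", "nanobeads",
                                           "bacteriabots")))
  record <- function(ri, t_now) {
    times[ri] <<- t_now
    cell_tag <- sw$tag[sw$cell_owner]
    for (g in tags) {
      sel <- cell_tag == g
      mean_gm[ri, g] <<- mean(sw$Gm[sel])
      mean_q[ri, g] <<- mean(perceive(grid, sw$x[sw$cell_owner[sel]],
                                      sw$y[sw$cell_owner[sel]]))
    }
    cpc_series[ri] <<- cpc(sw$x, W / 2)
    counts[ri, ] <<- tabulate(sw$kind, 3L)
  }
  record(1L, 0)
  ri <- 1L

  # plateau bookkeeping
  max_dgm <- 0; max_dq <- 0
  quiet_since <- NA_real_
  status <- "horizon"

  max_speed <- max(c(config$chemo$speed,
                     if (!is.null(nb_pool)) max(nb_pool$speeds),
                     if (!is.null(bb_pool)) max(bb_pool$speeds)))
  refresh <- 10L
  cand <- NULL
  thr <- qs$gfp_threshold

  is_b <- sw$kind == KIND_BACTERIUM
  is_nb <- sw$kind == KIND_NANOBEADS
  is_bb <- sw$kind == KIND_BACTERIABOT
  refresh_masks <- function() {
    is_b <<- sw$kind == KIND_BACTERIUM
    is_nb <<- sw$kind == KIND_NANOBEADS
    is_bb <<- sw$kind == KIND_BACTERIABOT
  }

  sampler_advance <- function(sw, mask, pool, step_dt) {
    idx <- which(mask)
    if (!length(idx)) return(sw)
    fresh <- is.na(sw$trk[idx])
    if (any(fresh)) {
      f <- idx[fresh]
      sw$trk[f] <- draw_tracks(pool, length(f), sw$heading[f], grad_dir)
      sw$cursor[f] <- 1L
    }
    ptr <- pool$offset[sw$trk[idx]] + sw$cursor[idx]
    sw$heading[idx] <- wrap_angle(sw$heading[idx] + pool$turns[ptr] * step_dt)
    hr <- sw$heading[idx] * pi / 180
    sl <- pool$speeds[ptr] * step_dt
    sw$.nx[idx] <- sw$x[idx] + sl * cos(hr)
    sw$.ny[idx] <- sw$y[idx] + sl * sin(hr)
    sw$cursor[idx] <- sw$cursor[idx] + 1L
    done <- sw$cursor[idx] > pool$len[sw$trk[idx]]
    if (any(done)) {
      d <- idx[done]
      sw$trk[d] <- draw_tracks(pool, length(d), sw$heading[d], grad_dir)
      sw$cursor[d] <- 1L
    }
    sw
  }

  t_now <- 0
  for (s in seq_len(n_steps)) {
    t_now <- s * dt
    if (!config$static) {
      sw$.nx <- sw$x
      sw$.ny <- sw$y
      # bacteria: run/tumble clocks
      bi <- which(is_b)
      if (length(bi)) {
        run <- sw$phase[bi] & sw$t_left[bi] > 0
        if (any(run)) {
          r <- bi[run]
          hr <- sw$heading[r] * pi / 180
          sw$.nx[r] <- sw$x[r] + config$chemo$speed * dt * cos(hr)
          sw$.ny[r] <- sw$y[r] + config$chemo$speed * dt * sin(hr)
        }
        sw$t_left[bi] <- sw$t_left[bi] - dt
        expired <- bi[sw$t_left[bi] <= 0]
        if (length(expired)) {
          to_t <- expired[sw$phase[expired]]
          to_r <- expired[!sw$phase[expired]]
          if (length(to_t)) {
            sw$phase[to_t] <- FALSE
            sw$t_left[to_t] <- draw_phase_duration(
              rep(config$chemo$tauT, length(to_t)))
          }
          if (length(to_r)) {
            sw$heading[to_r] <- wrap_angle(
              sw$heading[to_r] + draw_tumble_angle(length(to_r),
                                                   config$chemo))
            tau <- mean_run_time(sw$x[to_r], sw$y[to_r], sw$heading[to_r],
                                 field, config$chemo, t_now)
            sw$phase[to_r] <- TRUE
            sw$t_left[to_r] <- draw_phase_duration(tau)
          }
        }
      }
      if (!is.null(nb_pool) && any(is_nb))
        sw <- sampler_advance(sw, is_nb, nb_pool, nb_pool$dt)
      if (!is.null(bb_pool) && any(is_bb) && s %% bb_stride == 0L)
        sw <- sampler_advance(sw, is_bb, bb_pool, bb_pool$dt)

      # boundaries: periodic wrap in y (when the field is periodic),
      # pause at the x-walls of the motility domain
      if (config$y_boundary == "periodic") {
        sw$.ny <- sw$.ny %% H
        bad <- sw$.nx < 0 | sw$.nx > W
      } else {
        bad <- sw$.nx < 0 | sw$.nx > W | sw$.ny < 0 | sw$.ny > H
      }
      sw$.nx[bad] <- sw$x[bad]
      sw$.ny[bad] <- sw$y[bad]

      if (config$collisions) {
        if (is.null(cand) || s %% refresh == 0L ||
            attr(cand, "n") != length(sw$kind)) {
          # per-step closing distance bound: every agent moves at most one
          # frame's displacement per step (BacteriaBots move on an 11-step
          # stride but by a full 0.77 s frame when they do)
          slack <- 2 * refresh * max_speed * dt *
            max(1, if (!is.null(bb_pool)) bb_pool$dt / (refresh * dt) else 0)
          cand <- collision_candidates(sw$x, sw$y, kind_radius(sw$kind),
                                       slack)
          attr(cand, "n") <- length(sw$kind)
        }
        if (nrow(cand)) {
          # cheap gate: only run the sequential resolver when a candidate
          # pair actually violates the overlap rule at the proposed moves
          d2 <- (sw$.nx[cand[, 1L]] - sw$.nx[cand[, 2L]])^2 +
            (sw$.ny[cand[, 1L]] - sw$.ny[cand[, 2L]])^2
          rsum <- kind_radius(sw$kind[cand[, 1L]]) +
            kind_radius(sw$kind[cand[, 2L]])
          hit <- d2 < rsum^2
          if (any(hit)) {
            inv <- unique(c(cand[hit, 1L], cand[hit, 2L]))
            acc <- resolve_collisions(sw$x[inv], sw$y[inv],
                                      sw$.nx[inv], sw$.ny[inv],
                                      kind_radius(sw$kind[inv]))
            rej <- inv[!acc]
            sw$.nx[rej] <- sw$x[rej]
            sw$.ny[rej] <- sw$y[rej]
          }
        }
      }
      sw$x <- sw$.nx
      sw$y <- sw$.ny
    }

    # --- circuit / field coupling ----------------------------------
    if (s %% couple == 0L) {
      own <- sw$cell_owner
      qcell <- perceive(grid, sw$x[own], sw$y[own])
      prod <- production_rate(qcell, qs)
      grid <- field_step(grid, dt_c, qs,
                         sources = list(x = sw$x[own], y = sw$y[own],
                                        molecules = prod * dt_c))
      mu <- mu_kind[sw$kind[own]]
      upd <- gfp_step(sw$Gi, sw$Gm, qcell, dt_c, qs, mu)
      sw$Gi <- upd$Gi
      sw$Gm <- upd$Gm
      if (config$growth != "off") {
        n_before <- length(sw$kind)
        sw <- growth_step(sw, dt_c, taus)
        if (length(sw$kind) != n_before) {
          refresh_masks()
          cand <- NULL
        }
      }
      if (s %% rec_stride == 0L) {
        ri <- ri + 1L
        record(ri, t_now)
        # stopping rules ------------------------------------------
        cur_gm <- mean_gm[ri, ]
        if (config$stop_at_activation && all(cur_gm > thr)) {
          status <- "activated"
          break
        }
        if (ri >= 3L) {
          dgm <- max(abs(mean_gm[ri, ] - mean_gm[ri - 1L, ]))
          dq <- max(abs(mean_q[ri, ] - mean_q[ri - 1L, ]))
          max_dgm <- max(max_dgm, dgm)
          max_dq <- max(max_dq, dq)
          quiet <- all(cur_gm < thr) &&
            (max_dgm == 0 || dgm <= config$plateau_rtol * max_dgm) &&
            (max_dq == 0 || dq <= config$plateau_rtol * max_dq)
          if (quiet) {
            if (is.na(quiet_since)) quiet_since <- t_now
            if (t_now - quiet_since >= config$plateau_window) {
              status <- "plateau"
              break
            }
          } else {
            quiet_since <- NA_real_
          }
        }
      }
    }
  }

  keep <- seq_len(ri)
  times <- times[keep]
  mean_gm <- mean_gm[keep, , drop = FALSE]
  mean_q <- mean_q[keep, , drop = FALSE]
  act <- vapply(tags, function(g)
    activation_time(times, mean_gm[, g], thr), numeric(1))
  structure(
    list(times = times,
         mean_gm = mean_gm, mean_q = mean_q,
         cpc = cpc_series[keep], counts = counts[keep, , drop = FALSE],
         activation = act, status = status,
         agents = data.frame(
           kind = c("bacteria", "nanobeads", "bacteriabots")[sw$kind],
           x = sw$x, y = sw$y, heading = sw$heading, tag = sw$tag),
         grid = grid, config = config),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result: %s, %s after %.1f min>\n",
              x$config$scenario, x$status, max(x$times) / 60))
  for (g in names(x$activation)) {
    a <- x$activation[g]
    cat(sprintf("  population %s: %s\n", g,
                if (is.na(a)) "not activated"
                else sprintf("activated at %.1f min", a / 60)))
  }
  invisible(x)
}

#' @export
summary.scenario_result <- function(object, ...) {
  n <- nrow(object$mean_gm)
  cat(sprintf(
    "Scenario '%s' (%s growth): %d records over %.1f min, status %s\n",
    object$config$scenario, object$config$growth, n,
    max(object$times) / 60, object$status))
  cat(sprintf("  final mean GFP: %s molecules/cell\n",
              paste(sprintf("%s=%.1f", colnames(object$mean_gm),
                            object$mean_gm[n, ]), collapse = ", ")))
  cat(sprintf("  final mean perceived signal: %s nM\n",
              paste(sprintf("%s=%.3g", colnames(object$mean_q),
                            object$mean_q[n, ]), collapse = ", ")))
  cat(sprintf("  final CPC: %.3f\n", object$cpc[n]))
  invisible(object)
}

#' Activation-time sweep over circuit sensitivity and migration bias
#'
#' Runs `replicates` scenario simulations per grid cell and returns mean
#' and SD activation-time matrices (RBS strength eta by migration-bias
#' rung) together with a not-activated mask. Bias rungs are supplied as a
#' [migration_bias_ladder()] result (or the single isotropic rung `NULL`).
#'
#' @param config base [scenario_config()] (its `qs$eta` and libraries are
#'   overridden per cell).
#' @param eta_grid RBS strengths to sweep.
#' @param ladder list of bias rungs (`NULL` entries mean isotropic) as
#'   produced by [migration_bias_ladder()]; default a single isotropic rung.
#' @param replicates simulations per cell.
#' @return list with `mean`, `sd`, `not_activated` (eta x bias matrices)
#'   and the grids.
#' @export
activation_sweep <- function(config, eta_grid, ladder = list(NULL),
                             replicates = 5L) {
  biases <- vapply(ladder, function(r) if (is.null(r)) 0 else r$bias,
                   numeric(1))
  m <- matrix(NA_real_, length(eta_grid), length(ladder),
              dimnames = list(eta = eta_grid, bias = biases))
  sdm <- m
  mask <- matrix(FALSE, length(eta_grid), length(ladder),
                 dimnames = dimnames(m))
  for (i in seq_along(eta_grid)) {
    for (j in seq_along(ladder)) {
      cfg <- config
      cfg$qs$eta <- eta_grid[i]
      rung <- ladder[[j]]
      if (!is.null(rung) && rung$bias > 0) {
        cfg$scenario <- "gradient"
        kind1 <- names(cfg$n_agents)[1L]
        if (kind1 == "nanobeads") cfg$nb_library <- rung$library
        if (kind1 == "bacteriabots") cfg$bb_library <- rung$library
      }
      acts <- vapply(seq_len(replicates), function(r) {
        cfg$seed <- config$seed + 1000L * r + 17L * i + j
        run_scenario(cfg)$activation[[1L]]
      }, numeric(1))
      if (all(is.na(acts))) {
        mask[i, j] <- TRUE
      } else {
        m[i, j] <- mean(acts, na.rm = TRUE)
        sdm[i, j] <- if (replicates > 1L) stats::sd(acts[!is.na(acts)]) else 0
        if (anyNA(acts)) mask[i, j] <- TRUE
      }
    }
  }
  list(mean = m, sd = sdm, not_activated = mask,
       eta_grid = eta_grid, biases = biases, replicates = replicates)
}
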