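# Data-driven motility engine.
#
# Simulated agents replay experimental (or synthetic) speed / turn-rate
# sequences *in order*. Each agent holds a cursor into one track; on every
# frame it first rotates by the track's turn rate, then translates at the
# track's speed along the new heading. When a track is exhausted, a
# replacement is drawn uniformly -- from the whole library in isotropic
# runs, or, under a gradient, from one of two track groups chosen by
# whether the agent is currently oriented up- or down-gradient. Chemotactic
# bias emerges from asymmetries between the two groups; the calibration
# below searches random group partitions for the one whose simulated CPC
# curve best matches a target.

# Flatten a library into parallel vectors for O(1) vectorized lookup.
sampler_pool <- function(library) {
  stopifnot(inherits(library, "trajectory_library"))
  lens <- vapply(library$tracks, function(tr) length(tr$speeds), integer(1))
  if (any(vapply(library$tracks, function(tr) is.null(tr$speeds), logical(1))))
    stop("all tracks need extracted kinematics (see extract_kinematics)")
  list(
    speeds = unlist(lapply(library$tracks, `[[`, "speeds")),
    turns = unlist(lapply(library$tracks, `[[`, "turn_rates")),
    offset = c(0L, cumsum(lens))[seq_along(lens)],
    len = lens,
    dt = library$tracks[[1L]]$frame_interval,
    group_pos = library$group_pos,
    group_neg = library$group_neg,
    n_tracks = length(library$tracks))
}

# Draw replacement tracks for agents whose current track is exhausted.
# heading in degrees; gradient NULL (isotropic) or a unit vector c(gx, gy).
draw_tracks <- function(pool, n, heading = NULL, gradient = NULL) {
  if (is.null(gradient) || is.null(pool$group_pos)) {
    sample.int(pool$n_tracks, n, replace = TRUE)
  } else {
    hr <- heading * pi / 180
    up <- (cos(hr) * gradient[1L] + sin(hr) * gradient[2L]) >= 0
    idx <- integer(n)
    if (any(up))
      idx[up] <- pool$group_pos[sample.int(length(pool$group_pos),
                                           sum(up), replace = TRUE)]
    if (any(!up))
      idx[!up] <- pool$group_neg[sample.int(length(pool$group_neg),
                                            sum(!up), replace = TRUE)]
    idx
  }
}

#' Simulate a swarm driven by trajectory replay
#'
#' Advances `n_agents` by in-sequence replay of the library's kinematics at
#' the library's own frame interval. Agents whose proposed position leaves
#' the rectangular motility domain pause (no translation) for that frame
#' while their heading continues to evolve, mirroring the inelastic
#' collision rule. CPC is recorded about the domain's x midline.
#'
#' @param library a [trajectory_library()]; groups are only required when
#'   `gradient` is non-NULL.
#' @param n_agents number of agents.
#' @param duration simulated time, seconds.
#' @param gradient `NULL` for isotropic sampling, or a 2-vector giving the
#'   direction of increasing chemoattractant (normalized internally).
#' @param mode `"insequence"` (default) replays each track's values in
#'   order; `"random"` draws uniformly with replacement from the current
#'   track's values at every frame (the degraded sampling scheme kept as a
#'   regression contrast -- it destroys persistence structure).
#' @param domain motility domain extent `c(width, height)`, micrometres.
#' @param seed integer RNG seed.
#' @param record_every cadence of CPC recording, seconds.
#' @param record_positions if `TRUE`, keep the full position history
#'   (`n_agents` must be modest).
#' @param init one of `"uniform"` (positions uniform over the domain,
#'   headings uniform) or a list with elements `x`, `y`, `heading`.
#' @param y_periodic wrap agents in y (the domain's periodic boundary);
#'   set `FALSE` to pause at the y-walls instead.
#' @return list with `times`, `cpc`, final `x`, `y`, `heading`, and
#'   optionally `xs`, `ys` (step-by-step position matrices).
#' @export
simulate_sampler <- function(library, n_agents, duration, gradient = NULL,
                             mode = c("insequence", "random"),
                             domain = c(1000, 1000), seed = 1L,
                             record_every = 10, record_positions = FALSE,
                             init = "uniform", y_periodic = TRUE) {
  mode <- match.arg(mode)
  pool <- sampler_pool(library)
  if (!is.null(gradient)) {
    if (is.null(pool$group_pos))
      stop("library has no sampling groups; call partition_library() first")
    gradient <- gradient / sqrt(sum(gradient^2))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  dt <- pool$dt
  n_steps <- round(duration / dt)
  if (identical(init, "uniform")) {
    x <- stats::runif(n_agents, 0, domain[1L])
    y <- stats::runif(n_agents, 0, domain[2L])
    heading <- stats::runif(n_agents, -180, 180)
  } else {
    x <- init$x; y <- init$y; heading <- init$heading
    stopifnot(length(x) == n_agents)
  }
  trk <- draw_tracks(pool, n_agents, heading, gradient)
  cursor <- rep(1L, n_agents)

  rec_stride <- max(1L, round(record_every / dt))
  rec_i <- unique(c(seq(0L, n_steps, by = rec_stride), n_steps))
  times <- rec_i * dt
  cpc_series <- numeric(length(rec_i))
  cpc_series[1L] <- cpc(x, domain[1L] / 2)
  ri <- 2L
  if (record_positions) {
    xs <- matrix(NA_real_, n_steps + 1L, n_agents)
    ys <- matrix(NA_real_, n_steps + 1L, n_agents)
    xs[1L, ] <- x; ys[1L, ] <- y
  }

  for (s in seq_len(n_steps)) {
    if (mode == "insequence") {
      ptr <- pool$offset[trk] + cursor
    } else {
      ptr <- pool$offset[trk] +
        floor(stats::runif(n_agents) * pool$len[trk]) + 1L
    }
    heading <- wrap_angle(heading + pool$turns[ptr] * dt)
    hr <- heading * pi / 180
    step_len <- pool$speeds[ptr] * dt
    nx <- x + step_len * cos(hr)
    ny <- y + step_len * sin(hr)
    if (y_periodic) {
      ny <- ny %% domain[2L]
      ok <- nx >= 0 & nx <= domain[1L]
    } else {
      ok <- nx >= 0 & nx <= domain[1L] & ny >= 0 & ny <= domain[2L]
    }
    x[ok] <- nx[ok]
    y[ok] <- ny[ok]
    cursor <- cursor + 1L
    done <- cursor > pool$len[trk]
    if (any(done)) {
      trk[done] <- draw_tracks(pool, sum(done), heading[done], gradient)
      cursor[done] <- 1L
    }
    if (record_positions) {
      xs[s + 1L, ] <- x; ys[s + 1L, ] <- y
    }
    if (s %% rec_stride == 0L || s == n_steps) {
      cpc_series[ri] <- cpc(x, domain[1L] / 2)
      ri <- ri + 1L
    }
  }
  out <- list(times = times, cpc = cpc_series, x = x, y = y,
              heading = heading, dt = dt)
  if (record_positions) {
    out$xs <- xs
    out$ys <- ys
  }
  out
}

#' Randomly split a library into the two sampling groups
#'
#' Uniformly random equal split (sizes differing by at most one) of all
#' tracks into `group_pos` / `group_neg`.
#'
#' @param library a [trajectory_library()] with at least 2 tracks.
#' @return the library with groups assigned.
#' @export
partition_library <- function(library) {
  n <- length(library$tracks)
  if (n < 2L) stop("need at least 2 tracks to partition")
  perm <- sample.int(n)
  k <- ceiling(n / 2)
  trajectory_library(library$tracks, library$agent_kind,
                     group_pos = sort(perm[seq_len(k)]),
                     group_neg = sort(perm[(k + 1L):n]))
}

#' Calibrate the sampling-group split against a target CPC curve
#'
#' Repeats \{random partition -> simulate `n_agents` under a +x gradient ->
#' CPC at the target times\} for `n_pools` pools and keeps the partition
#' minimizing the unweighted sum of squared CPC errors at the target time
#' points.
#'
#' @param library a [trajectory_library()].
#' @param target_cpc data frame with columns `t` (seconds) and `cpc`.
#' @param n_pools number of random partitions to try (study default 300).
#' @param n_agents agents per trial simulation (study default 1000).
#' @param seed integer RNG seed (drives both the partitions and the trial
#'   simulations; the whole search is deterministic given it).
#' @param domain motility domain, micrometres.
#' @param tol warn if the best summed squared error exceeds this.
#' @return object of class `bias_calibration`: the winning library (with
#'   groups), `error`, the achieved CPC at the target times, and bookkeeping.
#' @export
calibrate_bias <- function(library, target_cpc, n_pools = 300L,
                           n_agents = 1000L, seed = 1L,
                           domain = c(1000, 1000), tol = Inf) {
  stopifnot(is.data.frame(target_cpc), nrow(target_cpc) >= 1L,
            all(c("t", "cpc") %in% names(target_cpc)))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  duration <- max(target_cpc$t)
  best <- NULL
  for (p in seq_len(n_pools)) {
    lib_p <- partition_library(library)
    sim_seed <- sample.int(2^30, 1L)
    sim <- simulate_sampler(lib_p, n_agents, duration, gradient = c(1, 0),
                            domain = domain, seed = sim_seed,
                            record_every = min(diff(sort(unique(
                              c(0, target_cpc$t))))))
    achieved <- stats::approx(sim$times, sim$cpc, xout = target_cpc$t,
                              rule = 2)$y
    err <- sum((achieved - target_cpc$cpc)^2)
    if (is.null(best) || err < best$error) {
      best <- list(library = lib_p, error = err, achieved = achieved,
                   pool = p, sim_seed = sim_seed)
    }
  }
  if (best$error > tol)
    warning(sprintf("best calibration error %.4g exceeds tolerance %.4g",
                    best$error, tol))
  structure(
    list(library = best$library, error = best$error,
         target = target_cpc, achieved = best$achieved,
         n_pools = n_pools, n_agents = n_agents, seed = seed,
         winning_pool = best$pool),
    class = "bias_calibration")
}

#' @export
print.bias_calibration <- function(x, ...) {
  cat(sprintf(
    "<bias_calibration: %d pools x %d agents, SSE %.4g (pool %d)>\n",
    x$n_pools, x$n_agents, x$error, x$winning_pool))
  invisible(x)
}

#' Steady-state CPC of a partitioned library
#'
#' Simulates `n_agents` under a +x gradient and returns the mean CPC over
#' the final `window` seconds (study protocol: 85 min runs, final 20 min).
#'
#' @param library partitioned [trajectory_library()] (or plain library with
#'   `gradient = NULL` for the isotropic reference).
#' @param n_agents agents.
#' @param duration,window run length and averaging window, seconds.
#' @param gradient gradient direction or NULL for isotropic.
#' @param domain,seed,record_every as in [simulate_sampler()].
#' @return scalar steady-state CPC.
#' @export
steady_state_cpc <- function(library, n_agents = 1000L, duration = 85 * 60,
                             window = 20 * 60, gradient = c(1, 0),
                             domain = c(1000, 1000), seed = 1L,
                             record_every = 30) {
  sim <- simulate_sampler(library, n_agents, duration, gradient = gradient,
                          domain = domain, seed = seed,
                          record_every = record_every)
  mean(sim$cpc[sim$times >= duration - window])
}

#' Build a migration-bias ladder
#'
#' Evaluates `n_pools` random partitions, ranks them by steady-state CPC,
#' and returns calibrations whose steady-state CPC most closely matches the
#' targets `0.9 * bias` for `bias` on a uniform grid in `[0, 1]`. Bias 0 is
#' the isotropic sampler (no grouping), which has steady-state CPC 0 by
#' symmetry; bias 1 corresponds to a steady-state CPC of 0.9.
#'
#' @param library a [trajectory_library()].
#' @param n_levels number of ladder rungs (including bias 0).
#' @param n_pools partitions to evaluate.
#' @param n_agents,duration,window,domain,seed,record_every passed to
#'   [steady_state_cpc()].
#' @param tol rungs whose nearest achieved CPC differs from the target by
#'   more than this are dropped with a warning (range unreachable).
#' @return list of rungs, each `list(bias, target_cpc, achieved_cpc,
#'   library)`; sorted by bias, achieved CPC non-decreasing.
#' @export
migration_bias_ladder <- function(library, n_levels = 5L, n_pools = 20L,
                                  n_agents = 200L, duration = 85 * 60,
                                  window = 20 * 60, domain = c(1000, 1000),
                                  seed = 1L, record_every = 60, tol = 0.15) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  parts <- vector("list", n_pools)
  ss <- numeric(n_pools)
  for (p in seq_len(n_pools)) {
    parts[[p]] <- partition_library(library)
    ss[p] <- steady_state_cpc(parts[[p]], n_agents = n_agents,
                              duration = duration, window = window,
                              domain = domain,
                              seed = sample.int(2^30, 1L),
                              record_every = record_every)
  }
  ord <- order(ss)
  parts <- parts[ord]
  ss <- ss[ord]
  biases <- seq(0, 1, length.out = n_levels)
  rungs <- list()
  j_min <- 1L # partitions are CPC-sorted; advancing j keeps the ladder monotone
  for (b in biases) {
    target <- 0.9 * b
    if (b == 0) {
      rungs[[length(rungs) + 1L]] <- list(
        bias = 0, target_cpc = 0, achieved_cpc = 0,
        library = library) # isotropic: no grouping
      next
    }
    cand <- seq(j_min, n_pools)
    j <- cand[which.min(abs(ss[cand] - target))]
    if (abs(ss[j] - target) > tol) {
      warning(sprintf(
        "bias %.2f (CPC %.2f) unreachable with this library; dropped",
        b, target))
      next
    }
    j_min <- j
    rungs[[length(rungs) + 1L]] <- list(
      bias = b, target_cpc = target, achieved_cpc = ss[j],
      library = parts[[j]])
  }
  rungs
}
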