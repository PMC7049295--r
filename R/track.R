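# Tracked-trajectory containers and kinematic statistics.
#
# A track is an ordered sequence of 2D positions (micrometres) recorded at a
# fixed frame interval, plus the derived per-step kinematics: speeds (um/s)
# and signed turn rates (deg/s). Positive turn rates are counter-clockwise in
# the image plane; turn angles are wrapped to the smallest equivalent angle
# in (-180, 180] degrees.

#' Wrap angles to (-180, 180] degrees
#'
#' @param a numeric vector of angles in degrees.
#' @return angles mapped to the half-open interval (-180, 180].
#' @keywords internal
wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Construct a track
#'
#' A `track` holds the ordered positions of one agent and, once
#' [extract_kinematics()] has been applied, its per-step speeds and turn
#' rates. Speeds and turn rates have length `nrow(positions) - 1`; the first
#' turn rate is zero by convention (a velocity vector has no predecessor to
#' turn from), so that replaying the pairs `(speed[i], turn_rate[i])` as
#' "rotate, then translate" reproduces the positions exactly.
#'
#' @param track_id identifier (coerced to character).
#' @param frame_interval time between successive positions, seconds.
#' @param positions two-column numeric matrix of (x, y) in micrometres.
#' @param speeds optional numeric vector, um/s.
#' @param turn_rates optional numeric vector, deg/s (signed, CCW positive).
#' @return an object of class `track`.
#' @export
track <- function(track_id, frame_interval, positions,
                  speeds = NULL, turn_rates = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L)
    stop("positions must be a two-column (x, y) matrix")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("frame_interval must be a single positive number")
  n <- nrow(positions)
  if (n < 3L)
    stop(sprintf("track '%s' has %d positions; at least 3 are required",
                 as.character(track_id), n))
  if (!is.null(speeds)) {
    stopifnot(length(speeds) == n - 1L, all(speeds >= 0))
  }
  if (!is.null(turn_rates)) {
    stopifnot(length(turn_rates) == n - 1L)
  }
  structure(
    list(track_id = as.character(track_id),
         frame_interval = frame_interval,
         positions = unname(positions),
         speeds = speeds,
         turn_rates = turn_rates),
    class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track '%s': %d positions @ %.4g s (%.3g s), kinematics %s>\n",
              x$track_id, nrow(x$positions), x$frame_interval,
              (nrow(x$positions) - 1L) * x$frame_interval,
              if (is.null(x$speeds)) "not extracted" else "extracted"))
  invisible(x)
}

#' Read tracked-position tables
#'
#' Reads a CSV with columns `track_id, frame, x_um, y_um` and returns one
#' [track()] per distinct id, positions ordered by frame. Frames within a
#' track must be consecutive integers; kinematics are left unset until
#' [extract_kinematics()] is called.
#'
#' @param path CSV file path.
#' @param frame_interval seconds between frames (applied to every track).
#' @return list of `track` objects.
#' @export
read_tracks <- function(path, frame_interval) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  split_df <- split(df, df$track_id)
  lapply(split_df, function(d) {
    id <- d$track_id[1L]
    d <- d[order(d$frame), , drop = FALSE]
    if (anyDuplicated(d$frame))
      stop(sprintf("track '%s' has duplicated frames", id))
    if (nrow(d) >= 2L && any(diff(d$frame) != 1L))
      stop(sprintf("track '%s' has non-consecutive frames", id))
    if (nrow(d) < 3L)
      stop(sprintf("track '%s' has fewer than 3 positions", id))
    track(id, frame_interval, cbind(d$x_um, d$y_um))
  })
}

#' Write tracks in the CSV dialect read by [read_tracks()]
#'
#' @param tracks list of `track` objects (or a [trajectory_library()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "trajectory_library")) tracks <- tracks$tracks
  rows <- lapply(tracks, function(tr) {
    data.frame(track_id = tr$track_id,
               frame = seq_len(nrow(tr$positions)),
               x_um = tr$positions[, 1L],
               y_um = tr$positions[, 2L])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Derive per-step speeds and turn rates from positions
#'
#' The velocity vector between every two successive positions gives the step
#' speed; the signed smallest angle between successive velocity vectors,
#' divided by the frame interval, gives the turn rate. Conventions:
#' * `turn_rates[1]` is 0 (the first velocity has no predecessor);
#'   `turn_rates[i]` (i >= 2) is the rotation leading *into* velocity i.
#' * A zero-length step records speed 0 and turn rate 0; the heading is
#'   carried over, and the next non-degenerate step's turn rate is measured
#'   against the last well-defined heading, so dead-reckoning reintegration
#'   remains exact.
#'
#' @param tr a `track` with positions populated.
#' @return the same `track` with `speeds` and `turn_rates` filled in.
#' @export
extract_kinematics <- function(tr) {
  stopifnot(inherits(tr, "track"))
  dt <- tr$frame_interval
  v <- diff(tr$positions)
  d <- sqrt(rowSums(v^2))
  speeds <- d / dt
  head_raw <- atan2(v[, 2L], v[, 1L]) * 180 / pi
  # carry heading through zero-length steps (leading zeros inherit the first
  # well-defined heading so their turn rates are 0)
  nz <- d > 0
  headings <- head_raw
  if (!all(nz)) {
    if (!any(nz)) {
      headings[] <- 0
    } else {
      first_nz <- which(nz)[1L]
      headings[seq_len(first_nz)] <- head_raw[first_nz]
      for (i in seq_along(headings)[-1L]) {
        if (!nz[i]) headings[i] <- headings[i - 1L]
      }
    }
  }
  turns <- c(0, wrap_angle(diff(headings))) / dt
  tr$speeds <- speeds
  tr$turn_rates <- turns
  tr$heading0 <- headings[1L]
  tr
}

#' Reintegrate a track from its kinematics (dead reckoning)
#'
#' Cumulates the stored (speed, turn-rate) pairs from the initial heading and
#' position: at each step the heading is first incremented by
#' `turn_rate * frame_interval`, then the agent translates
#' `speed * frame_interval` along the new heading. For a track produced by
#' [extract_kinematics()] this reproduces the original positions to floating
#' precision.
#'
#' @param tr a `track` with kinematics extracted.
#' @param origin starting (x, y); defaults to the track's first position.
#' @param heading0 initial heading in degrees; defaults to the heading of the
#'   track's first displacement.
#' @return matrix of reintegrated positions (same dimension as
#'   `tr$positions`).
#' @export
reintegrate_track <- function(tr, origin = tr$positions[1L, ],
                              heading0 = tr$heading0) {
  stopifnot(inherits(tr, "track"), !is.null(tr$speeds))
  dt <- tr$frame_interval
  h <- heading0 + cumsum(tr$turn_rates) * dt
  hr <- h * pi / 180
  x <- origin[1L] + cumsum(tr$speeds * dt * cos(hr))
  y <- origin[2L] + cumsum(tr$speeds * dt * sin(hr))
  out <- rbind(origin, cbind(x, y), deparse.level = 0)
  dimnames(out) <- NULL
  out
}

#' Persistence ratio of a track
#'
#' Persistence over a horizon of `n_steps` steps is the net Euclidean
#' displacement from the starting position divided by the summed step
#' lengths (path distance). It is 1 for straight monotone motion and tends
#' to 0 for confined wandering. A track that has not moved at all (zero path
#' distance) is defined to have persistence 1.
#'
#' @param tr a `track`.
#' @param n_steps horizon in steps, `1 <= n_steps <= nrow(positions) - 1`.
#' @return persistence in `[0, 1]`.
#' @export
persistence <- function(tr, n_steps) {
  stopifnot(inherits(tr, "track"))
  n <- nrow(tr$positions) - 1L
  if (n_steps < 1L || n_steps > n)
    stop(sprintf("n_steps must be in [1, %d]", n))
  p <- tr$positions
  disp <- sqrt(sum((p[n_steps + 1L, ] - p[1L, ])^2))
  dist <- sum(sqrt(rowSums(diff(p[seq_len(n_steps + 1L), , drop = FALSE])^2)))
  if (dist == 0) return(1)
  min(disp / dist, 1)
}

#' Persistence of every track in a collection at a common horizon
#'
#' @param tracks list of `track` objects or a [trajectory_library()].
#' @param n_steps horizon in steps; tracks shorter than the horizon are
#'   skipped with `NA`.
#' @return numeric vector, one value per track.
#' @export
persistence_profile <- function(tracks, n_steps) {
  if (inherits(tracks, "trajectory_library")) tracks <- tracks$tracks
  vapply(tracks, function(tr) {
    if (nrow(tr$positions) - 1L < n_steps) return(NA_real_)
    persistence(tr, n_steps)
  }, numeric(1))
}

#' Chemotaxis partition coefficient (CPC)
#'
#' `CPC = (BR - BL) / (BR + BL)` where `BR` and `BL` count agents in the
#' right-hand and left-hand halves of the domain. Agents exactly on the
#' midline count as right-hand (a measure-zero set under continuous motion).
#'
#' @param x_positions numeric vector of agent x coordinates, micrometres.
#' @param midline x coordinate of the domain midline.
#' @return CPC in `[-1, 1]`.
#' @export
cpc <- function(x_positions, midline) {
  if (length(x_positions) == 0L) stop("cpc: no agents")
  br <- sum(x_positions >= midline)
  bl <- sum(x_positions < midline)
  (br - bl) / (br + bl)
}

#' Per-track kinematics table
#'
#' Flattens a set of tracks into the long-format CSV dialect
#' `track_id, step, speed_um_s, turn_rate_deg_s`.
#'
#' @param tracks list of `track` objects (kinematics extracted) or a
#'   [trajectory_library()].
#' @return data frame with one row per step.
#' @export
kinematics_table <- function(tracks) {
  if (inherits(tracks, "trajectory_library")) tracks <- tracks$tracks
  rows <- lapply(tracks, function(tr) {
    if (is.null(tr$speeds))
      stop(sprintf("track '%s': kinematics not extracted", tr$track_id))
    data.frame(track_id = tr$track_id,
               step = seq_along(tr$speeds),
               speed_um_s = tr$speeds,
               turn_rate_deg_s = tr$turn_rates)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Trajectory library
#'
#' A set of tracks of one agent kind plus (optionally) the two sampling
#' groups used to bias chemotactic replay: agents oriented up-gradient draw
#' replacement tracks from `group_pos`, agents oriented down-gradient from
#' `group_neg`.
#'
#' @param tracks list of `track` objects.
#' @param agent_kind `"nanobeads"` or `"bacteriabots"` (free-form kinds are
#'   allowed for synthetic studies).
#' @param group_pos,group_neg optional integer index vectors into `tracks`;
#'   together they must cover every track exactly once and differ in size by
#'   at most one.
#' @return an object of class `trajectory_library`.
#' @export
trajectory_library <- function(tracks, agent_kind,
                               group_pos = NULL, group_neg = NULL) {
  stopifnot(is.list(tracks), length(tracks) >= 1L)
  tracks <- unname(tracks)
  if (xor(is.null(group_pos), is.null(group_neg)))
    stop("group_pos and group_neg must be given together")
  if (!is.null(group_pos)) {
    both <- sort(c(group_pos, group_neg))
    if (!identical(as.integer(both), seq_along(tracks)))
      stop("groups must cover all tracks exactly once")
    if (abs(length(group_pos) - length(group_neg)) > 1L)
      stop("groups must be equal in size up to one track")
  }
  structure(
    list(tracks = tracks, agent_kind = agent_kind,
         group_pos = group_pos, group_neg = group_neg),
    class = "trajectory_library")
}

#' @export
print.trajectory_library <- function(x, ...) {
  cat(sprintf("<trajectory_library: %d %s tracks%s>\n",
              length(x$tracks), x$agent_kind,
              if (is.null(x$group_pos)) ""
              else sprintf(", groups %d/%d", length(x$group_pos),
                           length(x$group_neg))))
  invisible(x)
}

#' Number of tracks in a library
#' @param x a `trajectory_library`.
#' @export
length.trajectory_library <- function(x) length(x$tracks)
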