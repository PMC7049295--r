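# Shared fixture builders (everything is generated in code at test time).

# A minimal straight-line track along +x.
straight_track <- function(n = 5, dt = 1, speed = 1) {
  extract_kinematics(track("straight", dt,
                           cbind(seq(0, by = speed * dt, length.out = n), 0)))
}

# Small heterogeneous synthetic library: part near-ballistic, part diffusive.
small_mixed_library <- function(n_tracks = 12, duration = 6, dt = 0.07,
                                seed = 42) {
  generate_library(track_gen_spec(
    "nanobeads", n_tracks = n_tracks, duration = duration,
    frame_interval = dt, speed_mean = 23.4, speed_sd = 10,
    persistence_mixture = list(c(0.5, 20), c(0.5, 800)), seed = seed))
}

# Write a track table CSV and return its path.
write_track_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Fast scenario config for coupled-simulation tests.
tiny_scenario <- function(...) {
  scenario_config(duration = 600, dx = 50, record_every = 30, ...)
}
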