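# shared fixtures: small, fast configurations used across test files

# tiny arena for unit-level checks (seconds, not minutes)
tiny_config <- function(...) {
  args <- modifyList(list(field_length_mm = 1500, n_steps = 400, n_robots = 6),
                     list(...))
  do.call(sim_config, args)
}

# the desk-scale study configuration (shared by the acceptance suite)
study_config <- function(...) reduced_arena_config(...)

# build a one-robot world at a chosen position/state
place_robot <- function(world, i = 1, x = NULL, y = NULL, heading = NULL,
                        state = NULL, stay = NULL) {
  if (!is.null(x)) world$x[i] <- x
  if (!is.null(y)) world$y[i] <- y
  if (!is.null(heading)) world$heading[i] <- heading
  if (!is.null(state)) world$state[i] <- as.integer(state)
  if (!is.null(stay)) world$stay_timer[i] <- as.integer(stay)
  world
}
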