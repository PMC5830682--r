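# small fixture builders shared across test files

tiny_arena <- function(...) {
  arena_config(width = 30, height = 30, n_flab = 2, n_hermi = 2, ...)
}

# a world with a single prey parked at a known position
lone_prey_world <- function(species = "hermi", x = 15, y = 15,
                            width = 30, height = 30, ...) {
  cfg <- arena_config(width = width, height = height,
                      n_flab = as.integer(species == "flab"),
                      n_hermi = as.integer(species == "hermi"),
                      n_fauxflab = as.integer(species == "fauxflab"),
                      prey_step_length = 0, ...)
  w <- init_arena(cfg)
  w$prey$x <- x
  w$prey$y <- y
  w
}

# advance the odor fields n steps with prey in place
settle_odors <- function(world, n = 60) {
  for (i in seq_len(n)) world <- deposit_and_diffuse(world)
  world
}
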