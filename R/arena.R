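ODOR_CHANNELS <- c("betaine", "hermi", "flab")
PREY_SPECIES <- c("flab", "hermi", "fauxflab")

#' Arena configuration
#'
#' Describes the 2D world: grid size and topology, prey population, odor
#' diffusion/decay dynamics, prey locomotion and the consumption radius.
#' All quantities are in cell units and per-step rates. The published model
#' text specifies none of these numerically (they live in the original
#' NetLogo implementation), so the defaults were calibrated so that a lone
#' prey's odor plume is detectable a few body lengths away with a gradient
#' steep enough for stable chemotaxis, and the unrestrained agent consumes
#' prey at the published scale; every field is overridable.
#'
#' @param width,height arena size in grid cells.
#' @param wrap logical; `TRUE` for a torus (the default topology), `FALSE`
#'   for reflecting walls.
#' @param n_flab,n_hermi,n_fauxflab prey counts per species. Faux-Flab is
#'   the Batesian mimic: Flab's odor signature with Hermi's rewarding
#'   consequences; it defaults to 0.
#' @param diffusion_rate fraction of each cell's odor content shared
#'   equally with its 8 neighbours per step, per channel.
#' @param decay_rate multiplicative odor loss per step (`1 - decay_rate`
#'   survives).
#' @param prey_step_length prey random-walk step, cells per time step.
#' @param max_prey_turn half-width of the uniform per-step prey heading
#'   perturbation, degrees.
#' @param prey_odor_emission concentration units a prey deposits on its
#'   cell per step, on the betaine channel and on its signature channel.
#' @param consumption_radius prey within this distance of the agent's mouth
#'   are consumed, cells.
#' @param seed optional RNG seed used by [init_arena()].
#'
#' @return A named list of class `cs_arena_config`.
#' @examples
#' arena_config(n_flab = 10, n_hermi = 3)
#' @export
arena_config <- function(width = 50, height = 50, wrap = TRUE,
                         n_flab = 10, n_hermi = 3, n_fauxflab = 0,
                         diffusion_rate = 0.3, decay_rate = 0.35,
                         prey_step_length = 0.05, max_prey_turn = 30,
                         prey_odor_emission = 0.5,
                         consumption_radius = 1.0, seed = NULL) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              wrap = isTRUE(wrap),
              n_flab = as.integer(n_flab), n_hermi = as.integer(n_hermi),
              n_fauxflab = as.integer(n_fauxflab),
              diffusion_rate = diffusion_rate, decay_rate = decay_rate,
              prey_step_length = prey_step_length,
              max_prey_turn = max_prey_turn,
              prey_odor_emission = prey_odor_emission,
              consumption_radius = consumption_radius,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$width <= 0L || cfg$height <= 0L) {
    stop("arena dimensions must be positive", call. = FALSE)
  }
  if (cfg$n_flab < 0L || cfg$n_hermi < 0L || cfg$n_fauxflab < 0L) {
    stop("prey counts must be non-negative", call. = FALSE)
  }
  if (cfg$diffusion_rate < 0 || cfg$diffusion_rate >= 1) {
    stop("diffusion_rate must be in [0, 1)", call. = FALSE)
  }
  if (cfg$decay_rate < 0 || cfg$decay_rate >= 1) {
    stop("decay_rate must be in [0, 1)", call. = FALSE)
  }
  if (cfg$consumption_radius <= 0) {
    stop("consumption_radius must be positive", call. = FALSE)
  }
  structure(cfg, class = "cs_arena_config")
}

# 1-based cell index of a continuous coordinate, clamped to the grid
cell_of <- function(v, n) pmin(pmax(floor(v), 0), n - 1) + 1L

wrap_coord <- function(v, extent) {
  v <- v %% extent
  v[v < 0] <- v[v < 0] + extent
  v
}

reflect_coord <- function(v, extent) {
  period <- 2 * extent
  v <- v %% period
  v[v < 0] <- v[v < 0] + period
  out <- ifelse(v >= extent, period - v, v)
  ifelse(out >= extent, extent * (1 - .Machine$double.eps), out)
}

# shortest signed displacement on a circle
wrap_delta <- function(d, extent) d - extent * round(d / extent)

#' Initialize a world
#'
#' Creates zeroed odor fields and places the configured prey uniformly at
#' random. If `config$seed` is set the RNG is seeded first, so identical
#' seeds give identical worlds.
#'
#' @param config an [arena_config()].
#' @return A list of class `cs_world` with elements `config`, `fields` (one
#'   `height x width` matrix per odor channel: betaine, hermi, flab) and
#'   `prey` (data frame: species, x, y, heading).
#' @examples
#' w <- init_arena(arena_config(n_flab = 10, n_hermi = 3, seed = 1))
#' nrow(w$prey) # 13
#' @export
init_arena <- function(config) {
  stopifnot(inherits(config, "cs_arena_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_flab + config$n_hermi + config$n_fauxflab
  species <- rep(PREY_SPECIES,
                 times = c(config$n_flab, config$n_hermi, config$n_fauxflab))
  prey <- data.frame(
    species = species,
    x = if (n) runif(n, 0, config$width) else numeric(0),
    y = if (n) runif(n, 0, config$height) else numeric(0),
    heading = if (n) runif(n, 0, 360) else numeric(0),
    stringsAsFactors = FALSE
  )
  zero <- matrix(0, nrow = config$height, ncol = config$width)
  structure(
    list(config = config,
         fields = list(betaine = zero, hermi = zero, flab = zero),
         prey = prey),
    class = "cs_world"
  )
}

#' Deposit prey odors and advance the fields one diffusion-decay step
#'
#' Each prey adds `prey_odor_emission` to its current cell on the betaine
#' channel and on its species signature channel (the Faux-Flab mimic emits
#' on the flab channel). Every channel then undergoes one discrete
#' diffusion step -- each cell shares `diffusion_rate` of its content
#' equally with its 8 neighbours -- followed by multiplicative decay. The
#' operator conserves channel mass exactly when `decay_rate = 0`.
#'
#' @param world a `cs_world`.
#' @return The updated world.
#' @export
deposit_and_diffuse <- function(world) {
  stopifnot(inherits(world, "cs_world"))
  cfg <- world$config
  if (nrow(world$prey)) {
    ix <- cell_of(world$prey$x, cfg$width)
    iy <- cell_of(world$prey$y, cfg$height)
    chan <- ifelse(world$prey$species == "hermi", "hermi", "flab")
    for (p in seq_len(nrow(world$prey))) {
      world$fields$betaine[iy[p], ix[p]] <-
        world$fields$betaine[iy[p], ix[p]] + cfg$prey_odor_emission
      world$fields[[chan[p]]][iy[p], ix[p]] <-
        world$fields[[chan[p]]][iy[p], ix[p]] + cfg$prey_odor_emission
    }
  }
  for (ch in ODOR_CHANNELS) {
    world$fields[[ch]] <- .cpp_diffuse_decay(world$fields[[ch]],
                                             cfg$diffusion_rate,
                                             cfg$decay_rate, cfg$wrap)
  }
  world
}

#' Advance the prey random walk by one step
#'
#' Each prey's heading is perturbed by a uniform angle in
#' `[-max_prey_turn, +max_prey_turn]` and the prey advances
#' `prey_step_length` cells along its new heading, respecting the boundary
#' topology.
#'
#' @param world a `cs_world`.
#' @return The updated world.
#' @export
move_prey <- function(world) {
  stopifnot(inherits(world, "cs_world"))
  cfg <- world$config
  n <- nrow(world$prey)
  if (n == 0L) return(world)
  world$prey$heading <- world$prey$heading +
    runif(n, -cfg$max_prey_turn, cfg$max_prey_turn)
  if (cfg$prey_step_length > 0) {
    hr <- world$prey$heading * pi / 180
    nx <- world$prey$x + cfg$prey_step_length * cos(hr)
    ny <- world$prey$y + cfg$prey_step_length * sin(hr)
    if (cfg$wrap) {
      world$prey$x <- wrap_coord(nx, cfg$width)
      world$prey$y <- wrap_coord(ny, cfg$height)
    } else {
      world$prey$x <- reflect_coord(nx, cfg$width)
      world$prey$y <- reflect_coord(ny, cfg$height)
    }
  }
  world
}

#' Consume prey near a point and respawn replacements
#'
#' Every prey within `consumption_radius` of `agent_position` is recorded
#' as consumed and immediately replaced by a new prey of the same species
#' at a uniform random position, so per-species population counts are
#' invariant.
#'
#' @param world a `cs_world`.
#' @param agent_position numeric length-2 vector, the position of the
#'   agent's mouth.
#' @return A list with elements `world` (updated) and `consumed` (character
#'   vector of consumed species, possibly empty).
#' @export
consume_and_respawn <- function(world, agent_position) {
  stopifnot(inherits(world, "cs_world"), length(agent_position) == 2L)
  cfg <- world$config
  consumed <- character(0)
  if (nrow(world$prey)) {
    dx <- world$prey$x - agent_position[1]
    dy <- world$prey$y - agent_position[2]
    if (cfg$wrap) {
      dx <- wrap_delta(dx, cfg$width)
      dy <- wrap_delta(dy, cfg$height)
    }
    hit <- which(dx^2 + dy^2 <= cfg$consumption_radius^2)
    for (p in hit) {
      consumed <- c(consumed, world$prey$species[p])
      world$prey$x[p] <- runif(1, 0, cfg$width)
      world$prey$y[p] <- runif(1, 0, cfg$height)
      world$prey$heading[p] <- runif(1, 0, 360)
    }
  }
  list(world = world, consumed = consumed)
}
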