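#' Scenario configuration for foraging trials
#'
#' Bundles everything a seeded trial needs: the arena, the mechanism
#' toggles, trial length, locomotion and sensing parameters, and the model
#' constants. The standard experiment protocol runs 150000 time steps and 6
#' trials per condition.
#'
#' Mechanism toggles follow the published inactivation protocol:
#' `learning_enabled = FALSE` freezes `Vh = Vf = 0` for the whole trial;
#' `satiation_enabled = FALSE` clamps the satiation input of the
#' appetitive-state equation to `satiation_clamp` (by default its value at
#' zero nutrition), making the agent behave as permanently hungry while
#' nutrition itself still evolves.
#'
#' @param arena an [arena_config()].
#' @param learning_enabled,satiation_enabled mechanism toggles.
#' @param n_steps time steps per trial.
#' @param n_trials number of trials in a battery.
#' @param seeds optional integer vector of per-trial seeds (length
#'   `n_trials`); when `NULL`, [run_battery()] derives them from its master
#'   seed.
#' @param agent_speed agent advance per step, cells.
#' @param trace_every interval between per-step trace rows (0 = no trace).
#' @param constants a [cs_constants()].
#' @param geometry a [sensor_geometry()].
#' @param sensor_floor concentration floor of the log sensor transform.
#' @param engage_threshold an averaged sensor reading above this value
#'   engages the decision turn; below it the agent wanders.
#' @param satiation_clamp satiation value used when satiation is
#'   inactivated; default `satiation(0)`.
#' @return A list of class `cs_scenario`.
#' @export
scenario_config <- function(arena = arena_config(),
                            learning_enabled = TRUE,
                            satiation_enabled = TRUE,
                            n_steps = 150000, n_trials = 6, seeds = NULL,
                            agent_speed = 0.12, trace_every = 0,
                            constants = cs_constants(),
                            geometry = sensor_geometry(),
                            sensor_floor = 1e-7,
                            engage_threshold = 1e-7,
                            satiation_clamp = NULL) {
  stopifnot(inherits(arena, "cs_arena_config"),
            inherits(constants, "cs_constants"),
            inherits(geometry, "cs_sensor_geometry"),
            n_steps >= 0, n_trials >= 1, agent_speed >= 0,
            sensor_floor > 0)
  if (!is.null(seeds) && length(seeds) != n_trials) {
    stop("`seeds` must have length n_trials", call. = FALSE)
  }
  if (is.null(satiation_clamp)) {
    satiation_clamp <- .cpp_satiation(0, constants$k4)
  }
  structure(
    list(arena = arena, learning_enabled = isTRUE(learning_enabled),
         satiation_enabled = isTRUE(satiation_enabled),
         n_steps = as.integer(n_steps), n_trials = as.integer(n_trials),
         seeds = seeds, agent_speed = agent_speed,
         trace_every = as.integer(trace_every),
         constants = constants, geometry = geometry,
         sensor_floor = sensor_floor,
         engage_threshold = engage_threshold,
         satiation_clamp = satiation_clamp),
    class = "cs_scenario"
  )
}

TRACE_COLUMNS <- c("step", "x", "y", "heading", "Nutrition", "Satiation",
                   "Incentive", "App_State", "App_State_Switch",
                   "Turn_Angle", "Vh", "Vf")

# Initial full simulation state for a scenario; consumes 3*n_prey + 3
# uniform draws (prey x/y/heading, then agent x/y/heading).
init_forager <- function(scenario) {
  world <- init_arena(scenario$arena)
  cfg <- scenario$arena
  agent <- list(x = runif(1, 0, cfg$width), y = runif(1, 0, cfg$height),
                heading = runif(1, 0, 360),
                nutrition = scenario$constants$nutrition_init,
                prev_switch = 1) # default response mode is avoidance
  list(world = world, agent = agent,
       learning = learning_state(enabled = scenario$learning_enabled),
       scenario = scenario,
       counts = c(flab = 0L, hermi = 0L, fauxflab = 0L))
}

# One full update cycle composed from the module-level R functions. This is
# the readable reference path; run_trial() executes the identical cycle in
# compiled code, and the two are held together by a trajectory-equality
# test.
step_forager <- function(state) {
  sc <- state$scenario
  cs <- sc$constants
  cfg <- sc$arena
  state$world <- move_prey(state$world)
  state$world <- deposit_and_diffuse(state$world)
  ag <- state$agent
  pts <- sensor_positions(c(ag$x, ag$y, ag$heading), sc$geometry)
  reading <- sample_sensors(state$world, pts, sc$sensor_floor)
  sm <- somatic_map(reading, cs$k0)
  inc <- incentive(reading, state$learning$Vh, state$learning$Vf, cs)
  sat <- if (sc$satiation_enabled) satiation(ag$nutrition, cs)
         else sc$satiation_clamp
  app <- app_state(inc$incentive, sat, ag$prev_switch, cs)
  sw <- app_state_switch(app, cs)
  engaged <- max(reading$sns_betaine, reading$sns_hermi,
                 reading$sns_flab) > sc$engage_threshold
  turn <- if (engaged) turn_angle(sw, sm, cs) else wander_turn(1)
  # the somatic map supplies the side of the decision turn: stimulus left
  # (positive place code) makes an approach turn counterclockwise and an
  # avoidance turn clockwise, mirrored for a stimulus on the right
  dh <- if (engaged) (if (sm >= 0) -turn else turn) else turn
  ag$heading <- (ag$heading + dh) %% 360
  hr <- ag$heading * pi / 180
  nx <- ag$x + sc$agent_speed * cos(hr)
  ny <- ag$y + sc$agent_speed * sin(hr)
  if (cfg$wrap) {
    ag$x <- wrap_coord(nx, cfg$width); ag$y <- wrap_coord(ny, cfg$height)
  } else {
    ag$x <- reflect_coord(nx, cfg$width); ag$y <- reflect_coord(ny, cfg$height)
  }
  mouth <- c(ag$x + 0.5 * sc$geometry$body_length * cos(hr),
             ag$y + 0.5 * sc$geometry$body_length * sin(hr))
  if (cfg$wrap) {
    mouth <- c(wrap_coord(mouth[1], cfg$width),
               wrap_coord(mouth[2], cfg$height))
  }
  res <- consume_and_respawn(state$world, mouth)
  state$world <- res$world
  for (sp in res$consumed) {
    state$learning <- on_consumption(state$learning, sp, cs)
    state$counts[sp] <- state$counts[sp] + 1L
  }
  ag$nutrition <- update_nutrition(ag$nutrition, length(res$consumed), cs)
  ag$prev_switch <- sw
  state$agent <- ag
  state$last <- list(reading = reading, somatic_map = sm,
                     incentive = inc$incentive, satiation = sat,
                     app_state = app, switch = sw, turn = turn,
                     consumed = res$consumed)
  state
}

#' Run one seeded foraging trial
#'
#' Runs `scenario$n_steps` update cycles in compiled code: prey random
#' walk, odor deposition/diffusion/decay, bilateral sensing, somatic map,
#' incentive, satiation, appetitive state (using the previous step's
#' switch), the new approach-avoidance switch, decision turn or wander,
#' advance, and consumption with respawn, nutrition gain and
#' Rescorla-Wagner updates. All randomness derives from `seed`, so results
#' are bit-reproducible.
#'
#' @param scenario a [scenario_config()].
#' @param seed integer RNG seed for this trial.
#' @param trace_every overrides `scenario$trace_every` when non-`NULL`.
#' @return A one-row data frame of class `cs_trial_result` with columns
#'   `seed`, `consumed_flab`, `consumed_hermi`, `consumed_fauxflab`,
#'   `total`, `pct_hermi` and `selectivity` (`NA` when no flab was
#'   consumed). Attributes: `trace` (matrix of interface readouts, when
#'   tracing), `consumed` (data frame of the consumption sequence) and
#'   `final` (final agent state incl. `Vh`, `Vf`, `nutrition`).
#' @examples
#' sc <- scenario_config(arena_config(n_flab = 2, n_hermi = 2),
#'                       n_steps = 500)
#' run_trial(sc, seed = 1)
#' @export
run_trial <- function(scenario, seed, trace_every = NULL) {
  stopifnot(inherits(scenario, "cs_scenario"))
  if (is.null(trace_every)) trace_every <- scenario$trace_every
  set.seed(as.integer(seed))
  st <- init_forager(scenario)
  cfg <- scenario$arena
  cs <- scenario$constants
  sp_code <- c(flab = 0L, hermi = 1L, fauxflab = 2L)
  par <- c(
    unclass(cfg)[c("width", "height", "wrap", "diffusion_rate",
                   "decay_rate", "prey_step_length", "max_prey_turn",
                   "prey_odor_emission", "consumption_radius")],
    list(body_length = scenario$geometry$body_length,
         sensor_distance = scenario$geometry$sensor_distance,
         sensor_angle = scenario$geometry$sensor_angle,
         agent_speed = scenario$agent_speed,
         sensor_floor = scenario$sensor_floor,
         engage_threshold = scenario$engage_threshold),
    unclass(cs)[c("k0", "k1", "k3", "k4", "k5", "k6", "k7", "k8", "k9",
                  "switch_threshold", "app_state_baseline",
                  "nutrition_decay", "feed_gain", "alpha", "beta",
                  "lambda")],
    list(n_steps = scenario$n_steps,
         learning_enabled = scenario$learning_enabled,
         satiation_enabled = scenario$satiation_enabled,
         trace_every = as.integer(trace_every),
         satiation_clamp = scenario$satiation_clamp,
         prey_species = unname(sp_code[st$world$prey$species]),
         prey_x = st$world$prey$x, prey_y = st$world$prey$y,
         prey_heading = st$world$prey$heading,
         agent_x = st$agent$x, agent_y = st$agent$y,
         agent_heading = st$agent$heading,
         nutrition = st$agent$nutrition,
         Vh = 0, Vf = 0, prev_switch = st$agent$prev_switch)
  )
  raw <- .cpp_run_trial(par)
  total <- raw$consumed_flab + raw$consumed_hermi + raw$consumed_fauxflab
  out <- data.frame(
    seed = as.integer(seed),
    consumed_flab = raw$consumed_flab,
    consumed_hermi = raw$consumed_hermi,
    consumed_fauxflab = raw$consumed_fauxflab,
    total = total,
    pct_hermi = if (total > 0) 100 * raw$consumed_hermi / total else NA_real_,
    selectivity = if (raw$consumed_flab > 0) {
      raw$consumed_hermi / raw$consumed_flab
    } else NA_real_
  )
  class(out) <- c("cs_trial_result", "data.frame")
  if (trace_every > 0 && !is.null(raw$trace)) {
    tr <- raw$trace
    colnames(tr) <- TRACE_COLUMNS
    attr(out, "trace") <- tr
  }
  attr(out, "consumed") <- data.frame(
    step = raw$consumed_step,
    species = names(sp_code)[raw$consumed_species + 1L],
    stringsAsFactors = FALSE
  )
  attr(out, "final") <- raw[c("Vh", "Vf", "nutrition", "agent_x",
                              "agent_y", "agent_heading", "prev_switch")]
  out
}

#' Selectivity coefficient of a trial
#'
#' Total Hermis taken divided by total Flabs taken; `NA` when no Flab was
#' consumed. Accepts a trial-result data frame (vectorized over rows).
#'
#' @param result a `cs_trial_result` or any data frame with
#'   `consumed_hermi` and `consumed_flab` columns.
#' @return Numeric selectivity value(s).
#' @examples
#' selectivity(data.frame(consumed_hermi = 3, consumed_flab = 10)) # 0.3
#' @export
selectivity <- function(result) {
  stopifnot(all(c("consumed_hermi", "consumed_flab") %in% names(result)))
  ifelse(result$consumed_flab > 0,
         result$consumed_hermi / result$consumed_flab, NA_real_)
}
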