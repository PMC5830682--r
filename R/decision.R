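#' Incentive: net signed stimulus value
#'
#' Sums the innate appetitive value of the resource odor betaine with the
#' learned valences of the prey signature odors. The appetitive term
#' `R+ = sns_betaine / (1 + k1*Vh*sns_hermi) + k3*Vh*sns_hermi` shifts
#' weight from the innate betaine signal onto the learned hermi association
#' as `Vh` grows; the aversive term is `R- = k3*Vf*sns_flab`. A naive agent
#' (`Vh = Vf = 0`) reduces to pure resource tracking,
#' `Incentive = sns_betaine`.
#'
#' @param reading a `cs_sensor_reading`.
#' @param Vh,Vf learned associations of the hermi and flab signature odors,
#'   in `[0, lambda]`.
#' @param constants a [cs_constants()].
#' @return List with `R_plus`, `R_minus` and `incentive`.
#' @export
incentive <- function(reading, Vh, Vf, constants = cs_constants()) {
  stopifnot(inherits(reading, "cs_sensor_reading"))
  v <- .cpp_incentive(reading$sns_betaine, reading$sns_hermi,
                      reading$sns_flab, Vh, Vf, constants$k1, constants$k3)
  list(R_plus = v[["R_plus"]], R_minus = v[["R_minus"]],
       incentive = v[["incentive"]])
}

#' Nutrition update
#'
#' Nutrition decays by a fixed fraction per step and jumps by `feed_gain`
#' for every prey consumed this step:
#' `N' = N * (1 - nutrition_decay) + feed_gain * n_consumed`.
#'
#' @param nutrition current nutrition (non-negative).
#' @param n_consumed number of prey consumed this step.
#' @param constants a [cs_constants()].
#' @return Updated nutrition.
#' @examples
#' update_nutrition(1, 0)   # 0.9995
#' update_nutrition(0.8, 1) # 1.0996
#' @export
update_nutrition <- function(nutrition, n_consumed = 0,
                             constants = cs_constants()) {
  stopifnot(nutrition >= 0, n_consumed >= 0)
  nutrition * (1 - constants$nutrition_decay) +
    constants$feed_gain * n_consumed
}

#' Satiation as a function of nutrition
#'
#' A squared-logistic sigmoid, `1 / (1 + k4 * exp(-4*N + 2))^2`, strictly
#' increasing in nutrition with lower bound near 0 and upper asymptote 1.
#' Vectorized over `nutrition`.
#'
#' @param nutrition nutrition value(s), non-negative.
#' @param constants a [cs_constants()].
#' @return Satiation in (0, 1).
#' @export
satiation <- function(nutrition, constants = cs_constants()) {
  vapply(nutrition, .cpp_satiation, numeric(1), k4 = constants$k4)
}

#' Appetitive state
#'
#' The central affective variable:
#' `App_State = baseline + 1/(1 + exp(-k5*Incentive + k6*Satiation))
#'  + k7*(prev_switch - 1)`.
#' Incentive excites it, satiation suppresses it, and the last term -- fed
#' by the *previous* step's approach-avoidance switch, resolving the
#' mutual dependence of the two variables -- transiently suppresses it
#' while the switch sits at the approach pole (the term vanishes at
#' `prev_switch = +1` and is maximal at `-1`).
#'
#' @param incentive signed incentive value.
#' @param satiation satiation in (0, 1).
#' @param prev_switch previous step's switch value in (-1, 1).
#' @param constants a [cs_constants()].
#' @return Appetitive state (non-negative in the operating regime).
#' @export
app_state <- function(incentive, satiation, prev_switch,
                      constants = cs_constants()) {
  .cpp_app_state(incentive, satiation, prev_switch,
                 constants$k5, constants$k6, constants$k7,
                 constants$app_state_baseline)
}

#' Approach-avoidance switch
#'
#' `App_State_Switch = -2/(1 + exp(-k8*(App_State - threshold))) + 1`: a
#' steep sigmoid through 0 at the threshold (0.245), converging to -1
#' (approach) for high appetitive state and +1 (avoid) for low.
#'
#' @param app_state appetitive state.
#' @param constants a [cs_constants()].
#' @return Switch value in (-1, 1).
#' @examples
#' app_state_switch(0.245) # exactly 0
#' app_state_switch(0.545) # near -1: approach
#' app_state_switch(0.029) # near +1: avoid
#' @export
app_state_switch <- function(app_state, constants = cs_constants()) {
  vapply(app_state, .cpp_app_state_switch, numeric(1),
         k8 = constants$k8, threshold = constants$switch_threshold)
}

#' Decision turn angle
#'
#' `Turn_Angle = k9 * switch / (1 + exp(3*Somatic_Map - switch))`, degrees.
#' The sign follows the switch (positive, counterclockwise turns in
#' avoidance; negative in approach) and the magnitude is modulated by the
#' somatic map, so stimulus laterality shapes the turn in both modes.
#'
#' @param switch switch value in (-1, 1).
#' @param somatic_map signed place code from [somatic_map()].
#' @param constants a [cs_constants()].
#' @return Signed heading change in degrees.
#' @export
turn_angle <- function(switch, somatic_map, constants = cs_constants()) {
  .cpp_turn_angle(switch, somatic_map, constants$k9)
}

#' Exploratory wander turn
#'
#' When the agent is not engaged with any odor it wanders: the per-step
#' heading change is uniform in [-1, 1) degrees.
#'
#' @param n number of draws.
#' @return `n` heading changes in degrees.
#' @export
wander_turn <- function(n = 1) {
  runif(n, -1, 1)
}
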