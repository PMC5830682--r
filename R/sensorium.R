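#' Sensor geometry
#'
#' The agent carries two point odor sensors slightly less than half a body
#' length in front of its center, at roughly 40 degrees either side of the
#' anteroposterior axis, abstracting the real animal's chemotactile oral
#' veil.
#'
#' @param sensor_distance distance from body center, in body lengths.
#' @param sensor_angle angle off the heading axis, degrees.
#' @param body_length agent body length, cells.
#' @return A named list of class `cs_sensor_geometry`.
#' @export
sensor_geometry <- function(sensor_distance = 0.45, sensor_angle = 40,
                            body_length = 4) {
  stopifnot(sensor_distance > 0, sensor_angle > 0, sensor_angle < 90,
            body_length > 0)
  structure(list(sensor_distance = sensor_distance,
                 sensor_angle = sensor_angle,
                 body_length = body_length),
            class = "cs_sensor_geometry")
}

#' Bilateral sensor positions for a pose
#'
#' Headings are in degrees, counterclockwise positive; the left sensor sits
#' at `heading + sensor_angle`, the right at `heading - sensor_angle`, both
#' `sensor_distance * body_length` cells from the center.
#'
#' @param pose numeric vector `c(x, y, heading)`.
#' @param geometry a [sensor_geometry()].
#' @return List with numeric `left` and `right` positions (`c(x, y)`).
#' @examples
#' sensor_positions(c(0, 0, 0), sensor_geometry(0.45, 40, 10))
#' @export
sensor_positions <- function(pose, geometry = sensor_geometry()) {
  stopifnot(length(pose) == 3L, inherits(geometry, "cs_sensor_geometry"))
  r <- geometry$sensor_distance * geometry$body_length
  la <- (pose[3] + geometry$sensor_angle) * pi / 180
  ra <- (pose[3] - geometry$sensor_angle) * pi / 180
  list(left = c(pose[1] + r * cos(la), pose[2] + r * sin(la)),
       right = c(pose[1] + r * cos(ra), pose[2] + r * sin(ra)))
}

#' Sample the odor fields at the two sensors
#'
#' Each sensor reads the concentration of the nearest cell (no
#' interpolation, matching the patch-based original) and log-transforms it:
#' `reading = max(0, log10(concentration / floor))`. The floor makes the
#' reading zero at zero concentration and bounds the detection range of a
#' plume; a 10-fold concentration ratio between the sensors yields a
#' reading difference of exactly 1. Per-channel averages follow the
#' bilateral mean.
#'
#' @param world a `cs_world`.
#' @param points list with `left` and `right` positions, as returned by
#'   [sensor_positions()] (wrapped into the arena if needed).
#' @param floor concentration floor of the log transform.
#' @return A list of class `cs_sensor_reading` with, per channel `o` in
#'   betaine/hermi/flab, elements `sns_o_left`, `sns_o_right` and their
#'   average `sns_o`.
#' @export
sample_sensors <- function(world, points, floor = 1e-7) {
  stopifnot(inherits(world, "cs_world"), floor > 0)
  cfg <- world$config
  fix <- function(p) {
    if (cfg$wrap) {
      c(wrap_coord(p[1], cfg$width), wrap_coord(p[2], cfg$height))
    } else {
      c(reflect_coord(p[1], cfg$width), reflect_coord(p[2], cfg$height))
    }
  }
  l <- fix(points$left); r <- fix(points$right)
  li <- c(cell_of(l[2], cfg$height), cell_of(l[1], cfg$width))
  ri <- c(cell_of(r[2], cfg$height), cell_of(r[1], cfg$width))
  out <- list()
  for (ch in ODOR_CHANNELS) {
    sl <- .cpp_sensor_transform(world$fields[[ch]][li[1], li[2]], floor)
    sr <- .cpp_sensor_transform(world$fields[[ch]][ri[1], ri[2]], floor)
    out[[paste0("sns_", ch, "_left")]] <- sl
    out[[paste0("sns_", ch, "_right")]] <- sr
    out[[paste0("sns_", ch)]] <- (sl + sr) / 2
  }
  structure(out, class = "cs_sensor_reading")
}

#' Construct a sensor reading from raw side values
#'
#' Convenience constructor used mostly in tests and examples: takes the six
#' log-scaled side readings directly and fills in the bilateral averages.
#'
#' @param betaine_left,betaine_right,hermi_left,hermi_right,flab_left,flab_right
#'   non-negative log-scaled intensities.
#' @return A `cs_sensor_reading`.
#' @export
sensor_reading <- function(betaine_left = 0, betaine_right = 0,
                           hermi_left = 0, hermi_right = 0,
                           flab_left = 0, flab_right = 0) {
  vals <- list(betaine = c(betaine_left, betaine_right),
               hermi = c(hermi_left, hermi_right),
               flab = c(flab_left, flab_right))
  out <- list()
  for (ch in ODOR_CHANNELS) {
    out[[paste0("sns_", ch, "_left")]] <- vals[[ch]][1]
    out[[paste0("sns_", ch, "_right")]] <- vals[[ch]][2]
    out[[paste0("sns_", ch)]] <- mean(vals[[ch]])
  }
  structure(out, class = "cs_sensor_reading")
}

#' Somatic map: virtual place code of stimulus laterality
#'
#' Combines the left-right differences of the two prey signature odors,
#' each gated by a logistic function of the relative strength of that odor
#' (`F = sns_flab - sns_hermi`, `H = -F`). The gates implement a
#' surround-suppression-like emphasis of the nearer/stronger odor: the
#' laterality signal of the weaker signature is suppressed. Betaine carries
#' no species information and does not enter the map. The output is a
#' signed turn-amplitude template, antisymmetric under left-right exchange.
#'
#' @param reading a `cs_sensor_reading`.
#' @param k0 gate steepness (defaults to the packaged constant).
#' @return A single signed number.
#' @export
somatic_map <- function(reading, k0 = cs_constants()$k0) {
  stopifnot(inherits(reading, "cs_sensor_reading"))
  .cpp_somatic_map(reading$sns_flab_left, reading$sns_flab_right,
                   reading$sns_hermi_left, reading$sns_hermi_right, k0)
}
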