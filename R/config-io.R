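#' Read a scenario configuration from a YAML file
#'
#' The file may contain three optional top-level blocks: `arena` (fields of
#' [arena_config()]), `constants` (fields of [cs_constants()]), `geometry`
#' (fields of [sensor_geometry()]), plus any top-level fields of
#' [scenario_config()] (`n_steps`, `n_trials`, `learning_enabled`,
#' `satiation_enabled`, `agent_speed`, `trace_every`, `seeds`, ...).
#' Unspecified values keep the package defaults.
#'
#' @param path path to a YAML file.
#' @return A [scenario_config()].
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("arena", "constants", "geometry", "learning_enabled",
             "satiation_enabled", "n_steps", "n_trials", "seeds",
             "agent_speed", "trace_every", "sensor_floor",
             "engage_threshold", "satiation_clamp")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- raw[setdiff(names(raw), c("arena", "constants", "geometry"))]
  args$arena <- do.call(arena_config, as.list(raw$arena))
  args$constants <- do.call(cs_constants, as.list(raw$constants))
  args$geometry <- do.call(sensor_geometry, as.list(raw$geometry))
  do.call(scenario_config, args)
}

#' Print the effective constant set
#'
#' Serialises a [cs_constants()] (YAML when available, plain `key: value`
#' lines otherwise), for use by the command-line runner's
#' `--dump-constants` flag and for recording the parameterization of a
#' run.
#'
#' @param constants a [cs_constants()].
#' @param file connection or path passed to [cat()]; default stdout.
#' @return Invisibly, the serialised string.
#' @export
dump_constants <- function(constants = cs_constants(), file = "") {
  stopifnot(inherits(constants, "cs_constants"))
  txt <- if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::as.yaml(unclass(constants))
  } else {
    paste0(names(constants), ": ",
           vapply(constants, format, character(1)), "\n", collapse = "")
  }
  cat(txt, file = file)
  invisible(txt)
}
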