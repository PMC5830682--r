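#' The standard learning-by-satiation scenario battery
#'
#' The published protocol: four mechanism combinations in the 10-Flab /
#' 3-Hermi arena (both mechanisms, learning only, satiation only, neither)
#' plus the two single-species arenas (13 Flabs alone, 13 Hermis alone,
#' both mechanisms active), each run for 6 trials of 150000 steps.
#'
#' @param n_steps,n_trials protocol size, defaulting to the standard
#'   150000 steps and 6 trials.
#' @param constants a [cs_constants()] shared by all scenarios.
#' @param ... further arguments passed to every [scenario_config()].
#' @return Named list of six `cs_scenario` objects: `both`,
#'   `learning_only`, `satiation_only`, `neither`, `flab_only`,
#'   `hermi_only`.
#' @export
standard_scenarios <- function(n_steps = 150000, n_trials = 6,
                               constants = cs_constants(), ...) {
  mixed <- arena_config(n_flab = 10, n_hermi = 3)
  flabs <- arena_config(n_flab = 13, n_hermi = 0)
  hermis <- arena_config(n_flab = 0, n_hermi = 13)
  mk <- function(arena, learn, sat) {
    scenario_config(arena = arena, learning_enabled = learn,
                    satiation_enabled = sat, n_steps = n_steps,
                    n_trials = n_trials, constants = constants, ...)
  }
  list(both = mk(mixed, TRUE, TRUE),
       learning_only = mk(mixed, TRUE, FALSE),
       satiation_only = mk(mixed, FALSE, TRUE),
       neither = mk(mixed, FALSE, FALSE),
       flab_only = mk(flabs, TRUE, TRUE),
       hermi_only = mk(hermis, TRUE, TRUE))
}

# Deterministic per-trial seed derivation: master seed plus a counter
# stride per scenario, kept within the 32-bit integer range.
derive_seeds <- function(master_seed, scenario_index, n_trials) {
  base <- (as.double(master_seed) * 1009 + scenario_index * 131071) %%
    2147480000
  as.integer(base + seq_len(n_trials))
}

#' Run a battery of scenarios
#'
#' Runs every scenario for its `n_trials` seeded trials, tallies per-trial
#' consumption, and summarises each scenario by mean and SEM (sd/sqrt(n))
#' of total consumed, percent Hermi and selectivity. Per-trial seeds come
#' from each scenario's `seeds` field when set, otherwise they are derived
#' from `master_seed` and recorded in the output, so a battery is fully
#' reproducible from one integer.
#'
#' @param scenarios a named list of [scenario_config()] objects (e.g.
#'   [standard_scenarios()]), or a single one.
#' @param master_seed integer master seed.
#' @param output_dir optional directory; when given, writes `trials.csv`
#'   and `summary.csv` there.
#' @param progress print a line per completed scenario.
#' @return List with data frames `trials` (one row per trial, with
#'   scenario id and seed) and `summary` (one row per scenario).
#' @examples
#' sc <- standard_scenarios(n_steps = 2000, n_trials = 2)["neither"]
#' run_battery(sc, master_seed = 1)$summary
#' @export
run_battery <- function(scenarios, master_seed = 1, output_dir = NULL,
                        progress = FALSE) {
  if (inherits(scenarios, "cs_scenario")) scenarios <- list(scenarios)
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios)))) {
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  }
  trials <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    stopifnot(inherits(sc, "cs_scenario"))
    seeds <- if (!is.null(sc$seeds)) as.integer(sc$seeds)
             else derive_seeds(master_seed, i, sc$n_trials)
    rows <- lapply(seeds, function(s) run_trial(sc, seed = s))
    df <- do.call(rbind, lapply(rows, as.data.frame))
    df <- cbind(scenario = names(scenarios)[i], trial = seq_along(seeds),
                df, stringsAsFactors = FALSE)
    trials[[i]] <- df
    if (progress) {
      message(sprintf("%s: mean total %.1f", names(scenarios)[i],
                      mean(df$total)))
    }
  }
  trials <- do.call(rbind, trials)
  summary <- do.call(rbind, lapply(split(trials, trials$scenario), function(d) {
    sem <- function(x) {
      x <- x[!is.na(x)]
      if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
    }
    mn <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    data.frame(scenario = d$scenario[1], n_trials = nrow(d),
               mean_total = mn(d$total), sem_total = sem(d$total),
               mean_pct_hermi = mn(d$pct_hermi),
               sem_pct_hermi = sem(d$pct_hermi),
               mean_selectivity = mn(d$selectivity),
               sem_selectivity = sem(d$selectivity),
               stringsAsFactors = FALSE)
  }))
  summary <- summary[match(names(scenarios), summary$scenario), ]
  rownames(summary) <- NULL
  rownames(trials) <- NULL
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) {
      ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok && !dir.exists(output_dir)) {
        stop("cannot create output directory: ", output_dir, call. = FALSE)
      }
    }
    write.csv(trials, file.path(output_dir, "trials.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(output_dir, "summary.csv"),
              row.names = FALSE)
  }
  list(trials = trials, summary = summary)
}
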