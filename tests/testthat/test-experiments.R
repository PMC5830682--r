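test_that("degenerate and deterministic trial contracts hold", {
  sc <- scenario_config(tiny_arena(), n_steps = 0)
  r <- run_trial(sc, seed = 1)
  expect_equal(r$total, 0)

  sc <- scenario_config(tiny_arena(), n_steps = 3000)
  a <- run_trial(sc, seed = 42)
  b <- run_trial(sc, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "consumed"), attr(b, "consumed"))
  expect_identical(attr(a, "final"), attr(b, "final"))
})

test_that("selectivity is the hermi/flab ratio with a guarded denominator", {
  expect_equal(selectivity(data.frame(consumed_hermi = 3, consumed_flab = 10)),
               0.30)
  expect_equal(selectivity(data.frame(consumed_hermi = 0, consumed_flab = 5)),
               0)
  expect_true(is.na(selectivity(data.frame(consumed_hermi = 4,
                                           consumed_flab = 0))))
})

test_that("run_battery tallies trials and summarises with SEM", {
  scs <- list(a = scenario_config(tiny_arena(), n_steps = 1500, n_trials = 3),
              b = scenario_config(tiny_arena(), n_steps = 1500, n_trials = 1))
  out <- run_battery(scs, master_seed = 2)
  expect_equal(nrow(out$trials), 4)
  expect_equal(out$summary$scenario, c("a", "b"))
  expect_equal(out$summary$n_trials, c(3, 1))
  ta <- out$trials[out$trials$scenario == "a", ]
  expect_equal(out$summary$mean_total[1], mean(ta$total))
  expect_equal(out$summary$sem_total[1], sd(ta$total) / sqrt(3))
  expect_true(is.na(out$summary$sem_total[2])) # single trial: SEM missing
  expect_equal(out$trials$total,
               out$trials$consumed_flab + out$trials$consumed_hermi +
                 out$trials$consumed_fauxflab)
})

test_that("battery CSV output is bit-identical across repeated runs", {
  sc <- list(x = scenario_config(tiny_arena(), n_steps = 2000, n_trials = 2))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_battery(sc, master_seed = 7, output_dir = d1)
  run_battery(sc, master_seed = 7, output_dir = d2)
  for (f in c("trials.csv", "summary.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("explicit per-trial seeds override the derived ones", {
  sc <- scenario_config(tiny_arena(), n_steps = 1000, n_trials = 2,
                        seeds = c(101L, 202L))
  out <- run_battery(sc, master_seed = 99)
  expect_equal(out$trials$seed, c(101L, 202L))
  direct <- run_trial(sc, seed = 101L)
  expect_equal(out$trials$total[1], direct$total)
  expect_equal(out$trials$consumed_hermi[1], direct$consumed_hermi)
})

test_that("the compiled trial loop matches the composed R update cycle", {
  sc <- scenario_config(
    arena_config(width = 25, height = 25, n_flab = 3, n_hermi = 2, seed = NULL),
    n_steps = 400
  )
  r <- run_trial(sc, seed = 17, trace_every = 1)
  tr <- attr(r, "trace")

  set.seed(17)
  st <- cyberslug:::init_forager(sc)
  for (i in 1:400) st <- cyberslug:::step_forager(st)
  expect_equal(unname(tr[400, c("x", "y")]),
               c(st$agent$x, st$agent$y), tolerance = 1e-12)
  expect_equal(unname(tr[400, "Nutrition"]), st$agent$nutrition,
               tolerance = 1e-12)
  expect_equal(unname(tr[400, c("Vh", "Vf")]),
               c(st$learning$Vh, st$learning$Vf))
  expect_equal(r$consumed_flab, unname(st$counts["flab"]))
  expect_equal(r$consumed_hermi, unname(st$counts["hermi"]))
})

test_that("per-species prey counts are invariant over a whole trial", {
  # every consumption triggers an immediate same-species respawn, so the
  # consumption log plus the fixed populations account for all dynamics
  sc <- scenario_config(arena_config(width = 30, height = 30, n_flab = 4,
                                     n_hermi = 4, consumption_radius = 2),
                        satiation_enabled = FALSE, n_steps = 8000)
  r <- run_trial(sc, seed = 23, trace_every = 0)
  expect_gt(r$total, 0)
  cons <- attr(r, "consumed")
  expect_equal(nrow(cons), r$total)
  expect_equal(sum(cons$species == "flab"), r$consumed_flab)
  expect_equal(sum(cons$species == "hermi"), r$consumed_hermi)
})

test_that("learning-disabled trials never acquire associations", {
  sc <- scenario_config(tiny_arena(), learning_enabled = FALSE,
                        satiation_enabled = FALSE, n_steps = 6000)
  r <- run_trial(sc, seed = 3, trace_every = 50)
  expect_gt(r$total, 0)
  tr <- attr(r, "trace")
  expect_true(all(tr[, "Vh"] == 0))
  expect_true(all(tr[, "Vf"] == 0))
})

test_that("an agent in an empty arena wanders with bounded heading change", {
  sc <- scenario_config(arena_config(n_flab = 0, n_hermi = 0), n_steps = 2000)
  r <- run_trial(sc, seed = 8, trace_every = 1)
  tr <- attr(r, "trace")
  dh <- diff(tr[, "heading"])
  dh <- pmin(abs(dh), 360 - abs(dh))
  expect_lte(max(dh), 1)
  expect_equal(r$total, 0)
})

test_that("a hungry naive agent approaches a lone hermi source", {
  sc <- scenario_config(
    arena_config(width = 40, height = 40, n_flab = 0, n_hermi = 1),
    learning_enabled = FALSE, satiation_enabled = FALSE, n_steps = 20000
  )
  caught <- sapply(c(1, 2, 3), function(s) run_trial(sc, seed = s)$total)
  expect_gt(sum(caught), 0) # net displacement toward prey ends in capture
})

test_that("a trained satiated agent keeps away from a lone flab", {
  sc <- scenario_config(
    arena_config(width = 40, height = 40, n_flab = 1, n_hermi = 0,
                 prey_step_length = 0),
    n_steps = 4000,
    constants = cs_constants(nutrition_init = 2.5) # well fed
  )
  for (seed in c(5, 6)) {
    set.seed(seed)
    st <- cyberslug:::init_forager(sc)
    st$learning$Vf <- 1     # aversively trained
    px <- st$world$prey$x[1]; py <- st$world$prey$y[1]
    d <- numeric(1500)
    for (i in seq_along(d)) {
      st <- cyberslug:::step_forager(st)
      dx <- abs(st$agent$x - px); dx <- min(dx, 40 - dx)
      dy <- abs(st$agent$y - py); dy <- min(dy, 40 - dy)
      d[i] <- sqrt(dx^2 + dy^2)
    }
    expect_equal(sum(st$counts), 0)
    # never closes on the source, and keeps its distance on average
    expect_gt(min(d), 2)
    expect_gte(mean(d[751:1500]), mean(d[1:750]) - 3)
  }
})
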