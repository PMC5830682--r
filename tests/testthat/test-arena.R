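test_that("init_arena places the configured prey and respects the seed", {
  w <- init_arena(arena_config(n_flab = 10, n_hermi = 3, seed = 1))
  expect_equal(nrow(w$prey), 13)
  expect_equal(sum(w$prey$species == "flab"), 10)
  expect_equal(sum(w$prey$species == "hermi"), 3)
  expect_true(all(w$prey$x >= 0 & w$prey$x < 50))
  expect_true(all(sapply(w$fields, function(f) all(f == 0))))

  w2 <- init_arena(arena_config(n_flab = 10, n_hermi = 3, seed = 1))
  expect_identical(w$prey, w2$prey)

  w0 <- init_arena(arena_config(n_flab = 0, n_hermi = 0, seed = 1))
  expect_equal(nrow(w0$prey), 0)
  w0 <- settle_odors(w0, 5)
  expect_true(all(w0$fields$betaine == 0))
})

test_that("invalid arena configurations are rejected", {
  expect_error(arena_config(width = 0), "dimensions")
  expect_error(arena_config(n_flab = -1), "non-negative")
  expect_error(arena_config(diffusion_rate = 1), "diffusion_rate")
  expect_error(arena_config(decay_rate = -0.1), "decay_rate")
  expect_error(arena_config(consumption_radius = 0), "consumption_radius")
})

test_that("diffusion conserves mass at zero decay and keeps fields non-negative", {
  f <- matrix(0, 21, 21)
  f[11, 11] <- 5
  peak <- 5
  for (i in 1:50) {
    f <- cyberslug:::.cpp_diffuse_decay(f, 0.4, 0, TRUE)
    expect_true(all(f >= 0))
    expect_lt(max(f), peak + 1e-12) # peak decreases monotonically
    peak <- max(f)
    expect_equal(sum(f), 5, tolerance = 1e-9)
  }
  # mass is conserved on a bounded (reflecting-edge) grid as well
  g <- matrix(0, 9, 9); g[1, 1] <- 2
  for (i in 1:20) g <- cyberslug:::.cpp_diffuse_decay(g, 0.5, 0, FALSE)
  expect_equal(sum(g), 2, tolerance = 1e-9)
  # decay removes the expected fraction
  h <- cyberslug:::.cpp_diffuse_decay(f, 0.4, 0.25, TRUE)
  expect_equal(sum(h), sum(f) * 0.75, tolerance = 1e-9)
})

test_that("prey odors appear on the correct channels", {
  w <- settle_odors(lone_prey_world("hermi"), 30)
  expect_gt(sum(w$fields$betaine), 0)
  expect_gt(sum(w$fields$hermi), 0)
  expect_identical(sum(w$fields$flab), 0)
  expect_equal(which.max(w$fields$hermi), which.max(w$fields$betaine))

  # the Batesian mimic emits on the flab channel
  wm <- settle_odors(lone_prey_world("fauxflab"), 30)
  expect_gt(sum(wm$fields$flab), 0)
  expect_identical(sum(wm$fields$hermi), 0)
})

test_that("prey motion is a zero-drift random walk with linear MSD growth", {
  cfg <- arena_config(width = 400, height = 400, n_flab = 100, n_hermi = 0,
                      prey_step_length = 0.2, seed = 5)
  w <- init_arena(cfg)
  w$prey$x <- rep(200, 100); w$prey$y <- rep(200, 100) # far from the wrap seam
  x0 <- w$prey$x; y0 <- w$prey$y
  msd <- function(w) mean((w$prey$x - x0)^2 + (w$prey$y - y0)^2)
  n1 <- 250; n2 <- 1000
  for (i in 1:n1) w <- move_prey(w)
  m1 <- msd(w)
  for (i in 1:(n2 - n1)) w <- move_prey(w)
  m2 <- msd(w)
  # mean displacement ~ 0, MSD grows roughly linearly in time
  expect_lt(abs(mean(w$prey$x - x0)), 5)
  expect_lt(abs(mean(w$prey$y - y0)), 5)
  expect_gt(m2 / m1, 2)
  expect_lt(m2 / m1, 8)

  # zero step length leaves positions unchanged
  wz <- init_arena(arena_config(prey_step_length = 0, seed = 2))
  pz <- wz$prey
  wz <- move_prey(wz)
  expect_identical(wz$prey$x, pz$x)
  expect_identical(wz$prey$y, pz$y)

  # determinism
  wa <- init_arena(arena_config(seed = 9)); wb <- init_arena(arena_config(seed = 9))
  set.seed(3); for (i in 1:10) wa <- move_prey(wa)
  set.seed(3); for (i in 1:10) wb <- move_prey(wb)
  expect_identical(wa$prey, wb$prey)
})

test_that("consumption removes nearby prey and respawn keeps counts constant", {
  w <- init_arena(arena_config(width = 30, height = 30, n_flab = 2,
                               n_hermi = 1, consumption_radius = 1.5,
                               seed = 4))
  w$prey$x <- c(10, 10.5, 25)   # two flab together, one hermi far away
  w$prey$y <- c(10, 10, 25)
  w$prey$species <- c("flab", "flab", "hermi")

  # nothing in range
  res <- consume_and_respawn(w, c(2, 2))
  expect_identical(res$consumed, character(0))
  expect_identical(res$world$prey, w$prey)

  # two prey within the radius on one step: both consumed, both respawned
  res <- consume_and_respawn(w, c(10.2, 10))
  expect_identical(res$consumed, c("flab", "flab"))
  expect_equal(sum(res$world$prey$species == "flab"), 2)
  expect_equal(sum(res$world$prey$species == "hermi"), 1)
  moved <- res$world$prey$x != w$prey$x | res$world$prey$y != w$prey$y
  expect_identical(which(moved), c(1L, 2L))
})
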