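cs <- cs_constants()

test_that("incentive reduces correctly in the naive and learned limits", {
  zero <- sensor_reading()
  r <- incentive(zero, 0.5, 0.5, cs)
  expect_equal(r$R_plus, 0)
  expect_equal(r$R_minus, 0)
  expect_equal(r$incentive, 0)

  # a naive agent tracks betaine exactly
  rd <- sensor_reading(betaine_left = 3, betaine_right = 2,
                       hermi_left = 2, hermi_right = 2,
                       flab_left = 1, flab_right = 1)
  expect_equal(incentive(rd, 0, 0, cs)$incentive, rd$sns_betaine)

  # a strong learned flab signal drives incentive negative
  rdf <- sensor_reading(betaine_left = 3, betaine_right = 3,
                        flab_left = 5, flab_right = 5)
  csx <- cs_constants(k3 = 2)
  r2 <- incentive(rdf, 0, 1, csx)
  expect_equal(r2$R_minus, 2 * 5)
  expect_lt(r2$incentive, 0)

  # the learned hermi association attenuates the betaine term
  rdh <- sensor_reading(betaine_left = 3, betaine_right = 3,
                        hermi_left = 4, hermi_right = 4)
  r3 <- incentive(rdh, 1, 0, cs)
  expect_equal(r3$R_plus, 3 / (1 + cs$k1 * 4) + cs$k3 * 4)
})

test_that("nutrition follows the decay-plus-feeding recursion exactly", {
  expect_equal(update_nutrition(1, 0, cs), 0.9995)
  expect_equal(update_nutrition(0.8, 1, cs), 0.8 * 0.9995 + 0.3)
  n <- 0.8
  for (i in 1:1000) n <- update_nutrition(n, 0, cs)
  expect_equal(n, 0.8 * 0.9995^1000, tolerance = 1e-12)
})

test_that("satiation is a strictly increasing sigmoid in (0, 1)", {
  grid <- seq(0, 5, by = 0.05)
  s <- satiation(grid, cs)
  expect_true(all(s > 0 & s < 1))
  expect_true(all(diff(s) > 0))
  expect_equal(satiation(0, cs), 1 / (1 + cs$k4 * exp(2))^2)
  expect_gt(satiation(50, cs), 0.999)
  expect_lt(satiation(0.4, cs), satiation(0.8, cs))
  expect_lt(satiation(0.8, cs), satiation(1.2, cs))
})

test_that("appetitive state integrates incentive, satiation, and the switch", {
  # suppression term vanishes when the previous switch was avoidance (+1)
  expect_equal(app_state(0.3, 0.2, 1, cs),
               0.01 + 1 / (1 + exp(-cs$k5 * 0.3 + cs$k6 * 0.2)))
  # suppression is maximal at the approach pole (-1)
  expect_equal(app_state(0.3, 0.2, -1, cs) - app_state(0.3, 0.2, 1, cs),
               -2 * cs$k7)
  # high satiation pins the sigmoid term to (near) zero
  expect_equal(app_state(0, 1, 1, cs), 0.01 + 1 / (1 + exp(cs$k6)),
               tolerance = 1e-12)
  # strictly increasing in incentive at fixed satiation and switch
  # (checked where the sigmoid is not numerically saturated)
  for (s in c(0, 0.02, 0.05)) {
    v <- sapply(seq(-4, 4, by = 0.25), app_state, satiation = s,
                prev_switch = 0.5, constants = cs)
    expect_true(all(diff(v) > 0))
  }
})

test_that("the approach-avoidance switch crosses zero at the threshold", {
  expect_equal(app_state_switch(0.245, cs), 0)
  expect_lt(app_state_switch(0.545, cs), -0.95) # approach pole
  expect_gt(app_state_switch(0.029, cs), 0.95)  # avoidance pole
  v <- app_state_switch(seq(-0.5, 1.5, by = 0.01), cs)
  expect_true(all(v >= -1 & v <= 1))
  expect_true(all(diff(v) <= 0)) # non-increasing everywhere
  # strictly decreasing and strictly inside (-1, 1) short of saturation
  v2 <- app_state_switch(seq(0.05, 0.45, by = 0.005), cs)
  expect_true(all(v2 > -1 & v2 < 1))
  expect_true(all(diff(v2) < 0))
})

test_that("turn angle carries the switch sign with map-modulated magnitude", {
  expect_equal(turn_angle(0, 0.7, cs), 0)
  for (sm in seq(-2, 2, by = 0.5)) {
    expect_gt(turn_angle(0.9, sm, cs), 0)
    expect_lt(turn_angle(-0.9, sm, cs), 0)
  }
  # |turn| decreases as (3*Somatic_Map - switch) grows
  mags <- sapply(seq(-2, 2, by = 0.25), function(sm)
    abs(turn_angle(-0.9, sm, cs)))
  expect_true(all(diff(mags) < 0))
})

test_that("wander turns are uniform on [-1, 1) and reproducible", {
  set.seed(11)
  x <- wander_turn(1e5)
  expect_gte(min(x), -1)
  expect_lt(max(x), 1)
  se <- sqrt(1 / 3) / sqrt(length(x))
  expect_lt(abs(mean(x)), 3 * se)
  set.seed(11)
  expect_identical(wander_turn(1e5), x)
})
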