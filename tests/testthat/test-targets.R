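test_that("annual logit rates of change match the closed form", {
  p_const <- rep(0.3, 16)
  expect_true(all(annual_logit_aroc(p_const) == 0))
  p <- rep(0.5, 16); p[2] <- 0.45
  ar <- annual_logit_aroc(p)
  expect_equal(ar[1, 1], logit(0.45) - logit(0.5), tolerance = 1e-12)
  expect_equal(unname(ar[1, 1]), -0.2006707, tolerance = 1e-6)
  expect_error(annual_logit_aroc(rep(0.3, 10)), "16-year")
  expect_error(annual_logit_aroc(c(rep(0.3, 15), 1.2)), "\\[0, 1\\]")
})

test_that("recency weights normalize and weight recent years more", {
  cfg <- projection_config(gamma = 1)
  expect_equal(sum(cfg$weights), 1, tolerance = 1e-12)
  ## gamma = 1: w_2015 = 15/120 = 0.125
  expect_equal(cfg$weights[15], 0.125, tolerance = 1e-12)
  ## gamma = 0: uniform mean
  cfg0 <- projection_config(gamma = 0)
  expect_equal(cfg0$weights, rep(1 / 15, 15), tolerance = 1e-12)
  for (g in c(0, 0.5, 1, 2, 3)) {
    expect_equal(sum(projection_config(gamma = g)$weights), 1,
                 tolerance = 1e-12)
  }
  ## constant decline is reproduced for any gamma
  ar <- matrix(-0.05, 1, 15)
  for (g in c(0, 1, 2)) {
    expect_equal(weighted_aroc(ar, projection_config(gamma = g)), -0.05,
                 tolerance = 1e-12)
  }
})

test_that("projection is exact on the logit scale", {
  ## invlogit(-1 + 10 * -0.05) = invlogit(-1.5)
  expect_equal(project_prevalence(invlogit(-1), -0.05),
               invlogit(-1.5), tolerance = 1e-12)
  expect_equal(project_prevalence(invlogit(-1.5), -0.05, horizon = 10),
               1 / (1 + exp(2)), tolerance = 1e-9)
  expect_equal(project_prevalence(0.37, 0), 0.37, tolerance = 1e-9)
  ## constant decline d: logit(p_2025) = logit(p_2015) + 10 d, to 1e-12
  d <- -0.033
  p <- invlogit(-0.6 + d * (0:15))
  ar <- weighted_aroc(annual_logit_aroc(p))
  p2025 <- project_prevalence(p[16], ar)
  expect_equal(logit(p2025), logit(p[16]) + 10 * d, tolerance = 1e-12)
  expect_true(p2025 > 0 && p2025 < 1)
})

test_that("targets resolve from the 2010 aggregate or a fixed level", {
  ## relative: continental 2010 prevalence 0.50, reduction 0.40 -> 0.30
  w <- tiny_world(); grid <- w$grid
  series <- expand.grid(country_id = sort(unique(grid$country_id)),
                        year = c(2000, 2005, 2010, 2016))
  series$indicator <- "stunting"; series$prevalence <- 0.50
  spec <- resolve_targets(target_spec("stunting", "relative"), series, grid)
  expect_equal(spec$resolved_target, 0.30, tolerance = 1e-12)
  ## fixed wasting target: 5%
  wspec <- resolve_targets(target_spec("wasting", "fixed"))
  expect_equal(wspec$resolved_target, 0.05)
  expect_error(resolve_targets(target_spec("stunting", "relative")),
               "2010")
})

test_that("pace and acceleration classify pixels like the map legends", {
  ## achieved 0.05, required 0.10 -> pace 50%, acceleration 2.0
  target <- 0.2
  req <- 0.10
  p15 <- invlogit(logit(target) + 10 * req)
  d <- -0.05
  p <- invlogit(logit(p15) - d * (15:0))
  out <- pace_and_acceleration(p, target)
  expect_equal(out$achieved, 0.05, tolerance = 1e-9)
  expect_equal(out$required, 0.10, tolerance = 1e-9)
  expect_equal(out$pace_ratio, 50, tolerance = 1e-6)
  expect_equal(out$acceleration, 2, tolerance = 1e-6)
  expect_equal(out$accel_class, "up to 200%")
  ## already below the target in 2015 -> met
  pm <- rep(target / 2, 16)
  expect_equal(pace_and_acceleration(pm, target)$status, "met")
  ## increasing prevalence -> non-decreasing class
  pi <- invlogit(seq(-1.5, -0.5, length.out = 16))
  oi <- pace_and_acceleration(pi, target)
  expect_equal(oi$status, "non-decreasing")
  expect_equal(oi$accel_class, "non-decreasing")
  ## acceleration above 4 lands in the >400% class
  p_slow <- invlogit(logit(p15) + 0.01 * (15:0))
  expect_equal(pace_and_acceleration(p_slow, target)$accel_class, ">400%")
})

test_that("attainment probabilities count draws below the target", {
  w <- tiny_world(); grid <- w$grid
  nd <- 250
  prev <- array(0.20, dim = c(nd, 64, 16))
  cube <- manual_cube(prev, 2000:2015)
  pp <- prob_target_met(cube, 0.242, grid)
  expect_true(all(pp == 1))
  ## 100 of 250 draws below the target -> 0.40
  prev2 <- prev
  prev2[1:100, , 16] <- 0.22
  prev2[101:250, , 16] <- 0.26
  pp2 <- prob_target_met(manual_cube(prev2, 2000:2015), 0.242, grid)
  expect_true(all(pp2 == 0.4))
  ## nonincreasing as the target decreases
  set.seed(3)
  prev3 <- array(runif(nd * 64), dim = c(nd, 64, 1))
  cube3 <- manual_cube(prev3, 2015)
  p_hi <- prob_target_met(cube3, 0.6, grid)
  p_lo <- prob_target_met(cube3, 0.3, grid)
  expect_true(all(p_lo <= p_hi))
  ## admin level: draws of the unit aggregate
  ad <- prob_target_met(manual_cube(prev2, 2000:2015), 0.242, grid, "admin1")
  expect_true(all(ad$prob == 0.4))
  ## draws symmetric around the target: probability ~ 1/2
  prev4 <- array(rep(c(0.2, 0.3), each = 1), dim = c(2, 64, 1))
  expect_true(all(prob_target_met(manual_cube(prev4, 2015), 0.25, grid) == 0.5))
})

test_that("raking with a constant factor is documented to change the AROC", {
  ## the multiplicative calibration does not cancel in logit differences,
  ## which is why projections are computed from the raked series
  p <- invlogit(seq(-0.5, -1.4, length.out = 16))
  a0 <- weighted_aroc(annual_logit_aroc(p))
  a1 <- weighted_aroc(annual_logit_aroc(pmin(1, 1.3 * p)))
  expect_gt(abs(a1 - a0), 1e-4)
  ## factor exactly 1 leaves it unchanged
  expect_equal(weighted_aroc(annual_logit_aroc(1 * p)), a0)
})
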