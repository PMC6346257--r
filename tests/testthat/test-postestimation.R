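test_that("admin aggregation is the population-weighted draw mean", {
  w <- tiny_world(); grid <- w$grid
  nd <- 3; P <- 64; Tn <- 16
  prev <- array(0.2, dim = c(nd, P, Tn))
  cube <- manual_cube(prev, 2000:2015)
  agg <- aggregate_admin(cube, grid, "national")
  expect_true(all(abs(agg$draws - 0.2) < 1e-12))
  ## two-pixel hand check: {0.2, 0.4} with pop {100, 300} -> 0.35
  g2 <- grid
  g2$mask <- rep(TRUE, P); g2$mask[1:2] <- FALSE
  g2$population[] <- 0; g2$population[1, ] <- 100; g2$population[2, ] <- 300
  prev2 <- prev; prev2[, 1, ] <- 0.2; prev2[, 2, ] <- 0.4
  agg2 <- suppressWarnings(aggregate_admin(manual_cube(prev2, 2000:2015),
                                           g2, "national"))
  expect_equal(as.vector(agg2$draws), rep(0.35, nd * Tn))
  ## consistency: national equals population-weighted mean of admin1
  set.seed(2)
  prev3 <- array(runif(nd * P * Tn), dim = c(nd, P, Tn))
  cube3 <- manual_cube(prev3, 2000:2015)
  nat <- aggregate_admin(cube3, grid, "national")
  ad1 <- aggregate_admin(cube3, grid, "admin1")
  a2c <- tapply(grid$country_id, grid$admin1_id, function(v) v[1])
  for (ci in seq_along(nat$units)) {
    cc <- nat$units[ci]
    ui <- which(a2c[as.character(ad1$units)] == cc)
    for (t in c(1, 9)) {
      manual <- as.vector(ad1$draws[, ui, t] %*% ad1$population[ui, t] /
                            sum(ad1$population[ui, t]))
      expect_equal(nat$draws[, ci, t], manual, tolerance = 1e-12)
    }
  }
  ## aggregation is linear pre-clipping
  half <- manual_cube(prev3 / 2, 2000:2015)
  nat_half <- aggregate_admin(half, grid, "national")
  expect_equal(nat_half$draws, nat$draws / 2, tolerance = 1e-12)
})

test_that("raking factors are target/estimate ratios, linearly interpolated", {
  w <- tiny_world(); grid <- w$grid
  nd <- 4
  prev <- array(0.25, dim = c(nd, 64, 16))
  cube <- manual_cube(prev, 2000:2015)
  nat <- aggregate_admin(cube, grid, "national")
  series <- expand.grid(country_id = nat$units, year = c(2000, 2005, 2010, 2016))
  series$indicator <- "stunting"
  series$prevalence <- 0.30
  series$prevalence[series$year == 2016] <- 0.24
  rt <- compute_raking_factors(nat, series)
  ## anchor 2000: 0.30 / 0.25 = 1.2
  expect_true(all(abs(rt$factors[, , 1] - 1.2) < 1e-12))
  ## 2015 target interpolated between 2010 and 2016: 0.30 + (5/6)(0.24-0.30) = 0.25
  expect_true(all(abs(rt$factors[, , 16] - 0.25 / 0.25) < 1e-12))
  ## linear interpolation of factors between anchors:
  ## factor(2010) = 1.2, factor(2015) = 1.0 -> factor(2012) = 1.12
  expect_true(all(abs(rt$factors[, , 13] - 1.12) < 1e-12))
  ## zero estimate errors
  prev0 <- prev; prev0[] <- 0
  nat0 <- aggregate_admin(manual_cube(prev0, 2000:2015), grid, "national")
  expect_error(compute_raking_factors(nat0, series), "zero")
  ## missing series year errors
  expect_error(compute_raking_factors(nat, series[series$year != 2005, ]),
               "must cover")
})

test_that("raking multiplies, clamps at one, and hits anchors exactly", {
  w <- tiny_world(); grid <- w$grid
  nd <- 5
  set.seed(4)
  prev <- array(runif(nd * 64 * 16, 0.05, 0.35), dim = c(nd, 64, 16))
  cube <- manual_cube(prev, 2000:2015)
  nat <- aggregate_admin(cube, grid, "national")
  series <- expand.grid(country_id = nat$units, year = c(2000, 2005, 2010, 2016))
  series$indicator <- "stunting"; series$prevalence <- 0.22
  rt <- compute_raking_factors(nat, series)
  raked <- apply_raking(cube, rt, grid)
  expect_true(raked$raked)
  expect_equal(raked$clip_count, 0L)
  nat2 <- aggregate_admin(raked, grid, "national")
  for (yy in c(2000, 2005, 2010)) {
    t <- match(yy, nat2$years)
    expect_true(all(abs(nat2$draws[, , t] - 0.22) < 1e-10))
  }
  ## identity factors leave the cube unchanged
  rt1 <- rt; rt1$factors[] <- 1
  same <- apply_raking(cube, rt1, grid)
  expect_equal(same$prevalence, cube$prevalence)
  ## clamping: factor 4 on p = 0.3 -> 1, counted
  rt4 <- rt; rt4$factors[] <- 4
  clipped <- apply_raking(manual_cube(array(0.3, c(nd, 64, 16)), 2000:2015),
                          rt4, grid)
  expect_true(all(clipped$prevalence == 1))
  expect_equal(clipped$clip_count, nd * 64L * 16L)
})

test_that("masking uses the population threshold and is idempotent", {
  cf <- world_config(n_rows = 6, n_cols = 6, years = 2000:2002,
                     country_rows = 1, country_cols = 1, admin1_rows = 1,
                     admin1_cols = 1, mask_pop_threshold = 10)
  w <- make_world(cf, seed = 12)
  grid <- w$grid
  ## a pixel with population density below 10 is masked
  low <- apply(grid$population, 1, min) < 10
  expect_identical(grid$mask, low)
  expect_true(any(low))
  v <- seq_len(36) / 36
  vm <- apply_mask(v, grid)
  expect_true(all(is.na(vm[grid$mask])))
  expect_identical(apply_mask(vm, grid), vm)
  ## all-unmasked grid: identity
  g0 <- grid; g0$mask[] <- FALSE
  expect_identical(apply_mask(v, g0), v)
})

test_that("population-weighted tail classes obey the cumulative rule", {
  ## ten equal-population pixels: the lowest tail is exactly the smallest one
  v <- c(5, 3, 9, 1, 7, 2, 8, 4, 10, 6)
  cl <- pw_quantile_classes(v, rep(1, 10), frac = 0.10)
  expect_equal(which(cl == "lowest"), which.min(v))
  expect_equal(which(cl == "highest"), which.max(v))
  ## all-equal field: deterministic tie-break, no pixel in both tails
  cle <- pw_quantile_classes(rep(1, 10), rep(1, 10), frac = 0.10)
  expect_equal(sum(cle == "lowest"), 1L)
  expect_equal(sum(cle == "highest"), 1L)
  expect_true(which(cle == "lowest") != which(cle == "highest"))
  ## brute-force cumulative property on random cases
  set.seed(6)
  for (i in 1:20) {
    n <- 30
    vals <- rnorm(n); pop <- runif(n, 0.1, 5)
    cl <- pw_quantile_classes(vals, pop, frac = 0.25)
    tot <- sum(pop)
    o <- order(vals, seq_len(n))
    in_lo <- o %in% which(cl == "lowest")
    csum <- cumsum(pop[o])
    k <- sum(in_lo)
    expect_true(all(which(in_lo) == seq_len(k)))
    if (k > 0) expect_lte(csum[k], 0.25 * tot)
    expect_gt(csum[k + 1], 0.25 * tot)
  }
  expect_error(pw_quantile_classes(1:3, c(0, 0, 0)), "positive")
})
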