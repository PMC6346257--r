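## synthetic WHZ microdata with a known 12-month sinusoid
seasonal_records <- function(n = 5000, amp = 0.4, noise_sd = 0.1, seed = 21,
                             n_countries = 3) {
  set.seed(seed)
  m <- sample(1:12, n, replace = TRUE)
  data.frame(whz = amp * sin(2 * pi * m / 12) + rnorm(n, 0, noise_sd),
             interview_month = m,
             interview_year = sample(2000:2010, n, replace = TRUE),
             region_id = 1L,
             country_id = sample(seq_len(n_countries), n, replace = TRUE))
}

test_that("the seasonal model recovers an injected sinusoid", {
  rec <- seasonal_records()
  fit <- fit_seasonal_model(rec)
  amp <- unname(seasonal_amplitude(fit))
  expect_gt(amp, 0.3)
  expect_lt(amp, 0.5)
  ## periodic component is centered over the cycle
  expect_lt(abs(mean(fit$effects$f_per)), 1e-10)
  ## constant WHZ -> no seasonal effect
  recc <- rec; recc$whz <- 0.7
  fitc <- fit_seasonal_model(recc)
  expect_lt(max(abs(fitc$effects$f_per)), 1e-6)
  ## domain check
  rec13 <- rec; rec13$interview_month[1] <- 13
  expect_error(fit_seasonal_model(rec13), "1..12")
  ## single-month region advises skipping
  rec1m <- rec; rec1m$interview_month <- 6
  expect_error(fit_seasonal_model(rec1m), "single interview month")
})

test_that("adjustment subtracts only the periodic effect", {
  ## hand-built model: +0.3 in June, -0.3 in December, 0 elsewhere
  eff <- data.frame(region_id = 1L, month = 1:12, f_per = 0)
  eff$f_per[6] <- 0.3; eff$f_per[12] <- -0.3
  model <- structure(list(effects = eff, fitted_scale = 1,
                          country_effect = "random"),
                     class = "seasonal_model")
  rec <- data.frame(whz = c(-1, -1, -1), interview_month = c(6L, 12L, 3L),
                    region_id = 1L)
  adj <- adjust_seasonality(rec, model)
  expect_equal(adj$whz, c(-1.3, -0.7, -1))
  ## identity when the periodic component is zero
  model0 <- model; model0$effects$f_per <- 0
  expect_equal(adjust_seasonality(rec, model0)$whz, rec$whz)
  ## records without a month are dropped; missing regions error
  recna <- rbind(rec, data.frame(whz = 0, interview_month = NA, region_id = 1L))
  expect_equal(nrow(adjust_seasonality(recna, model)), 3L)
  rec2 <- rec; rec2$region_id <- 9L
  expect_error(adjust_seasonality(rec2, model), "region")
  ## uniform month representation: annual mean unchanged by adjustment
  recu <- data.frame(whz = rnorm(120), interview_month = rep(1:12, 10),
                     region_id = 1L)
  adju <- adjust_seasonality(recu, model)
  expect_lt(abs(mean(adju$whz) - mean(recu$whz)), 1e-12)
})

test_that("refitting after adjustment removes most of the seasonal signal", {
  rec <- seasonal_records(n = 6000, amp = 0.4)
  fit <- fit_seasonal_model(rec)
  adj <- adjust_seasonality(rec, fit)
  refit <- fit_seasonal_model(adj)
  expect_lt(unname(seasonal_amplitude(refit)),
            0.2 * unname(seasonal_amplitude(fit)))
})

test_that("polygon resampling conserves mass and respects population", {
  w <- tiny_world()
  grid <- w$grid
  poly_obs <- function(unit, year = 2005, N = 40, C = 10) {
    as_cluster_obs(data.frame(cluster_id = 1L, indicator = "stunting",
                              x = NA_real_, y = NA_real_, polygon_id = unit,
                              year = year, month = 4L, N = N, C = C,
                              weight = 1))
  }
  ## uniform population, k = 1: centroid near the unit's geometric center
  gu <- grid; gu$population[] <- 10
  ob <- poly_obs(1L)
  ps <- resample_polygon_obs(ob, gu, n_samples = 4000, k = 1, seed = 5)
  sel <- grid$admin2_id == 1L
  ctr <- c(mean(range(grid$coords[sel, 1])), mean(range(grid$coords[sel, 2])))
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$weight, 1)
  expect_lt(max(abs(c(ps$x, ps$y) - ctr)), 0.5)
  ## population concentrated in one pixel: all centroids inside it
  gc <- grid
  gc$population[] <- 0
  hot <- which(grid$admin2_id == 1L)[1]
  gc$population[hot, ] <- 100
  ps3 <- resample_polygon_obs(ob, gc, n_samples = 2000, k = 3, seed = 5)
  expect_equal(sum(ps3$weight), 1, tolerance = 1e-12)
  expect_true(all(abs(ps3$x - grid$coords[hot, 1]) <= 0.5 + 1e-9))
  expect_true(all(abs(ps3$y - grid$coords[hot, 2]) <= 0.5 + 1e-9))
  ## weights sum to one per parent for several polygons (1e-12)
  many <- as_cluster_obs(data.frame(cluster_id = 1:4, indicator = "stunting",
                                    x = NA_real_, y = NA_real_,
                                    polygon_id = c(1L, 2L, 3L, 4L),
                                    year = 2005, month = 4L, N = 30, C = 5,
                                    weight = 1))
  psm <- resample_polygon_obs(many, grid, n_samples = 3000, seed = 8)
  ws <- tapply(psm$weight, psm$parent_obs_id, sum)
  expect_true(all(abs(ws - 1) < 1e-12))
  ## seeded reproducibility
  psm2 <- resample_polygon_obs(many, grid, n_samples = 3000, seed = 8)
  expect_identical(psm, psm2)
  ## error paths
  gz <- grid; gz$population[grid$admin2_id == 2L, ] <- 0
  expect_error(resample_polygon_obs(poly_obs(2L), gz), "populated")
  expect_error(resample_polygon_obs(ob, grid, n_samples = 10, k = 50),
               "exceed")
})

test_that("two equal far-apart population masses split weights evenly", {
  w <- tiny_world()
  grid <- w$grid
  grid$population[] <- 0
  u <- which(grid$admin2_id == 1L)
  a <- u[1]; b <- u[length(u)]
  grid$population[c(a, b), ] <- 500
  ob <- as_cluster_obs(data.frame(cluster_id = 1L, indicator = "stunting",
                                  x = NA_real_, y = NA_real_, polygon_id = 1L,
                                  year = 2005, month = 4L, N = 30, C = 5,
                                  weight = 1))
  ps <- resample_polygon_obs(ob, grid, n_samples = 10000, k = 2, seed = 11)
  expect_equal(sort(ps$weight), sort(1 - ps$weight), tolerance = 1e-12)
  expect_true(all(abs(ps$weight - 0.5) < 0.02))
})
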