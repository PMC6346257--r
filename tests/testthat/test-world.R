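test_that("world generation is deterministic and partitions nest", {
  cf <- world_config(n_rows = 4, n_cols = 4, years = 2000:2002,
                     country_rows = 1, country_cols = 1,
                     admin1_rows = 1, admin1_cols = 1)
  w1 <- make_world(cf, seed = 9)
  expect_true(all(w1$grid$country_id == 1L))
  w2 <- make_world(cf, seed = 9)
  expect_identical(w1$grid$population, w2$grid$population)
  expect_identical(w1$covariates$values, w2$covariates$values)
  ## three admin1 blocks in one country, each mapping to that country
  cf3 <- world_config(n_rows = 6, n_cols = 4, years = 2000:2001,
                      country_rows = 1, country_cols = 1,
                      admin1_rows = 3, admin1_cols = 1)
  w3 <- make_world(cf3, seed = 1)
  expect_setequal(unique(w3$grid$admin1_id), 1:3)
  expect_true(all(tapply(w3$grid$country_id, w3$grid$admin1_id,
                         function(v) length(unique(v))) == 1))
  ## non-nestable partitions are a configuration error
  expect_error(world_config(n_rows = 10, n_cols = 10, country_rows = 3),
               "configuration error")
  ## static covariates identical across years
  expect_true(all(w1$covariates$values[, 1, 2] == w1$covariates$values[, 3, 2]))
})

test_that("truth surface reduces to its components in degenerate cases", {
  w <- tiny_world()
  ## no field, no covariate weight: logit 0, prevalence 1/2
  tr0 <- simulate_truth(w$grid, w$covariates,
                        gp_hyperparams(spatial_var = 0), beta = c(0, 0, 0),
                        intercept = 0, seed = 1)
  expect_true(all(tr0$logit_prev == 0))
  expect_true(all(invlogit(tr0$logit_prev) == 0.5))
  ## identity: single covariate with unit weight
  tr1 <- simulate_truth(w$grid, w$covariates,
                        gp_hyperparams(spatial_var = 0), beta = c(1, 0, 0),
                        intercept = 0, seed = 1)
  expect_equal(tr1$logit_prev, w$covariates$values[, , 1])
  expect_error(simulate_truth(w$grid, w$covariates, beta = c(1, 0)),
               "one weight per covariate")
})

test_that("the simulated field has the AR1 year correlation (Monte Carlo)", {
  cf <- world_config(n_rows = 6, n_cols = 6, years = 2000:2003,
                     country_rows = 1, country_cols = 1,
                     admin1_rows = 1, admin1_cols = 1)
  w <- make_world(cf, seed = 4)
  gp <- gp_hyperparams(spatial_range = 2, spatial_var = 1, ar1_rho = 0.8)
  acc <- matrix(NA_real_, 200, 2)
  for (s in 1:200) {
    tr <- simulate_truth(w$grid, w$covariates, gp, beta = c(0, 0, 0),
                         intercept = 0, seed = 1000 + s)
    f <- tr$logit_prev
    acc[s, 1] <- mean(f[, 1] * f[, 2] + f[, 2] * f[, 3] + f[, 3] * f[, 4]) / 3
    acc[s, 2] <- mean(f^2)
  }
  lag1 <- mean(acc[, 1]) / mean(acc[, 2])
  expect_gt(lag1, 0.75)
  expect_lt(lag1, 0.85)
  ## marginal variance matches sigma2 within Monte Carlo error
  expect_equal(mean(acc[, 2]), 1, tolerance = 0.1)
})

test_that("the simulated field matches the Matern correlogram at test distances", {
  cf <- world_config(n_rows = 8, n_cols = 8, years = 2000:2001,
                     country_rows = 1, country_cols = 1,
                     admin1_rows = 1, admin1_cols = 1)
  w <- make_world(cf, seed = 4)
  gp <- gp_hyperparams(spatial_range = 3, spatial_var = 1, ar1_rho = 0.5)
  D <- round(as.matrix(dist(w$grid$coords)), 6)
  test_d <- c(1, 3, 5)
  pairs <- lapply(test_d, function(dd) which(D == dd, arr.ind = TRUE))
  est <- matrix(0, 150, length(test_d))
  for (s in 1:150) {
    f <- simulate_truth(w$grid, w$covariates, gp, beta = c(0, 0, 0),
                        intercept = 0, seed = 3000 + s)$logit_prev[, 1]
    est[s, ] <- vapply(pairs, function(pp) mean(f[pp[, 1]] * f[pp[, 2]]),
                       numeric(1))
  }
  emp <- colMeans(est)
  theo <- matern_cov(test_d, 1, 3, 1)
  expect_lt(max(abs(emp - theo)), 0.08)
})

test_that("surveys carry the contracted geometry and binomial counts", {
  w <- tiny_world()
  ## prevalence == 0 -> every count 0
  tr0 <- simulate_truth(w$grid, w$covariates, gp_hyperparams(spatial_var = 0),
                        beta = c(0, 0, 0), intercept = -30, seed = 1)
  sv0 <- simulate_surveys(tr0, w$grid, survey_design(clusters_per_year = 10),
                          seed = 2)
  expect_true(all(sv0$clusters$C == 0))
  ## polygon fraction 1 -> no observation carries coordinates
  svp <- simulate_surveys(tr0, w$grid,
                          survey_design(clusters_per_year = 10,
                                        polygon_fraction = 1), seed = 2)
  expect_true(all(is.na(svp$clusters$x)))
  expect_true(all(!is.na(svp$clusters$polygon_id)))
  ## large-N empirical proportion near truth (binomial standard error)
  trc <- simulate_truth(w$grid, w$covariates, gp_hyperparams(spatial_var = 0),
                        beta = c(0, 0, 0), intercept = logit(0.3), seed = 1)
  svn <- simulate_surveys(trc, w$grid,
                          survey_design(clusters_per_year = 4, mean_n = 10000,
                                        polygon_fraction = 0, years = 2005),
                          seed = 3)
  expect_true(all(abs(svn$clusters$C / svn$clusters$N - 0.3) < 0.015))
  ## determinism
  sv0b <- simulate_surveys(tr0, w$grid, survey_design(clusters_per_year = 10),
                           seed = 2)
  expect_identical(sv0$clusters, sv0b$clusters)
})

test_that("microdata tally to the cluster counts and carry the seasonal signal", {
  w <- tiny_world()
  tr <- simulate_truth(w$grid, w$covariates, gp_hyperparams(spatial_var = 0),
                       beta = c(0.3, 0, 0), intercept = -1,
                       indicator = "wasting", seed = 5)
  sv <- simulate_surveys(tr, w$grid,
                         survey_design(clusters_per_year = 15, mean_n = 30,
                                       polygon_fraction = 0.3,
                                       seasonal_amplitude = 0.4,
                                       microdata = TRUE), seed = 6)
  ## recomputing z-scores from the measurements reproduces the counts
  lms <- synthetic_lms_table("WHZ")
  obs <- collapse_to_cluster(sv$children, lms, "wasting",
                             cluster_meta = sv$clusters)
  m <- merge(sv$clusters, obs, by = "cluster_id")
  expect_equal(m$C.x, m$C.y)
  expect_equal(m$N.x, m$N.y)
})

test_that("national series equal population-weighted truth when unperturbed", {
  w <- tiny_world()
  tr <- simulate_truth(w$grid, w$covariates, gp_hyperparams(spatial_var = 0.3),
                       seed = 7)
  ns <- simulate_national_series(tr, w$grid, perturbation_sd = 0)
  ## manual aggregate for one country-year
  t10 <- match(2010, w$grid$years)
  sel <- w$grid$country_id == 2 & !w$grid$mask
  manual <- sum(invlogit(tr$logit_prev[sel, t10]) * w$grid$population[sel, t10]) /
    sum(w$grid$population[sel, t10])
  expect_equal(ns$prevalence[ns$country_id == 2 & ns$year == 2010], manual,
               tolerance = 1e-12)
  ## constant truth -> constant series
  trc <- simulate_truth(w$grid, w$covariates, gp_hyperparams(spatial_var = 0),
                        beta = c(0, 0, 0), intercept = logit(0.25), seed = 1)
  nsc <- simulate_national_series(trc, w$grid, 0)
  expect_equal(nsc$prevalence, rep(0.25, nrow(nsc)), tolerance = 1e-9)
  ## CLT: perturbations average out on the logit scale
  devs <- vapply(1:500, function(s) {
    nsp <- simulate_national_series(trc, w$grid, 0.1, seed = s)
    mean(logit(nsp$prevalence) - logit(0.25))
  }, numeric(1))
  expect_lt(abs(mean(devs)), 0.01)
})
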