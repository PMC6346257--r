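test_that("Matern covariance follows the sqrt(8 nu) convention", {
  expect_equal(matern_cov(0, sigma2 = 2.5, range = 4, nu = 1), 2.5)
  ## nu = 1/2 reduces to the exponential kernel exp(-2 d / range)
  d <- c(0.3, 1, 2.7, 6)
  expect_equal(matern_cov(d, 1, range = 3, nu = 0.5), exp(-2 * d / 3),
               tolerance = 1e-12)
  ## at d = range, nu = 1: value frozen from an independent Bessel
  ## evaluation (scipy.special.kv): sqrt(8)*K_1(sqrt(8)) = 0.1396674740
  expect_equal(matern_cov(1, 1, range = 1, nu = 1), 0.1396674740152931,
               tolerance = 1e-9)
  ## monotone nonincreasing in distance
  dd <- seq(0, 10, by = 0.1)
  expect_true(all(diff(matern_cov(dd, 1, 3, 1)) <= 1e-12))
  expect_error(matern_cov(1, 1, range = 0, nu = 1), "range")
  expect_error(matern_cov(-1, 1, 1, 1), "nonnegative")
})

test_that("space-time covariance is the AR1 x Matern Kronecker product", {
  gp <- gp_hyperparams(spatial_range = 2, spatial_var = 1.3, ar1_rho = 0.9)
  coords <- cbind(c(0, 1, 0, 3), c(0, 0, 2, 1))
  years <- 2000:2002
  K <- st_covariance(coords, years, gp)
  expect_equal(dim(K), c(12L, 12L))
  expect_equal(K, t(K))
  expect_true(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) >=
                -1e-8)
  ## same pixel, lag 2 -> rho^2 * sigma2
  expect_equal(K[1, 9], 0.9^2 * 1.3)
  ## eigenvalues of the Kronecker product are all products of the factors'
  ## eigenvalues (brute-force oracle)
  A <- ar1_corr(years, 0.9)
  S <- cgfmap:::matern_cov_matrix(coords, 1.3, 2, 1)
  ev_expected <- sort(as.vector(outer(eigen(A)$values, eigen(S)$values)))
  expect_equal(sort(eigen(K, only.values = TRUE)$values), ev_expected,
               tolerance = 1e-9)
  expect_error(st_covariance(matrix(runif(400), 200), 2000:2100, gp),
               "refusing")
})

test_that("hyperparameter containers validate their domains", {
  expect_error(gp_hyperparams(ar1_rho = 1), "strictly inside")
  expect_error(gp_hyperparams(spatial_range = 0), "positive")
  expect_error(gp_hyperparams(spatial_var = -1), "nonnegative")
  expect_error(ar1_corr(2000:2002, -1), "strictly inside")
})

test_that("the state-space filter reproduces the dense Kronecker likelihood", {
  ## oracle: direct dense multivariate-normal computation over pixel-years
  set.seed(77)
  w <- make_world(world_config(n_rows = 4, n_cols = 4, years = 2000:2002,
                               country_rows = 1, country_cols = 1,
                               admin1_rows = 1, admin1_cols = 1), seed = 3)
  grid <- w$grid
  gp <- gp_hyperparams(spatial_range = 2.5, spatial_var = 0.7, ar1_rho = 0.6,
                       nugget_var = 0)
  n <- 20
  pix <- sample(1:16, n, replace = TRUE)
  tix <- sample(1:3, n, replace = TRUE)
  y <- rnorm(n); noise <- runif(n, 0.05, 0.3)
  obs_by_year <- lapply(1:3, function(t) {
    i <- which(tix == t); list(i = i, pix = pix[i])
  })
  S <- cgfmap:::matern_cov_matrix(grid$coords, gp$spatial_var,
                                  gp$spatial_range, 1)
  kp <- cgfmap:::kalman_pass(y, noise, S, gp$ar1_rho, obs_by_year, 16, 3,
                             want_smooth = TRUE)
  ## dense route: year-major Kronecker covariance at the observed cells
  Kfull <- st_covariance(grid$coords, grid$years, gp)
  cell <- (tix - 1) * 16 + pix
  Cobs <- Kfull[cell, cell] + diag(noise)
  ll_dense <- mvn_loglik(y, Cobs)
  expect_equal(kp$loglik, ll_dense, tolerance = 1e-6)
  ## smoothed field mean equals the GLS conditional mean
  cond <- Kfull[, cell] %*% solve(Cobs, y)
  f_sm <- do.call(cbind, kp$m_smooth)        # P x T
  expect_lt(max(abs(as.vector(f_sm) - as.vector(cond))), 1e-5)
})

test_that("FFBS draws have the conditional mean and covariance", {
  set.seed(99)
  w <- make_world(world_config(n_rows = 4, n_cols = 4, years = 2000:2001,
                               country_rows = 1, country_cols = 1,
                               admin1_rows = 1, admin1_cols = 1), seed = 3)
  grid <- w$grid
  gp <- gp_hyperparams(spatial_range = 2, spatial_var = 0.6, ar1_rho = 0.7)
  pix <- c(1, 5, 9, 14); tix <- c(1, 1, 2, 2)
  y <- c(0.5, -0.4, 0.8, 0.1); noise <- rep(0.1, 4)
  obs_by_year <- lapply(1:2, function(t) {
    i <- which(tix == t); list(i = i, pix = pix[i])
  })
  S <- cgfmap:::matern_cov_matrix(grid$coords, gp$spatial_var,
                                  gp$spatial_range, 1)
  kp <- cgfmap:::kalman_pass(y, noise, S, gp$ar1_rho, obs_by_year, 16, 2,
                             want_smooth = TRUE)
  fd <- cgfmap:::ffbs_draws(kp, gp$ar1_rho, 4000, 16, 2)
  Kfull <- st_covariance(grid$coords, grid$years, gp)
  cell <- (tix - 1) * 16 + pix
  Cobs <- Kfull[cell, cell] + diag(noise)
  cond_mean <- as.vector(Kfull[, cell] %*% solve(Cobs, y))
  cond_cov <- Kfull - Kfull[, cell] %*% solve(Cobs, t(Kfull[, cell]))
  emp_mean <- as.vector(apply(fd, c(2, 3), mean))
  expect_lt(max(abs(emp_mean - cond_mean)), 0.05)
  emp_var <- as.vector(apply(fd, c(2, 3), var))
  expect_lt(max(abs(emp_var - diag(cond_cov))), 0.06)
})
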