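#' Parameter-recovery and calibration study
#'
#' Runs seeded replicates of the full recovery experiment the package's
#' validation rests on: simulate a world and a truth surface from the
#' generative model (covariate mean plus Matern x AR1 field), simulate
#' point-cluster surveys, fit the geostatistical model with a well-specified
#' mean (each feature is the intercept plus one covariate, so the simplex
#' combination of features reproduces the true mean exactly), predict
#' candidate maps, and score hyperparameter recovery, pixel-level 95%
#' interval calibration against the known truth, and the raking factors
#' against a perturbation-free national series.
#'
#' @param n_replicates number of seeded replicates (default 10).
#' @param seed master seed; replicate r uses streams derived from it.
#' @param config a [world_config()] (default: the 20 x 20 pixel, 2000-2016
#'   study world).
#' @param gp true hyperparameters (default range 6 px, sigma2 0.5, rho 0.8).
#' @param beta,intercept truth mean structure.
#' @param design a [survey_design()] (default 150 point clusters/year).
#' @param n_draws posterior draws per replicate (default 200).
#' @param control fit control (default maxit 120, 6 hyper configurations).
#' @return a data.frame with one row per replicate: posterior medians of
#'   rho, range, sigma2 and nugget, pixel coverage of 95% intervals,
#'   RMSE of the posterior mean against truth, and the median raking factor.
#' @export
recovery_study <- function(n_replicates = 10, seed = 1L,
                           config = world_config(),
                           gp = gp_hyperparams(),
                           beta = c(0.5, 0.3, 0.2), intercept = -1,
                           design = survey_design(clusters_per_year = 150,
                                                  polygon_fraction = 0),
                           n_draws = 200,
                           control = list(maxit = 120, n_theta_draws = 6)) {
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rs <- child_seed(seed, paste0("rep", r))
    world <- make_world(config, seed = rs)
    grid <- world$grid; covs <- world$covariates
    truth <- simulate_truth(grid, covs, gp, beta = beta,
                            intercept = intercept, seed = rs + 1L)
    sv <- simulate_surveys(truth, grid, design, seed = rs + 2L)
    obs <- sv$clusters
    feats <- oracle_features(obs, covs, grid, intercept)
    fit <- suppressWarnings(
      fit_geostat(obs, feats$obs, grid, seed = rs + 3L, n_draws = n_draws,
                  control = control))
    cube <- predict_pixel_draws(fit, feats$pixel[, match(fit$years, grid$years),
                                                 , drop = FALSE], grid)
    ty <- match(fit$years, grid$years)
    ptrue <- invlogit(truth$logit_prev[, ty])
    lo <- apply(cube$prevalence, c(2, 3), stats::quantile, probs = 0.025)
    hi <- apply(cube$prevalence, c(2, 3), stats::quantile, probs = 0.975)
    pm <- apply(cube$prevalence, c(2, 3), mean)
    series <- simulate_national_series(truth, grid, perturbation_sd = 0)
    nat <- aggregate_admin(cube, grid, "national")
    rt <- compute_raking_factors(nat, series)
    out[[r]] <- data.frame(
      replicate = r,
      rho_median = stats::median(fit$hyper_draws$ar1_rho),
      range_median = stats::median(fit$hyper_draws$spatial_range),
      sigma2_median = stats::median(fit$hyper_draws$spatial_var),
      nugget_median = stats::median(fit$hyper_draws$nugget_var),
      coverage = mean(ptrue >= lo & ptrue <= hi),
      rmse = sqrt(mean((pm - ptrue)^2)),
      raking_median = stats::median(rt$factors))
  }
  do.call(rbind, out)
}

## well-specified stacked features: feature k = intercept + covariate k at
## the observation pixel-years (and over all pixel-years); any simplex
## combination then has the truth's functional form
oracle_features <- function(obs, covs, grid, intercept) {
  pix <- snap_to_pixel(grid, obs$x, obs$y)
  tix <- match(obs$year, grid$years)
  K <- dim(covs$values)[3]
  Fo <- vapply(seq_len(K), function(k) {
    intercept + covs$values[, , k][cbind(pix, tix)]
  }, numeric(nrow(obs)))
  Fp <- covs$values + intercept
  list(obs = Fo, pixel = Fp)
}

#' Gaussian-approximation vs exact-MCMC latent field comparison
#'
#' Builds a small instance (one observation per pixel-year, fixed
#' hyperparameters, fixed mean, no nugget so the latent equals the field on
#' both routes), fits the latent field with the default Gaussian
#' approximation engine and with the exact random-walk MCMC backend, and
#' returns the posterior mean discrepancy.
#'
#' @param seed integer seed.
#' @param n_pixels,n_years instance size (defaults 10 x 3 = 30 pixel-years).
#' @param N binomial sample size per observation.
#' @param gp fixed hyperparameters (nugget forced to 0).
#' @param n_iter MCMC iterations.
#' @return list with `max_abs_diff`, `eta_laplace`, `eta_mcmc`, `accept_rate`.
#' @export
oracle_comparison <- function(seed = 1L, n_pixels = 10, n_years = 3, N = 150,
                              gp = gp_hyperparams(spatial_range = 3,
                                                  spatial_var = 0.5,
                                                  ar1_rho = 0.7,
                                                  nugget_var = 0),
                              n_iter = 400000) {
  gp$nugget_var <- 0
  cf <- world_config(n_rows = max(4, ceiling(n_pixels / 5)), n_cols = 5,
                     years = 2000:(1999 + n_years), country_rows = 1,
                     country_cols = 1, admin1_rows = 1, admin1_cols = 1)
  world <- make_world(cf, seed = seed)
  grid <- world$grid
  Ptot <- nrow(grid$coords)
  pxs <- with_seed(child_seed(seed, "oracle-pix"),
                   sort(sample.int(Ptot, n_pixels)))
  truth <- simulate_truth(grid, world$covariates, gp, beta = c(0, 0, 0),
                          intercept = -1, seed = seed + 1L)
  obs <- with_seed(child_seed(seed, "oracle-obs"), {
    g <- expand.grid(pix = pxs, year = grid$years)
    p <- invlogit(truth$logit_prev[cbind(g$pix, match(g$year, grid$years))])
    data.frame(cluster_id = seq_len(nrow(g)), indicator = "stunting",
               x = grid$coords[g$pix, 1], y = grid$coords[g$pix, 2],
               polygon_id = NA_integer_, year = g$year, month = 6L,
               N = N, C = stats::rbinom(nrow(g), N, p), weight = 1)
  })
  obs <- as_cluster_obs(obs)
  offset <- rep(-1, nrow(obs))
  fix <- list(spatial_range = gp$spatial_range, spatial_var = gp$spatial_var,
              ar1_rho = gp$ar1_rho, nugget_var = 0,
              offset_obs = offset,
              offset_pixel = matrix(-1, Ptot, length(grid$years)))
  fit <- fit_geostat(obs, NULL, grid, mean_model = "offset", fix = fix,
                     seed = seed, n_draws = 50,
                     control = list(pql_iters = 4))
  mc <- fit_geostat_mcmc(obs, grid, gp, offset, n_iter = n_iter, seed = seed)
  list(max_abs_diff = max(abs(fit$eta_obs_mean - mc$eta_mean)),
       eta_laplace = fit$eta_obs_mean, eta_mcmc = mc$eta_mean,
       accept_rate = mc$accept_rate)
}
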