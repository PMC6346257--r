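#' Spatially stratified fold assignment
#'
#' Builds `n_folds` holdout sets from whole admin units so held-out data are
#' spatially separated from the training data. Units are ordered by a seeded
#' adjacency sweep (each next unit is drawn from those adjacent to the units
#' already placed, keeping folds spatially contiguous where the geography
#' allows) and the ordering is cut into `n_folds` consecutive groups whose
#' unit counts are balanced within one.
#'
#' @param obs `cluster_obs` (points or polygon references).
#' @param grid the `pixel_grid`.
#' @param n_folds number of folds (default 5).
#' @param unit "admin1" (default), "admin2" or "country".
#' @param seed integer seed.
#' @return integer fold id per observation, with the unit-to-fold map in
#'   `attr(, "unit_folds")`.
#' @export
spatial_folds <- function(obs, grid, n_folds = 5, unit = "admin1", seed = 1L) {
  ids <- switch(unit, admin1 = grid$admin1_id, admin2 = grid$admin2_id,
                country = grid$country_id, stop("unknown unit: ", unit))
  ## unit of each observation: snap points; map polygons through admin2
  ou <- integer(nrow(obs))
  pt <- is.finite(obs$x) & is.finite(obs$y)
  ou[pt] <- ids[snap_to_pixel(grid, obs$x[pt], obs$y[pt])]
  if (any(!pt)) {
    a2map <- tapply(ids, grid$admin2_id, function(v) v[1])
    ou[!pt] <- a2map[as.character(obs$polygon_id[!pt])]
  }
  units <- sort(unique(ids))
  if (length(units) < n_folds) stop("fewer ", unit, " units than folds")

  ## rook adjacency between units on the pixel grid
  nbr <- function(i, j) (i - 1L) * grid$n_cols + j
  adj <- matrix(FALSE, length(units), length(units))
  rid <- matrix(match(ids, units), grid$n_rows, grid$n_cols, byrow = TRUE)
  for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
    a <- rid[i, j]
    if (j < grid$n_cols) { b <- rid[i, j + 1]; adj[a, b] <- adj[b, a] <- TRUE }
    if (i < grid$n_rows) { b <- rid[i + 1, j]; adj[a, b] <- adj[b, a] <- TRUE }
  }
  ord <- with_seed(child_seed(seed, "folds"), {
    placed <- sample.int(length(units), 1)
    while (length(placed) < length(units)) {
      cand <- which(apply(adj[placed, , drop = FALSE], 2, any))
      cand <- setdiff(cand, placed)
      if (!length(cand)) cand <- setdiff(seq_along(units), placed)
      placed <- c(placed, cand[sample.int(length(cand), 1)])
    }
    placed
  })
  sizes <- rep(length(units) %/% n_folds, n_folds)
  extra <- length(units) %% n_folds
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  unit_fold <- integer(length(units))
  unit_fold[ord] <- rep(seq_len(n_folds), times = sizes)
  folds <- unit_fold[match(ou, units)]
  attr(folds, "unit_folds") <- data.frame(unit = units, fold = unit_fold)
  folds
}

## weighted Pearson correlation
wpearson <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  sxy <- sum(w * (x - mx) * (y - my))
  sx <- sqrt(sum(w * (x - mx)^2)); sy <- sqrt(sum(w * (y - my)^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sxy / (sx * sy)
}

#' Out-of-sample validation metrics
#'
#' The four reported metrics for held-out cluster observations against their
#' posterior predictive draws: mean error (bias) of the posterior mean
#' against the observed proportion, root-mean-square error, 95% data
#' coverage, and the sample-size-weighted Pearson correlation. Coverage is
#' data-level: the predictive interval for `C/N` mixes binomial sampling
#' noise over the prevalence draws (at aggregated levels a normal
#' approximation to the summed binomial is used), because observed
#' proportions are noisy realizations of the latent prevalence.
#'
#' @param obs held-out `cluster_obs`.
#' @param pred_draws draws x n matrix of prevalence draws at the
#'   observations' pixel-years.
#' @param level "pixel" (per observation), or "admin1"/"national", which
#'   pools observations within unit-years before computing metrics (requires
#'   `unit_id`).
#' @param unit_id unit id per observation (for aggregated levels).
#' @return one-row data.frame: `level`, `n`, `me`, `rmse`, `coverage`
#'   (percent), `correlation`.
#' @export
cv_metrics <- function(obs, pred_draws, level = "pixel", unit_id = NULL) {
  stopifnot(ncol(pred_draws) == nrow(obs))
  if (level == "pixel") {
    pm <- colMeans(pred_draws)
    yhat <- obs$C / obs$N
    resid <- pm - yhat
    covered <- vapply(seq_len(nrow(obs)), function(i) {
      ci <- binom_mix_interval(obs$N[i], pred_draws[, i])
      obs$C[i] >= ci[1] && obs$C[i] <= ci[2]
    }, logical(1))
    data.frame(level = level, n = nrow(obs), me = mean(resid),
               rmse = sqrt(mean(resid^2)), coverage = 100 * mean(covered),
               correlation = wpearson(pm, yhat, obs$N))
  } else {
    if (is.null(unit_id)) stop("aggregated levels need unit_id per observation")
    key <- paste(unit_id, obs$year)
    groups <- split(seq_len(nrow(obs)), key)
    agg <- lapply(groups, function(ii) {
      Nsum <- sum(obs$N[ii])
      mu_d <- as.numeric(pred_draws[, ii, drop = FALSE] %*% obs$N[ii])
      var_d <- as.numeric((pred_draws[, ii, drop = FALSE] *
                             (1 - pred_draws[, ii, drop = FALSE])) %*% obs$N[ii])
      ## normal-mixture predictive interval for the summed count
      qs <- normal_mix_quantiles(mu_d, sqrt(var_d), c(0.025, 0.975))
      Csum <- sum(obs$C[ii])
      c(yhat = Csum / Nsum, pm = mean(mu_d) / Nsum,
        covered = as.numeric(Csum >= qs[1] && Csum <= qs[2]), N = Nsum)
    })
    m <- do.call(rbind, agg)
    resid <- m[, "pm"] - m[, "yhat"]
    data.frame(level = level, n = nrow(m), me = mean(resid),
               rmse = sqrt(mean(resid^2)),
               coverage = 100 * mean(m[, "covered"]),
               correlation = wpearson(m[, "pm"], m[, "yhat"], m[, "N"]))
  }
}

## equal-tailed 95% predictive interval for a count: mixture over prevalence
## draws of Binomial(N, p_d)
binom_mix_interval <- function(N, p_draws, probs = c(0.025, 0.975)) {
  cdf <- rowMeans(vapply(p_draws, function(p) stats::pbinom(0:N, N, p),
                         numeric(N + 1)))
  c(which(cdf >= probs[1])[1] - 1L, which(cdf >= probs[2])[1] - 1L)
}

normal_mix_quantiles <- function(mu, sd, probs) {
  lo <- min(mu - 6 * sd); hi <- max(mu + 6 * sd)
  vapply(probs, function(pr) {
    stats::uniroot(function(x) mean(stats::pnorm(x, mu, sd)) - pr,
                   c(lo, hi))$root
  }, numeric(1))
}

#' Compare the five model formulations out of sample
#'
#' Fits, on identical spatially stratified folds, the five formulations:
#' stacked ensemble covariates with and without the space-time Gaussian
#' process, raw covariates (weighted binomial GLM mean) with and without the
#' space-time process, and the space-time process alone with no covariates;
#' then scores each on the held-out observations with [cv_metrics()].
#'
#' @param obs point `cluster_obs`.
#' @param covariates the `covariate_stack`.
#' @param grid the `pixel_grid`.
#' @param seed integer seed (folds and fits).
#' @param n_folds folds (default 5).
#' @param n_draws posterior draws per fit (default 100; this is a ranking
#'   exercise, not a mapping run).
#' @param control passed to [fit_geostat()] (defaults tuned lighter here:
#'   maxit 150, 5 hyperparameter configurations).
#' @param stack_control passed to [fit_child_learners()].
#' @return data.frame: one row of out-of-sample metrics per formulation.
#' @export
compare_formulations <- function(obs, covariates, grid, seed = 1L,
                                 n_folds = 5, n_draws = 100,
                                 control = list(), stack_control = list()) {
  ctl <- utils::modifyList(list(maxit = 150, n_theta_draws = 5, pql_iters = 2),
                           control)
  folds <- spatial_folds(obs, grid, n_folds = n_folds, seed = seed)
  pix <- snap_to_pixel(grid, obs$x, obs$y)
  tixg <- match(obs$year, grid$years)
  K <- dim(covariates$values)[3]
  Xobs <- vapply(seq_len(K), function(k) covariates$values[, , k][cbind(pix, tixg)],
                 numeric(nrow(obs)))
  colnames(Xobs) <- covariates$names
  years <- grid$years[grid$years >= min(obs$year) & grid$years <= max(obs$year)]

  forms <- c("stacked + space-time GP", "stacked, no space-time GP",
             "raw covariates + space-time GP", "raw covariates, no space-time GP",
             "space-time GP only")
  preds <- lapply(forms, function(f) matrix(NA_real_, n_draws, nrow(obs)))
  names(preds) <- forms

  for (f in seq_len(n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (!length(te)) next
    otr <- obs[tr, , drop = FALSE]
    sf <- fit_child_learners(otr, covariates, grid, n_folds = 5,
                             seed = child_seed(seed, paste0("stack", f)),
                             by_region = FALSE, control = stack_control)
    glm_fml <- stats::as.formula(paste("cbind(C, N - C) ~",
                                       paste(covariates$names, collapse = " + ")))
    glm_fit <- quiet_binomial(stats::glm(glm_fml, family = stats::binomial(),
                          data = data.frame(C = otr$C, N = otr$N,
                                            Xobs[tr, , drop = FALSE],
                                            check.names = FALSE),
                          weights = otr$weight))
    off_tr <- as.numeric(stats::predict(glm_fit, type = "link"))
    Xpixdf <- as.data.frame(matrix(NA_real_, nrow(grid$coords) * length(years), K))
    names(Xpixdf) <- covariates$names
    ty <- match(years, grid$years)
    for (k in seq_len(K)) Xpixdf[[k]] <- as.vector(covariates$values[, ty, k])
    off_pix <- matrix(as.numeric(stats::predict(glm_fit, newdata = Xpixdf,
                                                type = "link")),
                      nrow(grid$coords), length(years))
    fits <- suppressWarnings(list(
      fit_geostat(otr, sf, grid, seed = child_seed(seed, paste0("m1_", f)),
                  n_draws = n_draws, years = years, control = ctl),
      fit_geostat(otr, sf, grid, seed = child_seed(seed, paste0("m2_", f)),
                  n_draws = n_draws, years = years,
                  control = utils::modifyList(ctl, list(include_gp = FALSE))),
      fit_geostat(otr, NULL, grid, seed = child_seed(seed, paste0("m3_", f)),
                  n_draws = n_draws, years = years, mean_model = "offset",
                  fix = list(offset_obs = off_tr, offset_pixel = off_pix),
                  control = ctl),
      fit_geostat(otr, NULL, grid, seed = child_seed(seed, paste0("m4_", f)),
                  n_draws = n_draws, years = years, mean_model = "offset",
                  fix = list(offset_obs = off_tr, offset_pixel = off_pix),
                  control = utils::modifyList(ctl, list(include_gp = FALSE))),
      fit_geostat(otr, NULL, grid, seed = child_seed(seed, paste0("m5_", f)),
                  n_draws = n_draws, years = years, mean_model = "intercept",
                  control = ctl)))
    tix <- match(obs$year[te], years)
    for (m in seq_along(fits)) {
      cube <- predict_pixel_draws(fits[[m]],
        if (m <= 2) sf$pixel_features[, ty, , drop = FALSE] else NULL,
        grid)
      preds[[m]][, te] <- cube$prevalence[, , , drop = FALSE][
        cbind(rep(seq_len(n_draws), length(te)),
              rep(pix[te], each = n_draws),
              rep(tix, each = n_draws))]
    }
  }
  out <- do.call(rbind, lapply(seq_along(forms), function(m) {
    r <- cv_metrics(obs, preds[[m]])
    r$formulation <- forms[m]
    r
  }))
  out[, c("formulation", "level", "n", "me", "rmse", "coverage", "correlation")]
}
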