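#' Priors for the geostatistical model
#'
#' Weakly informative defaults on transformed hyperparameters: Gaussian
#' priors on log range, log sigma and log tau (each log-normal(0, 1.5^2) on
#' the natural scale) and a standard Gaussian on logit((rho + 1) / 2). The
#' simplex weights on the stacked features carry a flat (symmetric
#' Dirichlet(1)) prior.
#'
#' @param range_meanlog,range_sdlog prior on log spatial range (pixel units).
#' @param sigma_meanlog,sigma_sdlog prior on log field standard deviation.
#' @param tau_meanlog,tau_sdlog prior on log nugget standard deviation.
#' @param rho_mean,rho_sd prior on logit((rho + 1) / 2).
#' @return a `geostat_priors` list.
#' @export
geostat_priors <- function(range_meanlog = 0, range_sdlog = 1.5,
                           sigma_meanlog = 0, sigma_sdlog = 1.5,
                           tau_meanlog = 0, tau_sdlog = 1.5,
                           rho_mean = 0, rho_sd = 1) {
  structure(list(range_meanlog = range_meanlog, range_sdlog = range_sdlog,
                 sigma_meanlog = sigma_meanlog, sigma_sdlog = sigma_sdlog,
                 tau_meanlog = tau_meanlog, tau_sdlog = tau_sdlog,
                 rho_mean = rho_mean, rho_sd = rho_sd),
            class = "geostat_priors")
}

softmax <- function(a) {
  e <- exp(a - max(a))
  e / sum(e)
}

## ---- state-space representation -------------------------------------------
## The Kronecker Matern (space) x AR1 (years) field is exactly a
## linear-Gaussian state-space model: state f_t over P pixels with
## f_1 ~ N(0, S), f_t = rho f_{t-1} + e_t, e_t ~ N(0, (1 - rho^2) S),
## S the Matern covariance. The Kalman filter gives the Gaussian working
## marginal likelihood; the RTS smoother the posterior field; FFBS joint
## conditional draws. Observations are working Gaussians y_i with variance
## noise_i at pixel pix_i, year tix_i.

kalman_pass <- function(resid, noise, Smat, rho, obs_by_year, P, Tn,
                        want_smooth = FALSE) {
  diag(Smat) <- diag(Smat) + 1e-10 + 1e-8 * mean(diag(Smat))
  innov_var <- (1 - rho^2) * Smat
  m_pred <- vector("list", Tn); P_pred <- vector("list", Tn)
  m_filt <- vector("list", Tn); P_filt <- vector("list", Tn)
  ll <- 0
  for (t in seq_len(Tn)) {
    if (t == 1) {
      mp <- numeric(P); Pp <- Smat
    } else {
      mp <- rho * m_filt[[t - 1]]
      Pp <- rho^2 * P_filt[[t - 1]] + innov_var
    }
    ob <- obs_by_year[[t]]
    if (length(ob$i)) {
      idx <- ob$pix
      S <- Pp[idx, idx, drop = FALSE]
      diag(S) <- diag(S) + noise[ob$i]
      cS <- chol(S)                         # S = t(cS) %*% cS
      r <- resid[ob$i] - mp[idx]
      a <- backsolve(cS, r, transpose = TRUE)
      ll <- ll - sum(log(diag(cS))) - 0.5 * sum(a^2) -
        0.5 * length(r) * log(2 * pi)
      ## Kalman update in square-root form: A1 = P A' R^-1, so the gain
      ## times r is A1 a and the covariance downdate is A1 A1'
      A1 <- t(backsolve(cS, t(Pp[, idx, drop = FALSE]), transpose = TRUE))
      mf <- mp + as.numeric(A1 %*% a)
      Pf <- Pp - tcrossprod(A1)
    } else {
      mf <- mp; Pf <- Pp
    }
    m_pred[[t]] <- mp; P_pred[[t]] <- Pp
    m_filt[[t]] <- mf; P_filt[[t]] <- Pf
  }
  out <- list(loglik = ll)
  if (want_smooth) {
    m_s <- vector("list", Tn)
    J <- vector("list", Tn)
    m_s[[Tn]] <- m_filt[[Tn]]
    if (Tn > 1) {
      for (t in (Tn - 1):1) {
        cP <- safe_chol(P_pred[[t + 1]])
        ## J = rho * P_filt %*% solve(P_pred[t+1]); both symmetric
        J[[t]] <- rho * t(backsolve(cP, backsolve(cP, P_filt[[t]],
                                                  transpose = TRUE)))
        m_s[[t]] <- m_filt[[t]] +
          as.numeric(J[[t]] %*% (m_s[[t + 1]] - m_pred[[t + 1]]))
      }
    }
    out$m_smooth <- m_s; out$J <- J
    out$m_filt <- m_filt; out$P_filt <- P_filt
    out$m_pred <- m_pred; out$P_pred <- P_pred
  }
  out
}

## joint draws of the field via forward-filter backward-sampling;
## returns array (n_draw, P, Tn). `kp` must come from kalman_pass(want_smooth=TRUE).
ffbs_draws <- function(kp, rho, n_draw, P, Tn) {
  cholT <- safe_chol(kp$P_filt[[Tn]])
  Jc <- vector("list", Tn); Cc <- vector("list", Tn)
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      Jt <- kp$J[[t]]
      Ct <- kp$P_filt[[t]] - rho * Jt %*% kp$P_filt[[t]]
      Jc[[t]] <- Jt
      Cc[[t]] <- safe_chol(Ct)
    }
  }
  out <- array(0, dim = c(n_draw, P, Tn))
  for (d in seq_len(n_draw)) {
    f <- matrix(0, P, Tn)
    f[, Tn] <- kp$m_filt[[Tn]] + as.numeric(t(cholT) %*% stats::rnorm(P))
    if (Tn > 1) {
      for (t in (Tn - 1):1) {
        mu <- kp$m_filt[[t]] +
          as.numeric(Jc[[t]] %*% (f[, t + 1] - kp$m_pred[[t + 1]]))
        f[, t] <- mu + as.numeric(t(Cc[[t]]) %*% stats::rnorm(P))
      }
    }
    out[d, , ] <- f
  }
  out
}

## Cholesky with an escalating ridge; falls back to an eigenvalue clip for
## matrices that are numerically indefinite (near-singular conditional
## covariances of strongly correlated fields)
safe_chol <- function(M) {
  M <- (M + t(M)) / 2
  base <- max(diag(M), 0) + 1e-12
  for (j in base * c(1e-10, 1e-8, 1e-6, 1e-4)) {
    out <- tryCatch(chol(M + diag(j, nrow(M))), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  eg <- eigen(M, symmetric = TRUE)
  vals <- pmax(eg$values, base * 1e-8)
  chol(eg$vectors %*% (vals * t(eg$vectors)) + diag(base * 1e-10, nrow(M)))
}

## ---- parameter packing -----------------------------------------------------

gp_par_names <- c("log_range", "log_sigma2", "log_tau2", "z_rho")

build_parspec <- function(mean_model, L, fix, include_gp) {
  free <- character(0)
  if (include_gp) {
    if (is.null(fix$spatial_range)) free <- c(free, "log_range")
    if (is.null(fix$spatial_var)) free <- c(free, "log_sigma2")
    if (is.null(fix$ar1_rho)) free <- c(free, "z_rho")
  }
  if (is.null(fix$nugget_var)) free <- c(free, "log_tau2")
  if (mean_model == "simplex" && is.null(fix$beta)) {
    free <- c(free, paste0("a", 2:L))
  } else if (mean_model == "intercept" && is.null(fix$alpha)) {
    free <- c(free, "alpha")
  }
  free
}

par_to_model <- function(par, free, fix, mean_model, L, nu, include_gp) {
  g <- function(nm, default) {
    if (nm %in% free) par[[match(nm, free)]] else default
  }
  ## clamp the log scale so optimizer excursions cannot underflow to zero
  ex <- function(x) exp(pmin(pmax(x, -25), 25))
  range <- fix$spatial_range %||% ex(g("log_range", 0))
  sigma2 <- fix$spatial_var %||% ex(g("log_sigma2", 0))
  tau2 <- fix$nugget_var %||% ex(g("log_tau2", 0))
  rho <- fix$ar1_rho %||% (2 * invlogit(g("z_rho", 0)) - 1)
  if (!include_gp) { sigma2 <- 0; rho <- 0; range <- 1 }
  beta <- NULL; alpha <- NULL
  if (mean_model == "simplex") {
    beta <- fix$beta
    if (is.null(beta)) beta <- softmax(c(0, par[match(paste0("a", 2:L), free)]))
  } else if (mean_model == "intercept") {
    alpha <- fix$alpha %||% g("alpha", 0)
  }
  list(gp = list(spatial_range = range, spatial_var = sigma2,
                 matern_smoothness = nu, ar1_rho = rho, nugget_var = tau2),
       beta = beta, alpha = alpha)
}

log_prior <- function(par, free, mod, priors, mean_model) {
  lp <- 0
  if ("log_range" %in% free) {
    lp <- lp + stats::dnorm(par[match("log_range", free)],
                            priors$range_meanlog, priors$range_sdlog, log = TRUE)
  }
  if ("log_sigma2" %in% free) {
    lp <- lp + stats::dnorm(par[match("log_sigma2", free)] / 2,
                            priors$sigma_meanlog, priors$sigma_sdlog, log = TRUE)
  }
  if ("log_tau2" %in% free) {
    lp <- lp + stats::dnorm(par[match("log_tau2", free)] / 2,
                            priors$tau_meanlog, priors$tau_sdlog, log = TRUE)
  }
  if ("z_rho" %in% free) {
    lp <- lp + stats::dnorm(par[match("z_rho", free)], priors$rho_mean,
                            priors$rho_sd, log = TRUE)
  }
  if (mean_model == "simplex" && !is.null(mod$beta) &&
      any(grepl("^a[0-9]+$", free))) {
    ## flat Dirichlet(1) on the simplex + softmax Jacobian
    lp <- lp + sum(log(pmax(mod$beta, 1e-300)))
  }
  if (mean_model == "intercept" && "alpha" %in% free) {
    lp <- lp + stats::dnorm(par[match("alpha", free)], 0, 10, log = TRUE)
  }
  lp
}

## ---- main fit --------------------------------------------------------------

#' Fit the binomial space-time geostatistical model
#'
#' The core hierarchical model: cluster counts `C_i ~ Binomial(N_i, p_i)`
#' with `logit(p_i) = X_i' beta + Z(s_i, t_i) + eps_i`, where `X_i` are
#' logit-scale stacked-learner features, `beta` is constrained to the
#' simplex (nonnegative, summing to 1), `Z` is a zero-mean Gaussian process
#' with Kronecker Matern-in-space x AR1-in-time covariance, and `eps` is an
#' independent nugget. Pseudo-observations contribute their weight times the
#' binomial log-likelihood.
#'
#' Inference is empirical-Bayes: the Kronecker field is represented exactly
#' as a state-space model over years, hyperparameters (and the simplex
#' weights) are optimized by MAP against a penalized quasi-likelihood (PQL)
#' working-Gaussian marginal evaluated with the Kalman filter (the working
#' response and variances are recomputed at the smoothed fit, iterating the
#' Laplace/Gauss-Newton step), hyperparameter uncertainty comes from a
#' Gaussian approximation at the mode (numerical Hessian), and candidate
#' field draws come from forward-filter backward-sampling conditional on
#' hyperparameters sampled from that approximation. An exact MCMC backend
#' for small instances is available as [fit_geostat_mcmc()].
#'
#' @param obs a `cluster_obs` data.frame of point observations (resample
#'   polygons first with [resample_polygon_obs()]); needs >= 10 rows.
#' @param features out-of-sample stacked features: a `stacked_features`
#'   object or an n x L matrix of logit-scale predictions.
#' @param grid a `pixel_grid`; observations snap to its pixel centers.
#' @param priors a [geostat_priors()].
#' @param seed integer seed for the posterior draws.
#' @param n_draws number of posterior draws (candidate maps downstream);
#'   250 by default; use 1000 for full analyses.
#' @param years years to model (default: grid years from the first to the
#'   last observed year).
#' @param mean_model "simplex" (stacked weights summing to 1), "intercept"
#'   (single free intercept, features ignored), or "offset" (fixed
#'   logit-scale offset supplied via `fix$offset_obs`).
#' @param fix named list pinning parameters instead of estimating them:
#'   any of `spatial_range`, `spatial_var`, `ar1_rho`, `nugget_var`,
#'   `beta`, `alpha`, `offset_obs`.
#' @param control list: `maxit` (Nelder-Mead iterations, 300), `reltol`
#'   (1e-7), `pql_iters` (2), `n_theta_draws` (15 hyperparameter values
#'   shared across field draws), `include_gp` (TRUE; FALSE drops the
#'   space-time error term entirely).
#' @return a `model_posterior` with the MAP parameters, draw matrices
#'   (`beta_draws`, `hyper_draws`), the smoothed field mean and joint field
#'   draws over all grid pixels and modelled years.
#' @export
fit_geostat <- function(obs, features, grid, priors = geostat_priors(),
                        seed = 1L, n_draws = 250, years = NULL,
                        mean_model = c("simplex", "intercept", "offset"),
                        fix = list(), control = list()) {
  mean_model <- match.arg(mean_model)
  stopifnot(inherits(grid, "pixel_grid"))
  if (nrow(obs) < 10) stop("refusing to fit with fewer than 10 observations")
  if (any(!is.na(obs$polygon_id))) {
    stop("polygon observations present; resample them to pseudo-points first")
  }
  ctl <- utils::modifyList(list(maxit = 300, reltol = 1e-7, pql_iters = 2,
                                n_theta_draws = 15, include_gp = TRUE),
                           control)
  include_gp <- isTRUE(ctl$include_gp)

  Fobs <- NULL; L <- 0L
  if (mean_model == "simplex") {
    Fobs <- if (inherits(features, "stacked_features")) features$obs_features
            else as.matrix(features)
    if (nrow(Fobs) != nrow(obs)) stop("features must have one row per observation")
    if (any(!is.finite(Fobs))) stop("features must be finite")
    L <- ncol(Fobs)
    if (L < 2) stop("simplex mean needs at least two feature columns")
  } else if (mean_model == "offset") {
    if (is.null(fix$offset_obs)) stop("mean_model 'offset' needs fix$offset_obs")
    if (length(fix$offset_obs) != nrow(obs)) stop("offset_obs length mismatch")
  }

  years <- years %||% {
    yy <- grid$years[grid$years >= min(obs$year) & grid$years <= max(obs$year)]
    if (!length(yy)) stop("no grid years overlap the observations")
    yy
  }
  tix <- match(obs$year, years)
  if (anyNA(tix)) stop("observations outside the modelled years")
  pix <- snap_to_pixel(grid, obs$x, obs$y)
  P <- nrow(grid$coords); Tn <- length(years)
  obs_by_year <- lapply(seq_len(Tn), function(t) {
    i <- which(tix == t); list(i = i, pix = pix[i])
  })
  D <- as.matrix(stats::dist(grid$coords))
  nu <- fix$matern_smoothness %||% 1
  ## grid distances take few unique values; evaluate the Bessel form once
  ## per unique distance and scatter back
  Du <- sort(unique(round(as.vector(D), 9)))
  Dix <- match(round(D, 9), Du)
  matern_grid <- function(sigma2, range) {
    matrix(matern_cov(Du, sigma2, range, nu)[Dix], nrow(D), nrow(D))
  }

  offset_of <- function(mod) {
    switch(mean_model,
           simplex = as.numeric(Fobs %*% mod$beta),
           intercept = rep(mod$alpha, nrow(obs)),
           offset = fix$offset_obs)
  }

  ## working data (empirical logit start)
  phat <- (obs$C + 0.5) / (obs$N + 1)
  wk <- list(y = logit(phat), vbin = 1 / (obs$N * phat * (1 - phat)))
  w <- obs$weight

  free <- build_parspec(mean_model, L, fix, include_gp)
  objective <- function(par) {
    mod <- par_to_model(par, free, fix, mean_model, L, nu, include_gp)
    off <- offset_of(mod)
    noise <- (wk$vbin + mod$gp$nugget_var) / w
    resid <- wk$y - off
    ll <- if (include_gp && mod$gp$spatial_var > 1e-12) {
      S <- matern_grid(mod$gp$spatial_var, mod$gp$spatial_range)
      kalman_pass(resid, noise, S, mod$gp$ar1_rho, obs_by_year, P, Tn)$loglik
    } else {
      sum(stats::dnorm(resid, 0, sqrt(noise), log = TRUE))
    }
    -(ll + log_prior(par, free, mod, priors, mean_model))
  }

  init <- numeric(length(free)); names(init) <- free
  if ("log_range" %in% free) init["log_range"] <- log(max(2, max(D) / 4))
  if ("log_sigma2" %in% free) init["log_sigma2"] <- log(0.25)
  if ("log_tau2" %in% free) init["log_tau2"] <- log(0.05)
  if ("z_rho" %in% free) init["z_rho"] <- 1
  if ("alpha" %in% free) init["alpha"] <- mean(wk$y)

  smooth_at <- function(mod, off) {
    noise <- (wk$vbin + mod$gp$nugget_var) / w
    if (include_gp && mod$gp$spatial_var > 1e-12) {
      S <- matern_grid(mod$gp$spatial_var, mod$gp$spatial_range)
      kp <- kalman_pass(wk$y - off, noise, S, mod$gp$ar1_rho, obs_by_year,
                        P, Tn, want_smooth = TRUE)
    } else {
      kp <- list(m_smooth = rep(list(numeric(P)), Tn),
                 P_smooth = rep(list(matrix(0, P, P)), Tn))
    }
    kp
  }
  f_at_obs <- function(kp) {
    vapply(seq_len(nrow(obs)), function(i) kp$m_smooth[[tix[i]]][pix[i]],
           numeric(1))
  }

  theta <- init; opt_val <- NA_real_; conv <- 0L
  for (it in seq_len(max(1, ctl$pql_iters))) {
    if (length(free)) {
      op <- if (length(free) == 1) {
        stats::optim(theta, objective, method = "Brent",
                     lower = theta - 12, upper = theta + 12)
      } else {
        stats::optim(theta, objective, method = "Nelder-Mead",
                     control = list(maxit = if (it == 1) ctl$maxit
                                    else ceiling(ctl$maxit / 2),
                                    reltol = ctl$reltol))
      }
      theta <- op$par; opt_val <- op$value; conv <- op$convergence
      if (!is.finite(op$value)) {
        stop("geostat engine failed to converge: non-finite objective at mode; ",
             "parameters: ", paste(sprintf("%s=%.3g", free, theta), collapse = ", "))
      }
    }
    ## PQL refresh of the working data at the current mode
    mod <- par_to_model(theta, free, fix, mean_model, L, nu, include_gp)
    off <- offset_of(mod)
    kp <- smooth_at(mod, off)
    eta <- off + f_at_obs(kp)
    p <- pmin(pmax(invlogit(eta), 1e-4), 1 - 1e-4)
    wk$y <- eta + (obs$C / obs$N - p) / (p * (1 - p))
    wk$vbin <- 1 / (obs$N * p * (1 - p))
  }
  if (length(free) && conv != 0) {
    warning("optimizer stopped at the iteration cap; treat hyperparameters with care")
  }

  ## Gaussian approximation at the mode
  vcov <- matrix(0, length(free), length(free))
  if (length(free)) {
    H <- num_hessian(objective, theta, h = 0.01)
    vcov <- psd_inverse(H)
  }

  mod <- par_to_model(theta, free, fix, mean_model, L, nu, include_gp)
  off <- offset_of(mod)
  kp <- smooth_at(mod, off)
  eta_obs_mean <- off + f_at_obs(kp)
  field_mean <- do.call(cbind, kp$m_smooth)

  ## draws: sample hyperparameter configurations, allocate field draws
  n_theta <- max(1L, min(ctl$n_theta_draws, n_draws))
  theta_draws <- with_seed(child_seed(seed, "theta"), {
    if (length(free) && n_theta > 1) {
      ch <- chol(vcov + diag(1e-12, length(free)))
      sweep(matrix(stats::rnorm((n_theta - 1) * length(free)),
                   n_theta - 1) %*% ch, 2, theta, "+")
    } else NULL
  })
  configs <- vector("list", n_theta)
  configs[[1]] <- theta
  if (n_theta > 1) for (k in 2:n_theta) configs[[k]] <- theta_draws[k - 1, ]
  alloc <- rep(seq_len(n_theta), length.out = n_draws)

  field_draws <- array(0, dim = c(n_draws, P, Tn))
  beta_draws <- if (mean_model == "simplex") matrix(0, n_draws, L) else NULL
  alpha_draws <- if (mean_model == "intercept") numeric(n_draws) else NULL
  hyper_draws <- data.frame(spatial_range = numeric(n_draws),
                            spatial_var = numeric(n_draws),
                            ar1_rho = numeric(n_draws),
                            nugget_var = numeric(n_draws))
  with_seed(child_seed(seed, "field"), {
    for (k in seq_len(n_theta)) {
      dk <- which(alloc == k)
      if (!length(dk)) next
      mk <- par_to_model(configs[[k]], free, fix, mean_model, L, nu, include_gp)
      hyper_draws$spatial_range[dk] <- mk$gp$spatial_range
      hyper_draws$spatial_var[dk] <- mk$gp$spatial_var
      hyper_draws$ar1_rho[dk] <- mk$gp$ar1_rho
      hyper_draws$nugget_var[dk] <- mk$gp$nugget_var
      if (!is.null(beta_draws)) beta_draws[dk, ] <- rep(mk$beta, each = length(dk))
      if (!is.null(alpha_draws)) alpha_draws[dk] <- mk$alpha
      if (include_gp && mk$gp$spatial_var > 1e-12) {
        kpk <- smooth_at(mk, offset_of(mk))
        field_draws[dk, , ] <- ffbs_draws(kpk, mk$gp$ar1_rho, length(dk), P, Tn)
      }
    }
  })

  structure(list(
    mean_model = mean_model, include_gp = include_gp,
    par_names = free, theta_mode = theta, vcov = vcov,
    gp_mode = do.call(gp_hyperparams, mod$gp),
    beta_mode = mod$beta, alpha_mode = mod$alpha,
    beta_draws = beta_draws, alpha_draws = alpha_draws,
    hyper_draws = hyper_draws, field_draws = field_draws,
    field_mean = field_mean, eta_obs_mean = eta_obs_mean,
    working = wk, obs_pix = pix, obs_tix = tix,
    n_draws = n_draws, years = years, n_pixels = P,
    fix = fix, objective_value = opt_val, convergence = conv,
    indicator = if (nrow(obs)) obs$indicator[1] else NA_character_,
    seed = seed
  ), class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  g <- x$gp_mode
  cat(sprintf("<model_posterior> %s mean, %d draws over %d pixels x %d years\n",
              x$mean_model, x$n_draws, x$n_pixels, length(x$years)))
  cat(sprintf("  MAP: range=%.2f sigma2=%.3f rho=%.3f tau2=%.3f\n",
              g$spatial_range, g$spatial_var, g$ar1_rho, g$nugget_var))
  if (!is.null(x$beta_mode)) {
    cat("  beta:", paste(sprintf("%.3f", x$beta_mode), collapse = " "), "\n")
  }
  invisible(x)
}

num_hessian <- function(f, x, h = 0.01) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  hs <- h * pmax(1, abs(x))
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- hs[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hs[i]^2
    if (i < k) for (j in (i + 1):k) {
      ej <- numeric(k); ej[j] <- hs[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hs[i] * hs[j])
    }
  }
  H
}

psd_inverse <- function(H) {
  eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
  floor_v <- max(eg$values, 1e-6) * 1e-8 + 1e-10
  vals <- pmax(eg$values, floor_v)
  eg$vectors %*% diag(1 / vals, length(vals)) %*% t(eg$vectors)
}

#' Assemble posterior prevalence draws on the pixel grid
#'
#' Combines each draw's mean structure (stacked features weighted by that
#' draw's simplex beta) with its joint conditional field draw and inverts
#' the logit (clipped at +-12) to prevalence. The nugget is observation-level
#' noise and is excluded from the surface by default.
#'
#' @param posterior a `model_posterior` from [fit_geostat()].
#' @param pixel_features a `stacked_features` object or a P x T x L array of
#'   logit-scale in-sample learner predictions over the modelled years.
#' @param grid the `pixel_grid` used in fitting.
#' @param seed only used when `include_nugget = TRUE`.
#' @param include_nugget add independent nugget noise to every draw cell
#'   (off by default; the nugget represents observation-level noise).
#' @return a `posterior_cube`: prevalence array (draws x pixels x years).
#' @export
predict_pixel_draws <- function(posterior, pixel_features, grid, seed = 1L,
                                include_nugget = FALSE) {
  stopifnot(inherits(posterior, "model_posterior"))
  P <- posterior$n_pixels; Tn <- length(posterior$years)
  if (P != nrow(grid$coords)) stop("posterior and grid disagree on pixel count")
  Fx <- NULL
  if (posterior$mean_model == "simplex") {
    Fx <- if (inherits(pixel_features, "stacked_features")) {
      sf_years <- pixel_features$years
      ti <- match(posterior$years, sf_years)
      if (anyNA(ti)) stop("pixel features missing modelled years")
      pixel_features$pixel_features[, ti, , drop = FALSE]
    } else pixel_features
    if (!all(dim(Fx)[1:2] == c(P, Tn))) stop("pixel feature dimensions mismatch")
    if (any(!is.finite(Fx))) stop("pixel features must be finite")
  }
  nd <- posterior$n_draws
  prev <- array(0, dim = c(nd, P, Tn))
  for (d in seq_len(nd)) {
    off <- switch(posterior$mean_model,
      simplex = {
        b <- posterior$beta_draws[d, ]
        m <- matrix(0, P, Tn)
        for (l in seq_along(b)) m <- m + b[l] * Fx[, , l]
        m
      },
      intercept = matrix(posterior$alpha_draws[d], P, Tn),
      offset = {
        if (is.null(posterior$fix$offset_pixel)) {
          stop("offset mean model needs fix$offset_pixel for prediction")
        }
        posterior$fix$offset_pixel
      })
    prev[d, , ] <- off + posterior$field_draws[d, , ]
  }
  if (include_nugget) {
    prev <- prev + with_seed(child_seed(seed, "nugget"), {
      array(stats::rnorm(length(prev), 0,
                         sqrt(rep(posterior$hyper_draws$nugget_var,
                                  P * Tn))), dim = dim(prev))
    })
  }
  prev <- invlogit(clip_logit(prev))
  structure(list(prevalence = prev, indicator = posterior$indicator,
                 raked = FALSE, years = posterior$years,
                 n_draws = nd, clip_count = 0L),
            class = "posterior_cube")
}

#' @export
print.posterior_cube <- function(x, ...) {
  cat(sprintf("<posterior_cube> %s%s: %d draws x %d pixels x %d years (%d-%d)\n",
              x$indicator %||% "?", if (x$raked) " (raked)" else "",
              dim(x$prevalence)[1], dim(x$prevalence)[2],
              dim(x$prevalence)[3], min(x$years), max(x$years)))
  invisible(x)
}

#' Exact MCMC over the latent field (small instances)
#'
#' Random-walk Metropolis over the latent logit prevalences at the observed
#' pixel-years, with all hyperparameters and the mean structure held fixed.
#' The proposal is shaped by the prior Cholesky factor and its scale adapts
#' toward a 23% acceptance rate during burn-in; after burn-in the chain
#' targets the exact posterior. Intended as an exact reference backend on
#' instances of at most a few dozen pixel-years (the dense prior covariance
#' is built explicitly); the default engine is the Gaussian approximation in
#' [fit_geostat()].
#'
#' @param obs point `cluster_obs` with one observation per pixel-year.
#' @param grid the `pixel_grid`.
#' @param gp fixed [gp_hyperparams()] (the nugget adds to the latent
#'   covariance diagonal, valid because pixel-years are not replicated).
#' @param offset fixed logit-scale mean per observation (e.g. features times
#'   a fixed beta).
#' @param n_iter,burn_in,thin chain length controls.
#' @param seed integer seed.
#' @return list with `eta_draws` (kept draws x obs), `eta_mean`,
#'   `accept_rate`.
#' @export
fit_geostat_mcmc <- function(obs, grid, gp, offset, n_iter = 200000,
                             burn_in = floor(n_iter / 4), thin = 20,
                             seed = 1L) {
  stopifnot(inherits(grid, "pixel_grid"), inherits(gp, "gp_hyperparams"))
  if (any(!is.na(obs$polygon_id))) stop("resample polygon observations first")
  pix <- snap_to_pixel(grid, obs$x, obs$y)
  key <- paste(pix, obs$year)
  if (anyDuplicated(key)) {
    stop("the MCMC backend requires at most one observation per pixel-year")
  }
  n <- nrow(obs)
  if (n > 200) stop("MCMC backend is for small instances (<= 200 pixel-years)")
  coords <- grid$coords[pix, , drop = FALSE]
  Sig <- matern_cov_matrix(coords, gp$spatial_var, gp$spatial_range,
                           gp$matern_smoothness) *
    outer(obs$year, obs$year, function(a, b) gp$ar1_rho^abs(a - b))
  diag(Sig) <- diag(Sig) + gp$nugget_var + 1e-10
  cS <- chol(Sig)
  Q <- chol2inv(cS)
  mu <- offset
  C <- obs$C; N <- obs$N; w <- obs$weight

  logpost <- function(eta) {
    d <- eta - mu
    -0.5 * sum(d * (Q %*% d)) + sum(w * (C * eta - N * log1p(exp(eta))))
  }
  with_seed(child_seed(seed, "mcmc"), {
    eta <- mu
    lp <- logpost(eta)
    s <- 0.3 / sqrt(n)
    keep <- matrix(0, 0, n)
    acc <- 0L; tries <- 0L
    kept <- list(); ki <- 0L
    Lp <- t(cS)
    for (it in seq_len(n_iter)) {
      prop <- eta + s * as.numeric(Lp %*% stats::rnorm(n))
      lpp <- logpost(prop)
      tries <- tries + 1L
      if (log(stats::runif(1)) < lpp - lp) {
        eta <- prop; lp <- lpp; acc <- acc + 1L
      }
      if (it <= burn_in && it %% 100 == 0) {
        rate <- acc / tries
        s <- s * exp(0.6 * (rate - 0.234))
        acc <- 0L; tries <- 0L
      }
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        ki <- ki + 1L
        kept[[ki]] <- eta
      }
    }
    eta_draws <- do.call(rbind, kept)
    list(eta_draws = eta_draws, eta_mean = colMeans(eta_draws),
         accept_rate = if (tries > 0) acc / tries else NA_real_,
         scale = s)
  })
}
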