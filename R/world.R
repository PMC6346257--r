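#' Configuration for a synthetic raster world
#'
#' Describes a rectangular pixel world with nested administrative partitions
#' (admin2 within admin1 within country within region), per-year under-5
#' population, and a small set of smooth space-time covariate layers. All
#' coordinates are abstract planar pixel units; distances are Euclidean.
#'
#' Countries are laid out as a `country_rows x country_cols` block grid;
#' each country is split into `admin1_rows x admin1_cols` admin1 blocks and
#' each admin1 into `admin2_rows x admin2_cols` admin2 blocks. Regions group
#' contiguous rows of countries. Requesting a partition that does not divide
#' the grid evenly is a configuration error.
#'
#' @param n_rows,n_cols grid dimensions in pixels (>= 4).
#' @param years calendar years simulated; the default 2000:2016 covers the
#'   2000--2015 estimation span plus 2016, which national benchmark series
#'   report.
#' @param country_rows,country_cols country block layout.
#' @param admin1_rows,admin1_cols admin1 blocks per country.
#' @param admin2_rows,admin2_cols admin2 blocks per admin1.
#' @param n_regions number of regions (contiguous groups of country rows).
#' @param n_covariates number of covariate layers (>= 3).
#' @param pop_mean target mean under-5 population per pixel.
#' @param pop_growth annual multiplicative population growth rate.
#' @param mask_pop_threshold pixels whose minimum population across years
#'   falls below this count are masked out of analysis (0 = no masking).
#' @return a `world_config` list.
#' @export
world_config <- function(n_rows = 20, n_cols = 20, years = 2000:2016,
                         country_rows = 2, country_cols = 2,
                         admin1_rows = 2, admin1_cols = 2,
                         admin2_rows = 1, admin2_cols = 1,
                         n_regions = 1, n_covariates = 3,
                         pop_mean = 50, pop_growth = 0.02,
                         mask_pop_threshold = 0) {
  if (n_rows < 4 || n_cols < 4) stop("grid must be at least 4 x 4 pixels")
  if (country_rows < 1 || country_cols < 1) stop("need at least one country")
  if (n_covariates < 3) stop("need at least 3 covariate layers")
  if (n_rows %% (country_rows * admin1_rows * admin2_rows) != 0 ||
      n_cols %% (country_cols * admin1_cols * admin2_cols) != 0) {
    stop("configuration error: admin partition does not nest evenly in the grid")
  }
  if (country_rows %% n_regions != 0) {
    stop("configuration error: regions must group whole rows of countries")
  }
  structure(list(
    n_rows = n_rows, n_cols = n_cols, years = years,
    country_rows = country_rows, country_cols = country_cols,
    admin1_rows = admin1_rows, admin1_cols = admin1_cols,
    admin2_rows = admin2_rows, admin2_cols = admin2_cols,
    n_regions = n_regions, n_covariates = n_covariates,
    pop_mean = pop_mean, pop_growth = pop_growth,
    mask_pop_threshold = mask_pop_threshold
  ), class = "world_config")
}

## smooth random surface: sum of low-frequency cosines with seeded phases;
## returns a length-P vector (mean ~0, sd ~1 before any rescaling)
smooth_surface <- function(coords, n_waves = 4, max_freq = 0.08) {
  f <- numeric(nrow(coords))
  for (j in seq_len(n_waves)) {
    w <- stats::runif(2, -max_freq, max_freq)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + cos(2 * pi * (coords[, 1] * w[1] + coords[, 2] * w[2]) + ph)
  }
  as.numeric(scale(f))
}

#' Generate a synthetic pixel world with covariates
#'
#' Builds the raster world the analysis runs on: pixel centers, nested admin
#' id layers, a smooth log-normal under-5 population surface with temporal
#' growth, an analysis mask, and a stack of standardized covariate layers
#' (one with a deterministic space + time trend, one static, the rest smooth
#' and temporally dynamic). Deterministic for a fixed seed.
#'
#' @param config a [world_config()].
#' @param seed integer seed.
#' @return a list with elements `grid` (class `pixel_grid`) and
#'   `covariates` (class `covariate_stack`). The grid holds `coords`
#'   (P x 2 pixel centers), integer id vectors `country_id`, `admin1_id`,
#'   `admin2_id`, `region_id`, a `population` P x T matrix and logical
#'   `mask` (`TRUE` = excluded from analysis).
#' @export
make_world <- function(config = world_config(), seed = 1L) {
  stopifnot(inherits(config, "world_config"))
  cf <- config
  P <- cf$n_rows * cf$n_cols
  Tn <- length(cf$years)
  row_i <- rep(seq_len(cf$n_rows), each = cf$n_cols)
  col_i <- rep(seq_len(cf$n_cols), times = cf$n_rows)
  coords <- cbind(x = col_i - 0.5, y = row_i - 0.5)

  block_id <- function(r, c, nr_blocks, nc_blocks, nr, nc) {
    br <- ceiling(r / (nr / nr_blocks))
    bc <- ceiling(c / (nc / nc_blocks))
    as.integer((br - 1L) * nc_blocks + bc)
  }
  country_id <- block_id(row_i, col_i, cf$country_rows, cf$country_cols,
                         cf$n_rows, cf$n_cols)
  a1_rows_tot <- cf$country_rows * cf$admin1_rows
  a1_cols_tot <- cf$country_cols * cf$admin1_cols
  admin1_id <- block_id(row_i, col_i, a1_rows_tot, a1_cols_tot,
                        cf$n_rows, cf$n_cols)
  a2_rows_tot <- a1_rows_tot * cf$admin2_rows
  a2_cols_tot <- a1_cols_tot * cf$admin2_cols
  admin2_id <- block_id(row_i, col_i, a2_rows_tot, a2_cols_tot,
                        cf$n_rows, cf$n_cols)
  country_row <- ceiling(country_id / cf$country_cols)
  region_id <- as.integer(ceiling(country_row / (cf$country_rows / cf$n_regions)))

  pg <- with_seed(child_seed(seed, "world"), {
    pop_field <- smooth_surface(coords, n_waves = 5)
    yr_wobble <- as.numeric(scale(cumsum(stats::rnorm(Tn, sd = 1))))
    base <- exp(0.8 * pop_field)
    base <- base / mean(base) * cf$pop_mean
    population <- outer(base, (1 + cf$pop_growth)^(seq_len(Tn) - 1)) *
      exp(0.03 * matrix(yr_wobble, P, Tn, byrow = TRUE))
    mask <- apply(population, 1, min) < cf$mask_pop_threshold

    values <- array(NA_real_, dim = c(P, Tn, cf$n_covariates))
    nm <- paste0("cov", seq_len(cf$n_covariates))
    is_static <- rep(FALSE, cf$n_covariates)
    ## cov1: deterministic spatial gradient plus a linear time trend
    tr <- outer(as.numeric(scale(coords[, 1] + 0.5 * coords[, 2])),
                rep(1, Tn)) +
      matrix(seq(-1, 1, length.out = Tn), P, Tn, byrow = TRUE)
    values[, , 1] <- tr
    ## cov2: static surface; broad structure plus pixel-scale detail (real
    ## raster covariates carry fine-scale variation a smooth field cannot)
    st <- smooth_surface(coords, n_waves = 4) +
      0.7 * smooth_surface(coords, n_waves = 6, max_freq = 0.35)
    values[, , 2] <- matrix(st, P, Tn)
    is_static[2] <- TRUE
    ## remaining: broad + fine surfaces drifting slowly in time
    if (cf$n_covariates >= 3) {
      for (k in 3:cf$n_covariates) {
        s1 <- smooth_surface(coords, n_waves = 4) +
          0.7 * smooth_surface(coords, n_waves = 6, max_freq = 0.35)
        s2 <- smooth_surface(coords, n_waves = 4) +
          0.7 * smooth_surface(coords, n_waves = 6, max_freq = 0.35)
        a <- seq(0, 1, length.out = Tn)
        values[, , k] <- outer(s1, 1 - a) + outer(s2, a)
      }
    }
    ## standardize each layer over all pixel-years
    for (k in seq_len(cf$n_covariates)) {
      v <- values[, , k]
      values[, , k] <- (v - mean(v)) / stats::sd(v)
    }
    list(population = population, mask = mask, values = values,
         names = nm, is_static = is_static)
  })

  grid <- structure(list(
    n_rows = cf$n_rows, n_cols = cf$n_cols, pixel_size = 1,
    years = cf$years, coords = coords,
    country_id = country_id, admin1_id = admin1_id, admin2_id = admin2_id,
    region_id = region_id,
    population = pg$population, mask = pg$mask,
    config = cf, seed = seed
  ), class = "pixel_grid")
  covs <- structure(list(
    values = pg$values, names = pg$names, is_static = pg$is_static,
    years = cf$years
  ), class = "covariate_stack")
  validate_pixel_grid(grid)
  list(grid = grid, covariates = covs)
}

validate_pixel_grid <- function(grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (any(!is.finite(grid$population)) || any(grid$population < 0)) {
    stop("population must be finite and nonnegative")
  }
  if (any(is.na(grid$country_id[!grid$mask]))) {
    stop("every unmasked pixel must have a country id")
  }
  ## nesting: each finer unit maps to exactly one coarser unit
  nest_ok <- function(fine, coarse) {
    all(tapply(coarse, fine, function(v) length(unique(v))) == 1L)
  }
  if (!nest_ok(grid$admin2_id, grid$admin1_id) ||
      !nest_ok(grid$admin1_id, grid$country_id) ||
      !nest_ok(grid$country_id, grid$region_id)) {
    stop("admin layers must nest: admin2 in admin1 in country in region")
  }
  invisible(grid)
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> %d x %d pixels, %d years (%d-%d)\n",
              x$n_rows, x$n_cols, length(x$years), min(x$years), max(x$years)))
  cat(sprintf("  countries: %d  admin1: %d  admin2: %d  regions: %d  masked: %d\n",
              length(unique(x$country_id)), length(unique(x$admin1_id)),
              length(unique(x$admin2_id)), length(unique(x$region_id)),
              sum(x$mask)))
  invisible(x)
}

#' Simulate a true logit-prevalence surface
#'
#' Draws one realization of the generative model the geostatistical fit
#' assumes: a linear combination of covariates on the logit scale plus one
#' draw of a zero-mean Matern-in-space, AR1-in-time Gaussian process. The
#' field is simulated exactly through its state-space representation
#' (stationary Matern start, AR1 innovations), so marginally every year has
#' the full Matern covariance and the between-year correlation is rho^|t-s|.
#'
#' @param grid a `pixel_grid`.
#' @param covariates a `covariate_stack`.
#' @param gp a [gp_hyperparams()]; `nugget_var` is observation noise and does
#'   not enter the surface.
#' @param beta covariate weights (length = number of layers).
#' @param intercept logit-scale intercept setting the baseline prevalence.
#' @param indicator label carried through downstream products.
#' @param seed integer seed.
#' @param covariate_effect optional function taking the P x T x K covariate
#'   array and returning a P x T logit-scale mean surface; overrides the
#'   linear `intercept + sum(beta_k * cov_k)` term (use it to give the truth
#'   nonlinear covariate effects or interactions).
#' @return a `truth_surface`: `logit_prev` (P x T), the generating
#'   parameters, and the seed.
#' @export
simulate_truth <- function(grid, covariates, gp = gp_hyperparams(),
                           beta = c(0.5, 0.3, 0.2), intercept = -1,
                           indicator = "stunting", seed = 1L,
                           covariate_effect = NULL) {
  stopifnot(inherits(grid, "pixel_grid"), inherits(covariates, "covariate_stack"))
  K <- dim(covariates$values)[3]
  if (length(beta) != K) stop("beta must have one weight per covariate layer")
  if (!all(is.finite(beta))) stop("beta must be finite")
  P <- nrow(grid$coords); Tn <- length(grid$years)
  if (is.null(covariate_effect)) {
    lin <- matrix(intercept, P, Tn)
    for (k in seq_len(K)) lin <- lin + beta[k] * covariates$values[, , k]
  } else {
    lin <- covariate_effect(covariates$values)
    if (!identical(dim(lin), c(P, Tn))) {
      stop("covariate_effect must return a pixels x years matrix")
    }
  }

  f <- matrix(0, P, Tn)
  if (gp$spatial_var > 0) {
    S <- matern_cov_matrix(grid$coords, gp$spatial_var, gp$spatial_range,
                           gp$matern_smoothness)
    L <- t(chol(S + diag(1e-10 * gp$spatial_var, P)))
    f <- with_seed(child_seed(seed, "truth-gp"), {
      z <- matrix(stats::rnorm(P * Tn), P, Tn)
      out <- matrix(0, P, Tn)
      out[, 1] <- L %*% z[, 1]
      if (Tn > 1) {
        s <- sqrt(1 - gp$ar1_rho^2)
        for (t in 2:Tn) out[, t] <- gp$ar1_rho * out[, t - 1] + s * (L %*% z[, t])
      }
      out
    })
  }
  lp <- lin + f
  stopifnot(all(is.finite(lp)))
  structure(list(
    logit_prev = lp, gp_params_true = gp, beta_true = beta,
    intercept_true = intercept, indicator = indicator, seed = seed,
    years = grid$years
  ), class = "truth_surface")
}

#' Survey design for the synthetic world
#'
#' Defaults describe a DHS/MICS-like synthetic survey programme: 150 point or
#' polygon clusters per year, around 30 measured under-5 children per
#' cluster, and 60% of clusters carrying GPS coordinates (the remaining 40%
#' are referenced only to their admin2 polygon).
#'
#' @param clusters_per_year number of survey clusters sampled each year.
#' @param mean_n mean children measured per cluster (Poisson, floor 2).
#' @param polygon_fraction share of clusters reported as admin2 polygons.
#' @param seasonal_amplitude amplitude (z-score units) of a 12-month sinusoid
#'   added to per-child WHZ; used for the wasting indicator.
#' @param years survey years (default: grid years capped at 2015).
#' @param microdata if `TRUE`, per-child records are generated and cluster
#'   counts are tallied from them; if `FALSE`, cluster counts are drawn
#'   directly as binomials at the cluster's pixel-year truth.
#' @return a `survey_design` list.
#' @export
survey_design <- function(clusters_per_year = 150, mean_n = 30,
                          polygon_fraction = 0.4, seasonal_amplitude = 0,
                          years = NULL, microdata = FALSE) {
  stopifnot(clusters_per_year >= 1, mean_n >= 2,
            polygon_fraction >= 0, polygon_fraction <= 1)
  structure(list(clusters_per_year = clusters_per_year, mean_n = mean_n,
                 polygon_fraction = polygon_fraction,
                 seasonal_amplitude = seasonal_amplitude,
                 years = years, microdata = microdata),
            class = "survey_design")
}

#' Simulate cluster surveys from a truth surface
#'
#' Point clusters land at population-weighted random pixels and carry exact
#' coordinates; polygon clusters reference an admin2 unit and aggregate
#' children across its pixels (population-weighted). Counts are binomial at
#' the pixel-year truth. With `design$microdata = TRUE` per-child z-scores
#' and LMS-consistent measurements are generated (with a 12-month sinusoid
#' on WHZ when `seasonal_amplitude > 0`) and cluster counts are tallied from
#' the children, so microdata and counts agree by construction.
#'
#' @param truth a `truth_surface`.
#' @param grid a `pixel_grid`.
#' @param design a [survey_design()].
#' @param seed integer seed.
#' @return a list with `clusters` (a `cluster_obs` data.frame) and
#'   `children` (a `ChildRecord` data.frame, or `NULL` without microdata).
#' @export
simulate_surveys <- function(truth, grid, design = survey_design(), seed = 1L) {
  stopifnot(inherits(truth, "truth_surface"), inherits(grid, "pixel_grid"),
            inherits(design, "survey_design"))
  years <- design$years %||% grid$years[grid$years <= 2015]
  yr_idx <- match(years, grid$years)
  if (anyNA(yr_idx)) stop("survey years must be simulated in the world")
  keep <- !grid$mask
  if (!any(keep)) stop("cannot place clusters: every pixel is masked")

  res <- with_seed(child_seed(seed, "surveys"), {
    rows <- list(); kids <- list(); cid <- 0L
    for (ti in seq_along(years)) {
      yy <- years[ti]; t <- yr_idx[ti]
      pop <- grid$population[, t] * keep
      if (sum(pop) <= 0) stop("cannot place clusters: no unmasked population")
      n_poly <- stats::rbinom(1, design$clusters_per_year, design$polygon_fraction)
      n_pt <- design$clusters_per_year - n_poly
      ## point clusters
      px <- sample.int(length(pop), n_pt, replace = TRUE, prob = pop)
      for (i in seq_len(n_pt)) {
        cid <- cid + 1L
        N <- max(2L, stats::rpois(1, design$mean_n))
        month <- sample.int(12L, 1L)
        p <- invlogit(truth$logit_prev[px[i], t])
        if (design$microdata) {
          ch <- simulate_children(cid, N, p, month, yy, truth$indicator,
                                  design$seasonal_amplitude)
          kids[[length(kids) + 1L]] <- ch$records
          C <- ch$C
        } else C <- stats::rbinom(1, N, p)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_id = cid, indicator = truth$indicator,
          x = grid$coords[px[i], 1] + stats::runif(1, -0.5, 0.5) * grid$pixel_size,
          y = grid$coords[px[i], 2] + stats::runif(1, -0.5, 0.5) * grid$pixel_size,
          polygon_id = NA_integer_, year = yy, month = month,
          N = N, C = C, weight = 1)
      }
      ## polygon clusters: children spread over the admin2 unit's pixels
      if (n_poly > 0) {
        upop <- tapply(pop, grid$admin2_id, sum)
        units <- as.integer(names(upop))[upop > 0]
        uprob <- upop[upop > 0]
        us <- units[sample.int(length(units), n_poly, replace = TRUE, prob = uprob)]
        for (i in seq_len(n_poly)) {
          cid <- cid + 1L
          N <- max(2L, stats::rpois(1, design$mean_n))
          month <- sample.int(12L, 1L)
          upx <- which(grid$admin2_id == us[i] & keep)
          alloc <- as.vector(stats::rmultinom(1, N, grid$population[upx, t]))
          C <- 0L; chl <- NULL
          for (j in which(alloc > 0)) {
            p <- invlogit(truth$logit_prev[upx[j], t])
            if (design$microdata) {
              ch <- simulate_children(cid, alloc[j], p, month, yy,
                                      truth$indicator, design$seasonal_amplitude)
              chl <- rbind(chl, ch$records)
              C <- C + ch$C
            } else C <- C + stats::rbinom(1, alloc[j], p)
          }
          if (!is.null(chl)) kids[[length(kids) + 1L]] <- chl
          rows[[length(rows) + 1L]] <- data.frame(
            cluster_id = cid, indicator = truth$indicator,
            x = NA_real_, y = NA_real_, polygon_id = us[i],
            year = yy, month = month, N = N, C = C, weight = 1)
        }
      }
    }
    list(clusters = do.call(rbind, rows),
         children = if (length(kids)) do.call(rbind, kids) else NULL)
  })
  res$clusters <- as_cluster_obs(res$clusters)
  res
}

## children at one cluster-pixel: latent z ~ N(mu, 1) with P(z < -2) = p,
## plus an optional 12-month sinusoid (the wasting seasonality mechanism);
## measurements are generated through the inverse LMS transform so the
## anthro module recovers the same z-scores
simulate_children <- function(cluster_id, n, p, month, year, indicator, amp) {
  mu <- -2 - stats::qnorm(pmin(pmax(p, 1e-9), 1 - 1e-9))
  z <- stats::rnorm(n, mu, 1)
  if (amp != 0) z <- z + amp * sin(2 * pi * month / 12)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  age <- sample(0:59, n, replace = TRUE)
  height <- weight <- rep(NA_real_, n)
  if (indicator == "stunting") {
    height <- lms_measurement(z, "HAZ", sex, age)
  } else if (indicator == "underweight") {
    weight <- lms_measurement(z, "WAZ", sex, age)
  } else if (indicator == "wasting") {
    zh <- stats::rnorm(n, -1, 1)
    height <- lms_measurement(zh, "HAZ", sex, age)
    hb <- pmin(pmax(round(height), 45), 120)
    weight <- lms_measurement(z, "WHZ", sex, hb)
  } else stop("unknown indicator: ", indicator)
  list(records = data.frame(
    cluster_id = cluster_id, sex = sex, age = age,
    height = height, weight = weight,
    interview_year = year, interview_month = month,
    survey_weight = 1, stringsAsFactors = FALSE),
    C = sum(z < -2))
}

#' Simulate a national benchmark prevalence series
#'
#' Stands in for an external national estimation series (a GBD-like source):
#' the population-weighted national aggregate of the truth at the benchmark
#' years, optionally perturbed by logit-scale Gaussian noise.
#'
#' @param truth a `truth_surface`.
#' @param grid a `pixel_grid`.
#' @param perturbation_sd logit-scale noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param years benchmark years (default 2000, 2005, 2010, 2016).
#' @return a `national_series` data.frame with columns `country_id`,
#'   `indicator`, `year`, `prevalence`.
#' @export
simulate_national_series <- function(truth, grid, perturbation_sd = 0,
                                     seed = 1L,
                                     years = c(2000, 2005, 2010, 2016)) {
  stopifnot(perturbation_sd >= 0)
  yr_idx <- match(years, grid$years)
  if (anyNA(yr_idx)) stop("benchmark years must be simulated in the world")
  keep <- !grid$mask
  countries <- sort(unique(grid$country_id[keep]))
  out <- expand.grid(country_id = countries, year = years,
                     KEEP.OUT.ATTRS = FALSE)
  out$indicator <- truth$indicator
  out$prevalence <- mapply(function(cc, yy) {
    t <- match(yy, grid$years)
    sel <- keep & grid$country_id == cc
    wmean(invlogit(truth$logit_prev[sel, t]), grid$population[sel, t])
  }, out$country_id, out$year)
  if (perturbation_sd > 0) {
    out$prevalence <- with_seed(child_seed(seed, "national"), {
      invlogit(logit(out$prevalence) + stats::rnorm(nrow(out), 0, perturbation_sd))
    })
  }
  out <- out[order(out$country_id, out$year), c("country_id", "indicator",
                                                "year", "prevalence")]
  rownames(out) <- NULL
  class(out) <- c("national_series", "data.frame")
  out
}

## snap continuous coordinates to pixel indices on a grid
snap_to_pixel <- function(grid, x, y) {
  col <- pmin(pmax(ceiling(x / grid$pixel_size), 1L), grid$n_cols)
  row <- pmin(pmax(ceiling(y / grid$pixel_size), 1L), grid$n_rows)
  as.integer((row - 1L) * grid$n_cols + col)
}
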