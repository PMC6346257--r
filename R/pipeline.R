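#' Pipeline run configuration
#'
#' One object configures an end-to-end run: world and survey generation,
#' stacking, the geostatistical fit, raking, projection and validation.
#' A seed is mandatory; every stochastic stage derives its own stream from
#' it. `pipeline_config()` builds the nested list; [read_pipeline_config()]
#' loads the same structure from YAML.
#'
#' @param seed global integer seed (required).
#' @param output_dir where products are written.
#' @param indicator indicator label (stunting, wasting or underweight).
#' @param world a [world_config()].
#' @param design a [survey_design()].
#' @param gp true GP hyperparameters for the simulated world.
#' @param beta,intercept truth mean structure (covariate weights).
#' @param n_draws posterior draws (default 250).
#' @param series_sd logit-scale perturbation of the national series.
#' @param target a [target_spec()]; default: fixed 5% for wasting, 40%
#'   relative reduction otherwise.
#' @param validate run the formulation comparison (slow; default FALSE).
#' @param control fit control passed to [fit_geostat()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed, output_dir = tempfile("cgfmap_run_"),
                            indicator = "stunting",
                            world = world_config(), design = survey_design(),
                            gp = gp_hyperparams(), beta = c(0.5, 0.3, 0.2),
                            intercept = -1, n_draws = 250, series_sd = 0.05,
                            target = NULL,
                            validate = FALSE, control = list()) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  ## wasting has the fixed (< 5%) target; stunting and underweight the
  ## 40%-reduction-relative-to-2010 target
  target <- target %||% if (identical(indicator, "wasting")) {
    target_spec(indicator, "fixed")
  } else target_spec(indicator, "relative")
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 indicator = indicator, world = world, design = design,
                 gp = gp, beta = beta, intercept = intercept,
                 n_draws = n_draws, series_sd = series_sd, target = target,
                 validate = validate, control = control),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [pipeline_config()] fields (nested
#'   `world`, `design`, `gp`, `target` sections use the constructors'
#'   argument names). A missing seed is an error.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed")
  args <- list(seed = y$seed)
  for (nm in c("output_dir", "indicator", "n_draws", "series_sd", "validate")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$world)) args$world <- do.call(world_config, y$world)
  if (!is.null(y$design)) args$design <- do.call(survey_design, y$design)
  if (!is.null(y$gp)) args$gp <- do.call(gp_hyperparams, y$gp)
  if (!is.null(y$beta)) args$beta <- as.numeric(y$beta)
  if (!is.null(y$intercept)) args$intercept <- y$intercept
  if (!is.null(y$target)) args$target <- do.call(target_spec, y$target)
  if (!is.null(y$control)) args$control <- y$control
  do.call(pipeline_config, args)
}

#' Run the full mapping pipeline on a synthetic world
#'
#' Executes the stages end to end: simulate world and truth, simulate
#' surveys (with microdata), z-score and collapse the microdata (with
#' seasonality adjustment for wasting), resample polygon observations to
#' weighted pseudo-points, fit the stacked learners, fit the geostatistical
#' model per region, predict candidate maps, aggregate, rake to the national
#' series, mask, project to 2025 and score target attainment, optionally run
#' the formulation comparison, and write all products plus a manifest with
#' file checksums. Deterministic for a fixed config.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the main objects (`grid`, `truth`, `cube_raw`,
#'   `cube` (raked), aggregates, `projection`, `attainment`, `manifest`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ## 1. world + truth
  world <- stage("simulate", make_world(config$world, seed = seed))
  grid <- world$grid; covs <- world$covariates
  truth <- stage("simulate", simulate_truth(grid, covs, config$gp,
                                            beta = config$beta,
                                            intercept = config$intercept,
                                            indicator = config$indicator,
                                            seed = seed))
  design <- config$design
  if (config$indicator == "wasting" && design$seasonal_amplitude == 0) {
    design$seasonal_amplitude <- 0.4
  }
  design$microdata <- TRUE
  sv <- stage("simulate", simulate_surveys(truth, grid, design, seed = seed))
  series <- stage("simulate",
                  simulate_national_series(truth, grid, config$series_sd,
                                           seed = seed))

  ## 2. anthro: exclusions, z-scores, collapse
  excl <- stage("anthro", apply_exclusions(sv$children, cluster_meta = sv$clusters))
  records <- excl$records
  zind <- c(stunting = "HAZ", wasting = "WHZ", underweight = "WAZ")[config$indicator]
  lms <- synthetic_lms_table(zind)
  seasonal <- NULL
  if (config$indicator == "wasting") {
    records$whz <- child_zscores(records, lms, "WHZ")
    meta <- sv$clusters
    pixm <- ifelse(is.na(meta$polygon_id),
                   snap_to_pixel(grid, meta$x, meta$y),
                   match_poly_pixel(grid, meta$polygon_id))
    map <- data.frame(cluster_id = meta$cluster_id,
                      region_id = grid$region_id[pixm],
                      country_id = grid$country_id[pixm])
    records <- merge(records, map, by = "cluster_id", sort = FALSE)
    seasonal <- stage("preprocess", fit_seasonal_model(records))
    records <- stage("preprocess", adjust_seasonality(records, seasonal))
    ## re-express the adjusted z-scores as measurements for collapsing
    hb <- pmin(pmax(round(records$height), 45), 120)
    records$weight <- lms_measurement(records$whz, "WHZ", records$sex, hb, lms)
  }
  obs <- stage("anthro", collapse_to_cluster(records, lms, config$indicator,
                                             cluster_meta = sv$clusters))

  ## 3. polygons -> pseudo-points
  pseudo <- stage("preprocess",
                  resample_polygon_obs(obs[!is.na(obs$polygon_id), ], grid,
                                       seed = seed))
  pts <- obs[is.na(obs$polygon_id), setdiff(names(obs), "parent_obs_id")]
  model_obs <- rbind(cbind(pts, parent_obs_id = pts$cluster_id),
                     pseudo[, c(names(pts), "parent_obs_id")])
  model_obs <- as_cluster_obs(model_obs)

  ## 4. stacking + 5. geostat fit + predict (per region)
  sf <- stage("stack", fit_child_learners(model_obs, covs, grid, seed = seed))
  years <- grid$years[grid$years >= min(model_obs$year) &
                        grid$years <= max(model_obs$year)]
  fit <- stage("fit", fit_geostat(model_obs, sf, grid, seed = seed,
                                  n_draws = config$n_draws, years = years,
                                  control = config$control))
  cube_raw <- stage("predict", predict_pixel_draws(fit, sf, grid))

  ## 6. aggregate + rake + mask
  nat <- stage("aggregate", aggregate_admin(cube_raw, grid, "national"))
  adm1 <- stage("aggregate", aggregate_admin(cube_raw, grid, "admin1"))
  rt <- stage("rake", compute_raking_factors(nat, series))
  cube <- stage("rake", apply_raking(cube_raw, rt, grid))
  cube <- stage("mask", apply_mask(cube, grid))
  nat_raked <- stage("aggregate", aggregate_admin(cube, grid, "national"))
  adm1_raked <- stage("aggregate", aggregate_admin(cube, grid, "admin1"))
  adm2_raked <- stage("aggregate", aggregate_admin(cube, grid, "admin2"))

  ## 7. projection + targets
  pmean <- apply(cube$prevalence, c(2, 3), mean)
  proj_years <- match(2000:2015, cube$years)
  tgt <- stage("targets", resolve_targets(config$target, series, grid))
  projection <- NULL; attain <- NULL; pace <- NULL
  if (!anyNA(proj_years)) {
    cfg <- projection_config()
    ok <- !grid$mask & apply(is.finite(pmean[, proj_years]), 1, all)
    ar <- rep(NA_real_, nrow(pmean))
    ar[ok] <- weighted_aroc(annual_logit_aroc(pmean[ok, proj_years]), cfg)
    p2025 <- rep(NA_real_, nrow(pmean))
    p2025[ok] <- project_prevalence(pmean[ok, proj_years[16]], ar[ok])
    pace <- data.frame(pixel = seq_len(nrow(pmean)), aroc = ar, p2025 = p2025)
    pc <- pace_and_acceleration(pmean[ok, proj_years, drop = FALSE],
                                tgt$resolved_target, cfg)
    pace$status <- NA_character_; pace$accel_class <- NA_character_
    pace$status[ok] <- pc$status; pace$accel_class[ok] <- pc$accel_class
    projection <- pace
    attain <- list(
      pixel = prob_target_met(cube, tgt$resolved_target, grid, "pixel"),
      admin1 = prob_target_met(cube, tgt$resolved_target, grid, "admin1"))
  }

  ## 8. optional validation
  cvrep <- NULL
  if (isTRUE(config$validate)) {
    cvrep <- stage("validate",
                   compare_formulations(model_obs, covs, grid, seed = seed))
  }

  results <- list(grid = grid, covariates = covs, truth = truth,
                  series = series, clusters = obs, model_obs = model_obs,
                  seasonal = seasonal, stacked = sf, fit = fit,
                  cube_raw = cube_raw, cube = cube,
                  national = nat_raked, admin1 = adm1_raked,
                  admin2 = adm2_raked, national_unraked = nat,
                  admin1_unraked = adm1, raking = rt, target = tgt,
                  projection = projection, attainment = attain,
                  cv = cvrep, config = config)
  manifest <- stage("report", write_products(results, config$output_dir))
  results$manifest <- manifest
  invisible(results)
}

match_poly_pixel <- function(grid, polygon_id) {
  first_px <- tapply(seq_along(grid$admin2_id), grid$admin2_id, `[`, 1)
  as.integer(first_px[as.character(polygon_id)])
}

#' Write pipeline products to disk
#'
#' Rasters (posterior mean/lower/upper per year, projections, attainment
#' probabilities) as ESRI ASCII grids with the mask applied via the nodata
#' sentinel; tables (admin aggregates, raking factors, cluster data,
#' national series, validation report) as CSV; boundaries as GeoJSON; plus a
#' `manifest.csv` listing every file with its md5 checksum and the seed.
#'
#' @param results the list built by [run_pipeline()].
#' @param dir output directory.
#' @return data.frame manifest (file, md5).
#' @export
write_products <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2) != 0) stop("output directory is not writable: ", dir)
  grid <- results$grid
  ind <- results$config$indicator
  paths <- character(0)
  keep_csv <- function(df, nm) {
    p <- file.path(dir, nm)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  cube <- results$cube
  qs <- apply(cube$prevalence, c(2, 3), stats::quantile,
              probs = c(0.025, 0.975), na.rm = TRUE)
  pm <- apply(cube$prevalence, c(2, 3), mean)
  for (t in seq_along(cube$years)) {
    for (nm in c("mean", "lower", "upper")) {
      v <- switch(nm, mean = pm[, t], lower = qs[1, , t], upper = qs[2, , t])
      p <- file.path(dir, sprintf("%s_%s_%d.asc", ind, nm, cube$years[t]))
      write_ascii_grid(apply_mask(v, grid), grid, p)
      paths <- c(paths, p)
    }
  }
  if (!is.null(results$projection)) {
    p <- file.path(dir, sprintf("%s_p2025.asc", ind))
    write_ascii_grid(apply_mask(results$projection$p2025, grid), grid, p)
    paths <- c(paths, p)
    keep_csv(results$projection, sprintf("%s_projection.csv", ind))
  }
  if (!is.null(results$attainment)) {
    p <- file.path(dir, sprintf("%s_prob_target_met.asc", ind))
    write_ascii_grid(apply_mask(results$attainment$pixel, grid), grid, p)
    paths <- c(paths, p)
    keep_csv(results$attainment$admin1, sprintf("%s_prob_target_met_admin1.csv", ind))
  }
  for (lv in c("national", "admin1", "admin2")) {
    keep_csv(results[[lv]]$summary, sprintf("%s_%s.csv", ind, lv))
  }
  rk <- results$raking
  keep_csv(data.frame(country_id = rep(rk$countries, times = length(rk$years)),
                      year = rep(rk$years, each = length(rk$countries)),
                      factor_median = as.vector(apply(rk$factors, c(2, 3),
                                                      stats::median))),
           sprintf("%s_raking_factors.csv", ind))
  keep_csv(results$model_obs, sprintf("%s_model_obs.csv", ind))
  keep_csv(results$series, "national_series.csv")
  if (!is.null(results$cv)) keep_csv(results$cv, "cv_report.csv")
  if (!is.null(results$seasonal)) {
    keep_csv(results$seasonal$effects, "seasonal_effects.csv")
  }
  for (lv in c("country", "admin1", "admin2")) {
    p <- file.path(dir, paste0(lv, ".geojson"))
    write_boundaries_geojson(grid, lv, p)
    paths <- c(paths, p)
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         seed = results$config$seed)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
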