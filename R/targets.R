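#' Projection configuration
#'
#' Recency weights for the annualized rate of change (AROC): weight of year
#' `t` is proportional to `(t - 2000)^gamma`, normalized to sum to 1 over
#' 2001..2015. `gamma = 1` (default) is the linear scheme; `gamma = 0` is a
#' simple mean.
#'
#' @param gamma weight exponent (>= 0).
#' @param horizon projection horizon in years (default 10, i.e. 2015 to 2025).
#' @param base_year final estimation year (default 2015).
#' @param start_year first estimation year (default 2000).
#' @return a `projection_config` with the normalized `weights`.
#' @export
projection_config <- function(gamma = 1, horizon = 10, base_year = 2015,
                              start_year = 2000) {
  stopifnot(gamma >= 0, horizon >= 1, base_year > start_year)
  tt <- (start_year + 1):base_year
  raw <- (tt - start_year)^gamma
  structure(list(gamma = gamma, horizon = horizon, base_year = base_year,
                 start_year = start_year, years = tt,
                 weights = raw / sum(raw)),
            class = "projection_config")
}

#' Annual logit-scale rates of change
#'
#' Differences of logit prevalence between adjacent years:
#' `AROC_t = logit(p_t) - logit(p_(t-1))` for t = 2001..2015, computed from
#' the 16-year posterior mean series per pixel. Prevalences are clipped at
#' 1e-6 before the logit.
#'
#' @param p matrix (pixels x 16 years, 2000..2015) or vector of length 16;
#'   values in \[0, 1\].
#' @return matrix (pixels x 15) of annual changes.
#' @export
annual_logit_aroc <- function(p) {
  if (is.vector(p)) p <- matrix(p, 1)
  if (ncol(p) != 16) stop("expected a 16-year series (2000..2015)")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("prevalence must be in [0, 1]")
  lp <- logit(p)
  lp[, -1, drop = FALSE] - lp[, -ncol(p), drop = FALSE]
}

#' Recency-weighted mean AROC
#'
#' @param aroc matrix (pixels x 15) from [annual_logit_aroc()].
#' @param config a [projection_config()].
#' @return numeric vector of weighted mean AROCs per pixel.
#' @export
weighted_aroc <- function(aroc, config = projection_config()) {
  if (is.vector(aroc)) aroc <- matrix(aroc, 1)
  if (ncol(aroc) != length(config$weights)) {
    stop("aroc columns must match the config weight vector")
  }
  as.numeric(aroc %*% config$weights)
}

#' Project prevalence forward at the estimated pace
#'
#' `p_future = invlogit(logit(p_base) + horizon * aroc)`, the simple
#' logit-linear projection from the final estimation year.
#'
#' @param p_base prevalence at the base year (in (0, 1)).
#' @param aroc weighted mean AROC per pixel.
#' @param horizon years projected forward (default 10).
#' @return projected prevalence, in (0, 1).
#' @export
project_prevalence <- function(p_base, aroc, horizon = 10) {
  invlogit(logit(p_base) + horizon * aroc)
}

#' WHO Global Nutrition Target specification
#'
#' Relative targets (stunting, underweight: 40% reduction relative to the
#' 2010 aggregate) resolve against a population-weighted continental 2010
#' prevalence; fixed targets (wasting: below 5%) resolve to their level.
#'
#' @param indicator indicator label.
#' @param target_type "relative" or "fixed".
#' @param reduction_fraction reduction for relative targets (default 0.40).
#' @param fixed_level level for fixed targets (default 0.05).
#' @return a `target_spec` (unresolved until [resolve_targets()]).
#' @export
target_spec <- function(indicator,
                        target_type = c("relative", "fixed"),
                        reduction_fraction = 0.40, fixed_level = 0.05) {
  target_type <- match.arg(target_type)
  if (target_type == "relative") {
    stopifnot(reduction_fraction > 0, reduction_fraction < 1)
  } else stopifnot(fixed_level > 0, fixed_level < 1)
  structure(list(indicator = indicator, target_type = target_type,
                 reduction_fraction = reduction_fraction,
                 fixed_level = fixed_level, resolved_target = NULL),
            class = "target_spec")
}

#' Resolve a target to a prevalence level
#'
#' Relative targets become `(1 - reduction_fraction)` times the
#' population-weighted aggregate prevalence at 2010 across the whole
#' modelled domain (computed from the national series and 2010 populations);
#' fixed targets pass their level through.
#'
#' @param spec a [target_spec()].
#' @param series a `national_series` including year 2010 (required for
#'   relative targets).
#' @param grid the `pixel_grid` (2010 national populations).
#' @return the spec with `resolved_target` set.
#' @export
resolve_targets <- function(spec, series = NULL, grid = NULL) {
  stopifnot(inherits(spec, "target_spec"))
  if (spec$target_type == "fixed") {
    spec$resolved_target <- spec$fixed_level
    return(spec)
  }
  if (is.null(series) || is.null(grid)) {
    stop("relative targets need the national series and grid at 2010")
  }
  s10 <- series[series$year == 2010, ]
  if (!nrow(s10)) stop("national series does not include 2010")
  t10 <- match(2010, grid$years)
  if (is.na(t10)) stop("grid does not include 2010")
  keep <- !grid$mask
  pop_c <- vapply(s10$country_id, function(cc) {
    sum(grid$population[keep & grid$country_id == cc, t10])
  }, numeric(1))
  agg2010 <- wmean(s10$prevalence, pop_c)
  spec$resolved_target <- (1 - spec$reduction_fraction) * agg2010
  spec
}

#' Pace of progress and required acceleration
#'
#' Compares the achieved annualized decline (minus the weighted AROC, logit
#' scale) with the decline required from the base year to reach the target
#' over the horizon. Pixels already at or below the target are "met";
#' pixels with non-declining prevalence are "non-decreasing". The pace
#' ratio is `100 * achieved / required` (blue >= 100% in the map legends);
#' the acceleration factor `required / achieved` is capped into a ">400%"
#' class above 4.
#'
#' @param p series matrix (pixels x 16 years 2000..2015) of posterior mean
#'   prevalence (raked).
#' @param target resolved target prevalence.
#' @param config a [projection_config()].
#' @return data.frame per pixel: `achieved`, `required`, `pace_ratio`,
#'   `acceleration`, `status`, `accel_class`.
#' @export
pace_and_acceleration <- function(p, target, config = projection_config()) {
  if (is.vector(p)) p <- matrix(p, 1)
  ar <- weighted_aroc(annual_logit_aroc(p), config)
  p15 <- p[, ncol(p)]
  achieved <- -ar
  required <- pmax(0, (logit(p15) - logit(target)) / config$horizon)
  met <- p15 <= target
  status <- ifelse(met, "met",
                   ifelse(achieved <= 0, "non-decreasing", "declining"))
  pace <- ifelse(met | achieved <= 0, NA_real_, 100 * achieved / required)
  accel <- ifelse(met | achieved <= 0, NA_real_, required / achieved)
  accel_class <- ifelse(met, "met",
                 ifelse(achieved <= 0, "non-decreasing",
                 ifelse(accel <= 1, "no increase required",
                 ifelse(accel <= 2, "up to 200%",
                 ifelse(accel <= 4, "200-400%", ">400%")))))
  data.frame(achieved = achieved, required = required, pace_ratio = pace,
             acceleration = accel, status = status, accel_class = accel_class,
             stringsAsFactors = FALSE)
}

#' Probability that the target has been met
#'
#' At pixel level: the fraction of posterior draws strictly below the target
#' at the evaluation year. At an admin level: the fraction of draws whose
#' population-weighted unit aggregate is below the target (an alternative
#' population-weighted mean of pixel probabilities is available with
#' `method = "pixel_mean"`).
#'
#' @param cube a (raked) `posterior_cube` covering `year`.
#' @param target resolved target prevalence.
#' @param grid the `pixel_grid`.
#' @param level "pixel", "admin1", "admin2" or "national".
#' @param year evaluation year (default 2015).
#' @param method admin-level definition: "aggregate_draws" (default) or
#'   "pixel_mean".
#' @return pixel level: numeric vector per pixel (NA where masked).
#'   Admin level: data.frame with `unit_id` and `prob`.
#' @export
prob_target_met <- function(cube, target, grid, level = "pixel", year = 2015,
                            method = c("aggregate_draws", "pixel_mean")) {
  method <- match.arg(method)
  stopifnot(inherits(cube, "posterior_cube"))
  if (dim(cube$prevalence)[1] < 1) stop("cube has no draws")
  t <- match(year, cube$years)
  if (is.na(t)) stop("cube does not cover year ", year)
  pp <- colMeans(cube$prevalence[, , t, drop = FALSE][, , 1] < target)
  pp[grid$mask] <- NA_real_
  if (level == "pixel") return(pp)
  ids <- switch(level, national = grid$country_id, admin1 = grid$admin1_id,
                admin2 = grid$admin2_id,
                stop("unknown level: ", level))
  keep <- !grid$mask
  tg <- match(year, grid$years)
  units <- sort(unique(ids[keep]))
  prob <- vapply(units, function(u) {
    sel <- which(keep & ids == u)
    pw <- grid$population[sel, tg]
    if (method == "aggregate_draws") {
      agg <- (cube$prevalence[, sel, t, drop = FALSE][, , 1] %*% pw) / sum(pw)
      mean(agg < target)
    } else {
      wmean(pp[sel], pw)
    }
  }, numeric(1))
  data.frame(level = level, unit_id = units, year = year, prob = prob)
}
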