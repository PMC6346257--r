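#' Aggregate candidate maps to administrative units
#'
#' Population-weighted conditional simulation: every posterior draw is
#' aggregated per unit and year as `sum(pop_px * p_px) / sum(pop_px)` over
#' the unit's unmasked pixels, using the year-matched population. Fully
#' masked (or unpopulated) units are omitted with a warning.
#'
#' @param cube a `posterior_cube`.
#' @param grid the `pixel_grid`.
#' @param level "national", "admin1" or "admin2".
#' @return an `admin_aggregate`: `draws` array (draws x units x years),
#'   `units`, `years`, `population` (units x years) and a `summary`
#'   data.frame (mean and 95% interval per unit-year).
#' @export
aggregate_admin <- function(cube, grid, level = c("national", "admin1", "admin2")) {
  level <- match.arg(level)
  stopifnot(inherits(cube, "posterior_cube"), inherits(grid, "pixel_grid"))
  ids <- switch(level, national = grid$country_id, admin1 = grid$admin1_id,
                admin2 = grid$admin2_id)
  tix <- match(cube$years, grid$years)
  if (anyNA(tix)) stop("cube years not covered by the grid")
  keep <- !grid$mask
  units_all <- sort(unique(ids))
  ok <- vapply(units_all, function(u) {
    any(keep & ids == u & rowSums(grid$population[, tix, drop = FALSE]) > 0)
  }, logical(1))
  if (any(!ok)) {
    warning("omitting fully masked/unpopulated unit(s): ",
            paste(units_all[!ok], collapse = ", "))
  }
  units <- units_all[ok]
  nd <- dim(cube$prevalence)[1]; Tn <- length(cube$years)
  draws <- array(NA_real_, dim = c(nd, length(units), Tn))
  popmat <- matrix(NA_real_, length(units), Tn)
  for (ui in seq_along(units)) {
    sel <- which(keep & ids == units[ui])
    for (t in seq_len(Tn)) {
      pw <- grid$population[sel, tix[t]]
      popmat[ui, t] <- sum(pw)
      ## draws x pixels slice times population weights
      draws[, ui, t] <- (cube$prevalence[, sel, t, drop = FALSE][, , 1] %*% pw) / sum(pw)
    }
  }
  summ <- do.call(rbind, lapply(seq_along(units), function(ui) {
    data.frame(level = level, unit_id = units[ui], year = cube$years,
               mean = apply(draws[, ui, , drop = FALSE], 3, mean),
               lower = apply(draws[, ui, , drop = FALSE], 3, stats::quantile,
                             probs = 0.025),
               upper = apply(draws[, ui, , drop = FALSE], 3, stats::quantile,
                             probs = 0.975),
               population = popmat[ui, ])
  }))
  rownames(summ) <- NULL
  structure(list(level = level, units = units, years = cube$years,
                 draws = draws, population = popmat, summary = summ,
                 indicator = cube$indicator),
            class = "admin_aggregate")
}

#' Per-draw raking factors against a national series
#'
#' For every posterior draw and country, the raking factor at the anchor
#' years 2000, 2005, 2010 and 2015 is the ratio of the national series
#' target to that draw's population-weighted national aggregate; the 2015
#' target is linearly interpolated between the series' 2010 and 2016 values,
#' and factors at the years in between anchors are linearly interpolated, so
#' every modelled year is covered.
#'
#' @param national an `admin_aggregate` at level "national".
#' @param series a `national_series` covering years 2000, 2005, 2010, 2016.
#' @param anchor_years years at which factors are computed from the series
#'   (default 2000, 2005, 2010, 2015).
#' @return a `raking_table`: `factors` array (draws x countries x years).
#' @export
compute_raking_factors <- function(national, series,
                                   anchor_years = c(2000, 2005, 2010, 2015)) {
  stopifnot(inherits(national, "admin_aggregate"), national$level == "national")
  need <- c(2000, 2005, 2010, 2016)
  years <- national$years
  nd <- dim(national$draws)[1]
  countries <- national$units
  factors <- array(NA_real_, dim = c(nd, length(countries), length(years)))
  for (ci in seq_along(countries)) {
    cc <- countries[ci]
    s <- series[series$country_id == cc, ]
    if (!all(need %in% s$year)) {
      stop("national series for country ", cc, " must cover years ",
           paste(need, collapse = ", "))
    }
    tgt <- function(y) {
      if (y %in% s$year) return(s$prevalence[s$year == y])
      ## interpolate between the two nearest series years (2015 from 2010/2016)
      lo <- max(s$year[s$year < y]); hi <- min(s$year[s$year > y])
      plo <- s$prevalence[s$year == lo]; phi <- s$prevalence[s$year == hi]
      plo + (y - lo) / (hi - lo) * (phi - plo)
    }
    anchors <- anchor_years[anchor_years >= min(years) & anchor_years <= max(years)]
    if (length(anchors) < 1) stop("no anchor years inside the modelled span")
    fa <- matrix(NA_real_, nd, length(anchors))
    for (ai in seq_along(anchors)) {
      est <- national$draws[, ci, match(anchors[ai], years)]
      if (any(est <= 0)) stop("zero national estimate; cannot compute raking factor")
      fa[, ai] <- tgt(anchors[ai]) / est
    }
    for (t in seq_along(years)) {
      y <- years[t]
      if (y <= anchors[1]) {
        factors[, ci, t] <- fa[, 1]
      } else if (y >= anchors[length(anchors)]) {
        factors[, ci, t] <- fa[, length(anchors)]
      } else {
        hi <- min(which(anchors >= y)); lo <- hi - 1
        if (anchors[hi] == y) {
          factors[, ci, t] <- fa[, hi]
        } else {
          lam <- (y - anchors[lo]) / (anchors[hi] - anchors[lo])
          factors[, ci, t] <- (1 - lam) * fa[, lo] + lam * fa[, hi]
        }
      }
    }
  }
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("raking factors must be positive and finite")
  }
  structure(list(factors = factors, countries = countries, years = years,
                 anchor_years = anchor_years, indicator = national$indicator),
            class = "raking_table")
}

#' Rake candidate maps to the national series
#'
#' Multiplies every pixel's prevalence by its country-year raking factor,
#' per draw, clamping at 1 (the multiplicative factor can push prevalence
#' above its support; clip events are counted on the returned cube). After
#' raking with no clipping, national population-weighted aggregates equal
#' the series targets at the anchor years exactly, draw by draw.
#'
#' @param cube a `posterior_cube`.
#' @param table a `raking_table` from [compute_raking_factors()].
#' @param grid the `pixel_grid`.
#' @return the raked `posterior_cube` (`raked = TRUE`, `clip_count` set).
#' @export
apply_raking <- function(cube, table, grid) {
  stopifnot(inherits(cube, "posterior_cube"), inherits(table, "raking_table"))
  if (!identical(as.numeric(cube$years), as.numeric(table$years))) {
    stop("cube and raking table cover different years")
  }
  ci <- match(grid$country_id, table$countries)
  if (any(is.na(ci) & !grid$mask)) stop("missing raking factors for some countries")
  if (dim(cube$prevalence)[1] != dim(table$factors)[1]) {
    stop("cube and raking table have different draw counts")
  }
  prev <- cube$prevalence
  nd <- dim(prev)[1]
  clip <- 0L
  for (t in seq_along(cube$years)) {
    fac <- table$factors[, ci, t]          # draws x pixels
    newp <- prev[, , t] * fac
    clip <- clip + sum(newp > 1, na.rm = TRUE)
    prev[, , t] <- pmin(newp, 1)
  }
  cube$prevalence <- prev
  cube$raked <- TRUE
  cube$clip_count <- clip
  cube
}

#' Mask excluded pixels in gridded products
#'
#' Sets masked pixels (e.g. barren or sparsely vegetated land, or population
#' below the reporting threshold) to `NA` in a pixel vector, a P x T matrix,
#' or a `posterior_cube`. Idempotent.
#'
#' @param x pixel vector, P x T matrix, or `posterior_cube`.
#' @param grid the `pixel_grid` carrying the mask.
#' @return `x` with masked pixels set to `NA`.
#' @export
apply_mask <- function(x, grid) {
  m <- grid$mask
  if (inherits(x, "posterior_cube")) {
    x$prevalence[, m, ] <- NA_real_
    return(x)
  }
  if (is.matrix(x)) { x[m, ] <- NA_real_; return(x) }
  x[m] <- NA_real_
  x
}

#' Population-weighted tail classes of a pixel field
#'
#' Labels the population-weighted lowest and highest tails of a field:
#' pixels are sorted by value (ties broken by pixel index) and the maximal
#' prefix whose cumulative population does not exceed `frac * total` forms
#' each tail. Masked or non-finite pixels are left unlabelled.
#'
#' @param values numeric field per pixel.
#' @param population per-pixel population weights.
#' @param frac tail fraction (default 0.10, as in lowest/highest-10% maps);
#'   use 0.25 for quartile-style tails.
#' @return character vector per pixel: "lowest", "middle", "highest" or NA.
#' @export
pw_quantile_classes <- function(values, population, frac = 0.10) {
  stopifnot(length(values) == length(population), frac > 0, frac < 0.5)
  ok <- is.finite(values) & is.finite(population)
  if (sum(population[ok]) <= 0) stop("total population must be positive")
  out <- rep(NA_character_, length(values))
  idx <- which(ok)
  tot <- sum(population[idx])
  lab <- rep("middle", length(idx))
  o_lo <- idx[order(values[idx], idx)]
  in_lo <- o_lo[cumsum(population[o_lo]) <= frac * tot]
  o_hi <- idx[order(-values[idx], -idx)]
  in_hi <- o_hi[cumsum(population[o_hi]) <= frac * tot]
  in_hi <- setdiff(in_hi, in_lo)
  lab[match(in_lo, idx)] <- "lowest"
  lab[match(in_hi, idx)] <- "highest"
  out[idx] <- lab
  out
}
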