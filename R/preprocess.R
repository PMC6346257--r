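#' Fit regional seasonal models to WHZ microdata
#'
#' Wasting is acute and seasonal, so weight-for-height z-scores are adjusted
#' for the interview month before collapsing. Per region, an additive model
#' `WHZ ~ f_per(month) + f_trend(time) + country effect` is fitted with
#' \pkg{mgcv}: `f_per` is a cyclic cubic spline over the 12-month cycle,
#' `f_trend` a smooth over the whole study span, and country effects are
#' shrunk random-effect offsets by default (`country_effect = "fixed"` for
#' unshrunk dummies). The periodic component is centered so it averages to
#' zero over months 1--12.
#'
#' @param records data.frame with columns `whz`, `interview_month`,
#'   `interview_year`, `region_id`, and `country_id`.
#' @param country_effect "random" (ridge-shrunk, default) or "fixed".
#' @return a `seasonal_model`: per-region table of centered monthly effects
#'   plus fit metadata.
#' @export
fit_seasonal_model <- function(records, country_effect = c("random", "fixed")) {
  country_effect <- match.arg(country_effect)
  need <- c("whz", "interview_month", "region_id", "country_id")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "))
  }
  d <- records[is.finite(records$whz) & !is.na(records$interview_month), ]
  if (any(d$interview_month < 1 | d$interview_month > 12 |
          d$interview_month != floor(d$interview_month))) {
    stop("interview_month must be an integer in 1..12")
  }
  d$tt <- d$interview_year + (d$interview_month - 0.5) / 12
  effects <- list(); scales <- list()
  for (rg in sort(unique(d$region_id))) {
    dr <- d[d$region_id == rg, ]
    if (length(unique(dr$interview_month)) < 2) {
      stop("region ", rg, " has a single interview month; skip seasonal adjustment there")
    }
    dr$country <- factor(dr$country_id)
    k_per <- min(8, length(unique(dr$interview_month)) + 1)
    terms <- "s(interview_month, bs = 'cc', k = k_per)"
    if (length(unique(dr$tt)) >= 5) {
      terms <- c(terms, "s(tt, k = 5)")
    } else if (length(unique(dr$tt)) >= 2) {
      terms <- c(terms, "tt")
    }
    if (nlevels(dr$country) > 1) {
      terms <- c(terms, if (country_effect == "random") "s(country, bs = 're')"
                 else "country")
    }
    fml <- stats::as.formula(paste("whz ~", paste(terms, collapse = " + ")))
    fit <- mgcv::gam(fml, data = dr,
                     knots = list(interview_month = c(0.5, 12.5)))
    nd <- dr[rep(1L, 12), , drop = FALSE]
    nd$interview_month <- 1:12
    tm <- stats::predict(fit, newdata = nd, type = "terms")
    percol <- grep("interview_month", colnames(tm))
    f_per <- if (length(percol)) as.numeric(tm[, percol[1]]) else rep(0, 12)
    f_per <- f_per - mean(f_per)
    effects[[as.character(rg)]] <- data.frame(region_id = rg, month = 1:12,
                                              f_per = f_per)
    scales[[as.character(rg)]] <- stats::sd(stats::residuals(fit))
  }
  structure(list(effects = do.call(rbind, effects),
                 fitted_scale = unlist(scales),
                 country_effect = country_effect),
            class = "seasonal_model")
}

#' Amplitude of the fitted periodic component
#'
#' Half the peak-to-trough range of the centered monthly effect, in z-score
#' units, per region.
#'
#' @param model a `seasonal_model`.
#' @return named numeric vector (one amplitude per region).
#' @export
seasonal_amplitude <- function(model) {
  stopifnot(inherits(model, "seasonal_model"))
  vapply(split(model$effects, model$effects$region_id),
         function(e) (max(e$f_per) - min(e$f_per)) / 2, numeric(1))
}

#' Remove the seasonal component from WHZ records
#'
#' Subtracts only the periodic (monthly) effect of the record's region, so
#' every measurement is consistent with a mean day of the seasonal cycle;
#' the long-term trend and country effects are untouched. Records without an
#' interview month cannot be adjusted and are dropped.
#'
#' @param records data.frame with `whz`, `interview_month`, `region_id`.
#' @param model a `seasonal_model` covering every region present.
#' @return the records with `whz` adjusted (and a `whz_raw` copy).
#' @export
adjust_seasonality <- function(records, model) {
  stopifnot(inherits(model, "seasonal_model"))
  d <- records[!is.na(records$interview_month), , drop = FALSE]
  miss <- setdiff(unique(d$region_id), unique(model$effects$region_id))
  if (length(miss)) stop("no seasonal model for region(s): ",
                         paste(miss, collapse = ", "))
  key <- paste(model$effects$region_id, model$effects$month)
  f <- model$effects$f_per[match(paste(d$region_id, d$interview_month), key)]
  d$whz_raw <- d$whz
  d$whz <- d$whz - f
  d
}

#' Resample a polygon observation to weighted pseudo-points
#'
#' Areal survey observations carry no exact coordinates. Each polygon
#' observation is resampled to `n_samples` locations drawn
#' population-proportionally from the polygon's pixels (uniformly jittered
#' within a pixel), reduced to `k` k-means centroids, and the centroids
#' become pseudo-observations that inherit the parent's `N` and `C`. The
#' weight of centroid j is the fraction of sampled locations in its cluster,
#' so weights sum to 1 per parent and one polygon contributes exactly one
#' observation's worth of likelihood.
#'
#' @param obs `cluster_obs` rows with a `polygon_id` (admin2 reference).
#' @param grid a `pixel_grid`.
#' @param n_samples sampled locations per observation (default 10000).
#' @param k number of centroids; default `min(10, populated pixels)`.
#' @param seed integer seed.
#' @return a `cluster_obs` data.frame of pseudo-observations with a
#'   `parent_obs_id` column.
#' @export
resample_polygon_obs <- function(obs, grid, n_samples = 10000, k = NULL,
                                 seed = 1L) {
  stopifnot(inherits(grid, "pixel_grid"))
  poly <- obs[!is.na(obs$polygon_id), , drop = FALSE]
  if (!nrow(poly)) return(as_cluster_obs(empty_cluster_obs()))
  if (!is.null(k) && k > n_samples) stop("k must not exceed n_samples")
  out <- with_seed(child_seed(seed, "resample"), {
    rows <- list()
    for (i in seq_len(nrow(poly))) {
      ob <- poly[i, ]
      t <- match(ob$year, grid$years)
      if (is.na(t)) stop("observation year not in grid years")
      px <- which(grid$admin2_id == ob$polygon_id & !grid$mask)
      pop <- grid$population[px, t]
      px <- px[pop > 0]; pop <- pop[pop > 0]
      if (!length(px)) stop("polygon ", ob$polygon_id,
                            " has no populated unmasked pixels")
      ki <- k %||% min(10L, length(px))
      sel <- px[sample.int(length(px), n_samples, replace = TRUE, prob = pop)]
      pts <- grid$coords[sel, , drop = FALSE] +
        matrix(stats::runif(2 * n_samples, -0.5, 0.5) * grid$pixel_size,
               ncol = 2)
      cl <- cluster_points(pts, ki)
      rows[[i]] <- data.frame(
        parent_obs_id = ob$cluster_id, cluster_id = ob$cluster_id,
        indicator = ob$indicator, x = cl$centers[, 1], y = cl$centers[, 2],
        polygon_id = NA_integer_, year = ob$year, month = ob$month,
        N = ob$N, C = ob$C, weight = ob$weight * cl$size / n_samples)
    }
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  as_cluster_obs(out)
}

## k-means reduction with the degenerate cases handled explicitly
cluster_points <- function(pts, k) {
  if (k == 1) {
    return(list(centers = matrix(colMeans(pts), 1), size = nrow(pts)))
  }
  uq <- unique(pts)
  if (nrow(uq) <= k) {
    key <- paste(pts[, 1], pts[, 2])
    ukey <- paste(uq[, 1], uq[, 2])
    size <- as.numeric(table(factor(key, levels = ukey)))
    return(list(centers = uq, size = size))
  }
  km <- stats::kmeans(pts, centers = k, iter.max = 100, nstart = 2,
                      algorithm = "Lloyd")
  list(centers = km$centers, size = km$size)
}
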