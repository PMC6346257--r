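#' LMS z-score
#'
#' Maps a skewed anthropometric measurement to a Gaussian z-score using the
#' LMS method: `z = ((x/M)^L - 1) / (L * S)`, with the limiting form
#' `log(x/M) / S` used when `|L| < 1e-8` so the function is continuous in
#' the skewness power at zero.
#'
#' @param x measurement (height in cm or weight in kg), > 0. Vectorized;
#'   `L`, `M`, `S` recycle against `x`.
#' @param L skewness power (lambda).
#' @param M median of the reference distribution (mu), > 0.
#' @param S coefficient of variation (sigma), > 0.
#' @return z-scores, finite reals.
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(x <= 0) || any(M <= 0) || any(S <= 0)) {
    stop("x, M and S must all be positive")
  }
  r <- x / M
  small <- abs(L) < 1e-8
  z <- numeric(length(r))
  Lr <- rep_len(L, length(r)); Sr <- rep_len(S, length(r))
  z[small] <- log(r[small]) / Sr[small]
  z[!small] <- (r[!small]^Lr[!small] - 1) / (Lr[!small] * Sr[!small])
  z
}

## inverse LMS: the measurement whose z-score is z (used by the synthetic
## microdata generator and by the round-trip property test)
lms_inverse <- function(z, L, M, S) {
  small <- abs(L) < 1e-8
  out <- numeric(length(z))
  Lr <- rep_len(L, length(z)); Mr <- rep_len(M, length(z))
  Sr <- rep_len(S, length(z))
  out[small] <- Mr[small] * exp(z[small] * Sr[small])
  b <- 1 + Lr[!small] * Sr[!small] * z[!small]
  if (any(b <= 0)) stop("z outside the support of the LMS distribution")
  out[!small] <- Mr[!small] * b^(1 / Lr[!small])
  out
}

#' Classify growth failure from a z-score
#'
#' A child counts as afflicted when the z-score is strictly below the
#' threshold (default -2, i.e. more than two standard deviations below the
#' reference median). Ties at the threshold are not afflicted.
#'
#' @param z z-score(s), finite.
#' @param threshold cut-off (default -2).
#' @return logical vector.
#' @export
classify_cgf <- function(z, threshold = -2) {
  if (any(!is.finite(z))) stop("z must be finite")
  z < threshold
}

#' Synthetic LMS reference tables
#'
#' Smooth, biologically plausible (but synthetic) LMS reference tables for
#' HAZ and WAZ (indexed by completed age in months, 0--59) and WHZ (indexed
#' by height band in cm, 45--120). These are NOT the WHO 2006 reference
#' values; they exist so the pipeline is runnable end-to-end without
#' licensed tables. Externally supplied tables in the same layout can be
#' loaded with [read_lms_table()].
#'
#' @param indicator one of "HAZ", "WHZ", "WAZ".
#' @return an `lms_table` data.frame with columns
#'   `indicator`, `sex`, `index`, `L`, `M`, `S`.
#' @export
synthetic_lms_table <- function(indicator = c("HAZ", "WHZ", "WAZ")) {
  indicator <- match.arg(indicator)
  tab <- switch(indicator,
    HAZ = {
      age <- 0:59
      do.call(rbind, lapply(c("male", "female"), function(sx) {
        off <- if (sx == "male") 0.7 else 0
        data.frame(indicator = "HAZ", sex = sx, index = age, L = 1,
                   M = 49.5 + off + 6.8 * age^0.62,
                   S = 0.036 + 0.00022 * age)
      }))
    },
    WAZ = {
      age <- 0:59
      do.call(rbind, lapply(c("male", "female"), function(sx) {
        off <- if (sx == "male") 0.15 else 0
        data.frame(indicator = "WAZ", sex = sx, index = age, L = 0.25,
                   M = 3.3 + off + 1.55 * age^0.72,
                   S = 0.125 - 0.0003 * age)
      }))
    },
    WHZ = {
      ht <- 45:120
      do.call(rbind, lapply(c("male", "female"), function(sx) {
        off <- if (sx == "male") 0.1 else 0
        data.frame(indicator = "WHZ", sex = sx, index = ht, L = -0.35,
                   M = 2.4 + off + 0.105 * (ht - 45)^1.28,
                   S = 0.085)
      }))
    })
  rownames(tab) <- NULL
  class(tab) <- c("lms_table", "data.frame")
  validate_lms_table(tab)
}

validate_lms_table <- function(tab) {
  need <- c("indicator", "sex", "index", "L", "M", "S")
  if (!all(need %in% names(tab))) {
    stop("LMS table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$M <= 0) || any(tab$S <= 0)) stop("LMS table requires M > 0 and S > 0")
  ## contiguous index coverage within each (indicator, sex) stratum
  by(tab, list(tab$indicator, tab$sex), function(d) {
    ix <- sort(unique(d$index))
    if (length(ix) > 1 && any(diff(ix) != 1)) {
      stop("LMS index coverage must be contiguous")
    }
  })
  class(tab) <- unique(c("lms_table", class(tab)))
  tab
}

#' Read an LMS reference table from CSV
#'
#' Expects columns `indicator`, `sex`, `index`, `L`, `M`, `S` (one row per
#' stratum); `index` is age in months for HAZ/WAZ and height band (cm) for
#' WHZ.
#'
#' @param path CSV path.
#' @return an `lms_table` data.frame.
#' @export
read_lms_table <- function(path) {
  validate_lms_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

## look up (L, M, S) rows for (indicator, sex, index) triples; errors name
## the missing stratum
lms_lookup <- function(tab, indicator, sex, index) {
  sub <- tab[tab$indicator == indicator, ]
  key <- paste(sub$sex, sub$index)
  i <- match(paste(sex, index), key)
  if (anyNA(i)) {
    miss <- unique(paste(indicator, sex, index)[is.na(i)])
    stop("no LMS entry for stratum: ", paste(utils::head(miss, 3), collapse = "; "))
  }
  sub[i, c("L", "M", "S")]
}

## measurement for a child with z-score z in the given stratum
lms_measurement <- function(z, indicator, sex, index, tab = NULL) {
  tab <- tab %||% synthetic_lms_table(indicator)
  p <- lms_lookup(tab, indicator, sex, index)
  lms_inverse(z, p$L, p$M, p$S)
}

#' Apply record-level exclusion rules
#'
#' Drops child records with missing sex, missing or out-of-range age
#' (outside 0--59 completed months), or nonpositive measurements, and drops
#' polygon survey clusters whose sample size is one. Optionally flags
#' biologically implausible z-scores (off by default). Idempotent; returns
#' the exclusion counts alongside the cleaned records.
#'
#' @param records ChildRecord data.frame (columns `cluster_id`, `sex`,
#'   `age`, `height`/`weight`, `interview_year`, `interview_month`).
#' @param cluster_meta optional data.frame with `cluster_id`, `polygon_id`
#'   and `N` identifying polygon clusters (for the sample-size-one rule).
#' @param flag_z if non-`NULL`, a positive number: records whose available
#'   z-scores (computed with `lms` and `indicator`) exceed this absolute
#'   value are dropped. Default `NULL` (rule off).
#' @param lms,indicator only used when `flag_z` is set.
#' @return list with `records` (cleaned) and `log` (data.frame of counts
#'   per rule).
#' @export
apply_exclusions <- function(records, cluster_meta = NULL, flag_z = NULL,
                             lms = NULL, indicator = NULL) {
  n0 <- nrow(records)
  log <- c(missing_sex = 0L, missing_age = 0L, nonpositive_measure = 0L,
           polygon_n1 = 0L, implausible_z = 0L)
  keep <- rep(TRUE, n0)

  bad_sex <- is.na(records$sex) | !(records$sex %in% c("male", "female"))
  log["missing_sex"] <- sum(keep & bad_sex); keep <- keep & !bad_sex
  bad_age <- is.na(records$age) | records$age < 0 | records$age > 59 |
    records$age != floor(records$age)
  log["missing_age"] <- sum(keep & bad_age); keep <- keep & !bad_age
  meas <- pmin(records$height, records$weight, na.rm = TRUE)
  bad_meas <- !is.finite(meas) | meas <= 0
  log["nonpositive_measure"] <- sum(keep & bad_meas); keep <- keep & !bad_meas

  if (!is.null(cluster_meta)) {
    poly1 <- cluster_meta$cluster_id[!is.na(cluster_meta$polygon_id) &
                                       cluster_meta$N == 1]
    bad_poly <- records$cluster_id %in% poly1
    log["polygon_n1"] <- sum(keep & bad_poly); keep <- keep & !bad_poly
  }
  if (!is.null(flag_z)) {
    stopifnot(flag_z > 0, !is.null(lms), !is.null(indicator))
    z <- rep(NA_real_, n0)
    z[keep] <- child_zscores(records[keep, ], lms, indicator)
    bad_z <- keep & is.finite(z) & abs(z) > flag_z
    log["implausible_z"] <- sum(bad_z); keep <- keep & !bad_z
  }
  list(records = records[keep, , drop = FALSE],
       log = data.frame(rule = names(log), n_excluded = as.integer(log)))
}

## z-scores for child records under one indicator
child_zscores <- function(records, lms, indicator) {
  if (indicator == "HAZ") {
    x <- records$height; index <- records$age
  } else if (indicator == "WAZ") {
    x <- records$weight; index <- records$age
  } else if (indicator == "WHZ") {
    x <- records$weight
    index <- pmin(pmax(round(records$height), min(lms$index)), max(lms$index))
  } else stop("indicator must be one of HAZ, WHZ, WAZ")
  ok <- is.finite(x) & x > 0
  z <- rep(NA_real_, nrow(records))
  if (any(ok)) {
    p <- lms_lookup(lms, indicator, records$sex[ok], index[ok])
    z[ok] <- lms_zscore(x[ok], p$L, p$M, p$S)
  }
  z
}

#' Collapse child microdata to cluster-level binomial observations
#'
#' Computes the indicator z-score for every scoreable child and per cluster
#' counts `N` (scoreable children) and `C` (children with `z < threshold`,
#' strict). The cluster month is the modal interview month. Clusters with no
#' scoreable children are omitted.
#'
#' @param records ChildRecord data.frame (post-exclusion).
#' @param lms an `lms_table` covering every (sex, index) stratum present.
#' @param indicator "HAZ", "WHZ" or "WAZ" (aliases "stunting", "wasting",
#'   "underweight" accepted).
#' @param cluster_meta optional data.frame with `cluster_id` plus location
#'   columns (`x`, `y`, `polygon_id`, `year`, `weight`) merged onto the
#'   output.
#' @param threshold z-score cut-off (default -2).
#' @return a `cluster_obs` data.frame.
#' @export
collapse_to_cluster <- function(records, lms, indicator, cluster_meta = NULL,
                                threshold = -2) {
  zmap <- c(stunting = "HAZ", wasting = "WHZ", underweight = "WAZ")
  zind <- if (indicator %in% names(zmap)) zmap[[indicator]] else indicator
  z <- child_zscores(records, lms, zind)
  ok <- is.finite(z)
  if (!any(ok)) return(as_cluster_obs(empty_cluster_obs()))
  d <- data.frame(cluster_id = records$cluster_id[ok], z = z[ok],
                  month = records$interview_month[ok],
                  year = records$interview_year[ok])
  agg <- do.call(rbind, lapply(split(d, d$cluster_id), function(g) {
    data.frame(cluster_id = g$cluster_id[1],
               year = as.integer(stats::median(g$year)),
               month = modal_month(g$month),
               N = nrow(g), C = sum(g$z < threshold))
  }))
  rownames(agg) <- NULL
  agg$indicator <- indicator
  if (!is.null(cluster_meta)) {
    loc <- cluster_meta[, intersect(c("cluster_id", "x", "y", "polygon_id",
                                      "weight"), names(cluster_meta))]
    agg <- merge(agg, loc, by = "cluster_id", all.x = TRUE, sort = TRUE)
  }
  ## [[ ]] for exact matching: $y would partially match "year"
  if (is.null(agg[["x"]])) agg$x <- NA_real_
  if (is.null(agg[["y"]])) agg$y <- NA_real_
  if (is.null(agg[["polygon_id"]])) agg$polygon_id <- NA_integer_
  if (is.null(agg[["weight"]])) agg$weight <- 1
  as_cluster_obs(agg[, c("cluster_id", "indicator", "x", "y", "polygon_id",
                         "year", "month", "N", "C", "weight")],
                 require_geometry = !is.null(cluster_meta))
}

modal_month <- function(m) {
  m <- m[!is.na(m)]
  if (!length(m)) return(NA_integer_)
  tb <- table(m)
  as.integer(names(tb)[which.max(tb)])
}

empty_cluster_obs <- function() {
  data.frame(cluster_id = integer(), indicator = character(),
             x = numeric(), y = numeric(), polygon_id = integer(),
             year = integer(), month = integer(), N = integer(),
             C = integer(), weight = numeric())
}

#' Validate and class a cluster observation table
#'
#' A cluster observation is one survey cluster collapsed to a binomial count:
#' `C` afflicted of `N` measured children, located either by point
#' coordinates (`x`, `y`) or by an admin polygon reference (`polygon_id`),
#' never both, with a likelihood weight (1 for real observations, fractional
#' for pseudo-observations).
#'
#' @param df data.frame with the `cluster_obs` columns.
#' @param require_geometry if `TRUE` (default), every row must carry exactly
#'   one of point coordinates or a polygon reference; `FALSE` additionally
#'   allows rows with neither (e.g. collapsed microdata awaiting geocoding).
#' @return the validated data.frame with class `cluster_obs`.
#' @export
as_cluster_obs <- function(df, require_geometry = TRUE) {
  need <- c("cluster_id", "year", "N", "C", "weight")
  if (!all(need %in% names(df))) {
    stop("cluster_obs needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df[["x"]])) df$x <- NA_real_
  if (is.null(df[["y"]])) df$y <- NA_real_
  if (is.null(df[["polygon_id"]])) df$polygon_id <- NA_integer_
  if (is.null(df[["month"]])) df$month <- NA_integer_
  if (is.null(df[["indicator"]])) df$indicator <- NA_character_
  if (nrow(df)) {
    if (any(df$N < 1)) stop("cluster_obs requires N >= 1")
    if (any(df$C < 0 | df$C > df$N)) stop("cluster_obs requires 0 <= C <= N")
    has_pt <- is.finite(df$x) & is.finite(df$y)
    has_poly <- !is.na(df$polygon_id)
    if (any(has_pt & has_poly)) {
      stop("each observation must have exactly one of point coordinates or a polygon reference")
    }
    if (require_geometry && any(!has_pt & !has_poly)) {
      stop("each observation must have exactly one of point coordinates or a polygon reference")
    }
    if (any(df$weight <= 0)) stop("weights must be positive")
  }
  class(df) <- unique(c("cluster_obs", class(df)))
  df
}
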