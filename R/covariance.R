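#' Matern covariance function
#'
#' Isotropic stationary Matern covariance under the sqrt(8 nu) range
#' convention: `C(d) = sigma2 * 2^(1-nu)/Gamma(nu) * (kappa d)^nu *
#' K_nu(kappa d)` with `kappa = sqrt(8 nu) / range`, so `C(0) = sigma2` and
#' the correlation at `d = range` is about 0.14 for any smoothness. At
#' `nu = 1/2` this reduces to the exponential kernel
#' `sigma2 * exp(-2 d / range)`.
#'
#' @param d distances (>= 0), any shape.
#' @param sigma2 marginal variance (>= 0).
#' @param range distance at which correlation has dropped to ~0.14 (> 0).
#' @param nu smoothness (> 0); default 1 matches the common SPDE alpha = 2
#'   convention in two dimensions.
#' @return covariances, same shape as `d`.
#' @export
matern_cov <- function(d, sigma2 = 1, range = 1, nu = 1) {
  if (range <= 0) stop("range must be positive")
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  if (nu <= 0) stop("nu must be positive")
  if (any(d < 0)) stop("distances must be nonnegative")
  kd <- sqrt(8 * nu) * d / range
  out <- d
  zero <- kd < 1e-12
  out[zero] <- sigma2
  if (any(!zero)) {
    x <- kd[!zero]
    out[!zero] <- sigma2 * (2^(1 - nu) / gamma(nu)) * x^nu *
      besselK(x, nu)
  }
  out
}

## Matern covariance matrix over planar coordinates (Euclidean distances)
matern_cov_matrix <- function(coords, sigma2, range, nu = 1, D = NULL) {
  if (is.null(D)) D <- as.matrix(stats::dist(coords))
  matern_cov(D, sigma2, range, nu)
}

#' AR1 correlation matrix over years
#'
#' Entry (s, t) is `rho^|s - t|` in year units.
#'
#' @param years integer vector of years.
#' @param rho autocorrelation, strictly inside (-1, 1).
#' @return a correlation matrix.
#' @export
ar1_corr <- function(years, rho) {
  if (abs(rho) >= 1) stop("rho must be strictly inside (-1, 1)")
  outer(years, years, function(a, b) rho^abs(a - b))
}

#' Space-time covariance over pixel-years
#'
#' The separable Kronecker covariance of the residual Gaussian process:
#' AR1 correlation over years crossed with Matern covariance over pixels,
#' in year-major ordering (index = (year - 1) * P + pixel). Intended for
#' small instances (exact simulation, the MCMC backend, tests); refuses more
#' than 20,000 pixel-years unless `force = TRUE`.
#'
#' @param coords P x 2 pixel center coordinates.
#' @param years integer years.
#' @param gp a [gp_hyperparams()] (nugget not included).
#' @param force override the size guard.
#' @return a dense symmetric PSD matrix of dimension `P * length(years)`.
#' @export
st_covariance <- function(coords, years, gp, force = FALSE) {
  coords <- rbind(coords)
  P <- nrow(coords); Tn <- length(years)
  if (P < 1 || Tn < 1) stop("need at least one pixel and one year")
  if (P * Tn > 20000 && !force) {
    stop("refusing to build a dense covariance over ", P * Tn,
         " pixel-years; pass force = TRUE to override")
  }
  A <- ar1_corr(years, gp$ar1_rho)
  S <- matern_cov_matrix(coords, gp$spatial_var, gp$spatial_range,
                         gp$matern_smoothness)
  kronecker(A, S)
}

#' Gaussian-process hyperparameters
#'
#' Container for the residual field hyperparameters: Matern range,
#' marginal variance and smoothness in space, AR1 correlation in time, and
#' the observation-level nugget variance. Defaults are the synthetic study
#' conditions used throughout the package's validation suite.
#'
#' @param spatial_range Matern range in pixel units.
#' @param spatial_var logit-scale marginal variance of the field.
#' @param matern_smoothness Matern nu.
#' @param ar1_rho annual autocorrelation in (-1, 1).
#' @param nugget_var independent per-observation logit-scale variance.
#' @return a `gp_hyperparams` list.
#' @export
gp_hyperparams <- function(spatial_range = 6, spatial_var = 0.5,
                           matern_smoothness = 1, ar1_rho = 0.8,
                           nugget_var = 0.1) {
  if (spatial_range <= 0) stop("spatial_range must be positive")
  if (spatial_var < 0 || nugget_var < 0) stop("variances must be nonnegative")
  if (abs(ar1_rho) >= 1) stop("ar1_rho must be strictly inside (-1, 1)")
  if (matern_smoothness <= 0) stop("matern_smoothness must be positive")
  structure(list(spatial_range = spatial_range, spatial_var = spatial_var,
                 matern_smoothness = matern_smoothness, ar1_rho = ar1_rho,
                 nugget_var = nugget_var), class = "gp_hyperparams")
}
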