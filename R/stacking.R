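#' Fit the three child learners and build stacked features
#'
#' Stacked generalization: three learners — a penalized spline additive
#' binomial smoother (\pkg{mgcv}), boosted regression trees with logistic
#' loss (\pkg{xgboost}, depth <= 3), and L1-penalized logistic regression
#' with internally cross-validated penalty (\pkg{glmnet}) — are each fitted
#' to the cluster counts with the raw covariates as predictors. Out-of-sample
#' predictions assembled across `n_folds` random folds become the
#' observation-level features the geostatistical model weights on the
#' simplex; fits on 100% of the data supply the in-sample pixel features
#' used at prediction time. All features are stored on the logit scale
#' (clipped at +-12) and never centre-scaled. Observation weights enter
#' every learner as case weights (weight x sample size for the smoother and
#' the trees; the count response plus weight for the lasso).
#'
#' When the grid has several regions and `by_region = TRUE`, learners are
#' fitted independently per region (shared hyperparameters) and pixel
#' features are assembled region by region.
#'
#' @param obs point `cluster_obs` (resample polygons first).
#' @param covariates a `covariate_stack` on the same grid.
#' @param grid a `pixel_grid`.
#' @param n_folds folds for the out-of-sample predictions (default 5).
#' @param seed integer seed (folds, tree fitting, lasso CV).
#' @param by_region fit per region when the grid has more than one.
#' @param control list: `xgb_nrounds` (150), `xgb_depth` (3), `xgb_eta`
#'   (0.1), `gam_k` (5).
#' @return a `stacked_features` object: `obs_features` (n x 3, logit,
#'   out-of-sample), `pixel_features` (P x T x 3, in-sample),
#'   `learner_names`, `fold_assignment`, `years`, and the full-data `fits`.
#' @export
fit_child_learners <- function(obs, covariates, grid, n_folds = 5, seed = 1L,
                               by_region = TRUE, control = list()) {
  stopifnot(inherits(covariates, "covariate_stack"), inherits(grid, "pixel_grid"))
  ctl <- utils::modifyList(list(xgb_nrounds = 150, xgb_depth = 3,
                                xgb_eta = 0.1, gam_k = 5), control)
  if (nrow(obs) < n_folds) stop("need at least n_folds observations")
  if (any(!is.na(obs$polygon_id))) {
    stop("polygon observations present; resample them to pseudo-points first")
  }
  pix <- snap_to_pixel(grid, obs$x, obs$y)
  tix <- match(obs$year, grid$years)
  if (anyNA(tix)) stop("observation years not covered by the covariate stack")
  K <- dim(covariates$values)[3]
  X <- vapply(seq_len(K), function(k) {
    covariates$values[, , k][cbind(pix, tix)]
  }, numeric(nrow(obs)))
  colnames(X) <- covariates$names
  learners <- c("smoother", "boosted_trees", "lasso")

  region <- if (by_region) grid$region_id[pix] else rep(1L, nrow(obs))
  regions <- sort(unique(region))

  n <- nrow(obs)
  folds <- with_seed(child_seed(seed, "folds"), {
    f <- integer(n)
    for (rg in regions) {
      i <- which(region == rg)
      f[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
    f
  })

  obs_features <- matrix(NA_real_, n, 3,
                         dimnames = list(NULL, learners))
  P <- nrow(grid$coords); Tn <- length(grid$years)
  pixel_features <- array(NA_real_, dim = c(P, Tn, 3),
                          dimnames = list(NULL, NULL, learners))
  fits <- list()
  for (rg in regions) {
    ri <- which(region == rg)
    for (f in seq_len(n_folds)) {
      tr <- ri[folds[ri] != f]; te <- ri[folds[ri] == f]
      if (!length(te)) next
      if (!length(tr)) stop("a fold has no training data; reduce n_folds")
      fit_f <- train_learners(X[tr, , drop = FALSE], obs$C[tr], obs$N[tr],
                              obs$weight[tr], ctl, child_seed(seed, paste0("f", rg, "_", f)))
      obs_features[te, ] <- predict_learners(fit_f, X[te, , drop = FALSE])
    }
    full <- train_learners(X[ri, , drop = FALSE], obs$C[ri], obs$N[ri],
                           obs$weight[ri], ctl, child_seed(seed, paste0("full", rg)))
    fits[[as.character(rg)]] <- full
    rpx <- which((if (by_region) grid$region_id else rep(1L, P)) == rg)
    Xpix <- matrix(NA_real_, length(rpx) * Tn, K)
    for (k in seq_len(K)) Xpix[, k] <- as.vector(covariates$values[rpx, , k])
    colnames(Xpix) <- covariates$names
    pf <- predict_learners(full, Xpix)
    for (l in 1:3) pixel_features[rpx, , l] <- matrix(pf[, l], length(rpx), Tn)
  }
  structure(list(obs_features = obs_features, pixel_features = pixel_features,
                 learner_names = learners, fold_assignment = folds,
                 years = grid$years, fits = fits, covariate_names = covariates$names),
            class = "stacked_features")
}

## fit the three learners on one training set; returns a list of fits
train_learners <- function(X, C, N, w, ctl, seed) {
  y <- C / N
  cw <- w * N
  if (all(C == 0) || all(C == N)) {
    warning("degenerate response (all zeros or all ones); learners fall back to a clipped constant")
    const <- clip_logit(logit((sum(C) + 0.5) / (sum(N) + 1)))
    return(list(constant = const))
  }
  with_seed(seed, {
    ## additive penalized-spline binomial smoother
    terms <- vapply(seq_len(ncol(X)), function(k) {
      nm <- colnames(X)[k]
      ku <- length(unique(X[, k]))
      if (ku >= ctl$gam_k + 2) sprintf("s(%s, k = %d)", nm, ctl$gam_k) else nm
    }, character(1))
    d <- data.frame(y = y, X, check.names = FALSE)
    ## proportion response with N-scaled weights; the non-integer-successes
    ## warning is the intended use here
    gam_fit <- quiet_binomial(
      mgcv::gam(stats::as.formula(paste("y ~", paste(terms, collapse = "+"))),
                family = stats::binomial(), weights = cw, data = d,
                select = TRUE))
    ## boosted trees, logistic loss (fractional labels C/N, case weights w*N)
    dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = cw, nthread = 1)
    xgb_fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = ctl$xgb_depth,
                    eta = ctl$xgb_eta, nthread = 1),
      data = dtrain, nrounds = ctl$xgb_nrounds, verbose = 0)
    ## lasso logistic with internally cross-validated penalty
    lasso_fit <- tryCatch(
      glmnet::cv.glmnet(X, cbind(N - C, C), family = "binomial", weights = w,
                        alpha = 1, nfolds = 5),
      error = function(e) NULL)
    list(gam = gam_fit, xgb = xgb_fit, lasso = lasso_fit,
         pooled = clip_logit(logit((sum(C) + 0.5) / (sum(N) + 1))),
         covariate_names = colnames(X))
  })
}

## logit-scale predictions from the three learners, clipped at +-12
predict_learners <- function(fit, X) {
  n <- nrow(X)
  if (!is.null(fit$constant)) {
    return(matrix(fit$constant, n, 3,
                  dimnames = list(NULL, c("smoother", "boosted_trees", "lasso"))))
  }
  miss <- setdiff(fit$covariate_names, colnames(X))
  if (length(miss)) stop("missing covariate layer(s): ", paste(miss, collapse = ", "))
  d <- as.data.frame(X, check.names = FALSE)
  p_gam <- as.numeric(stats::predict(fit$gam, newdata = d, type = "link"))
  p_xgb <- stats::qlogis(pmin(pmax(
    stats::predict(fit$xgb, xgboost::xgb.DMatrix(X, nthread = 1)),
    1e-12), 1 - 1e-12))
  p_lasso <- if (is.null(fit$lasso)) rep(fit$pooled, n) else {
    as.numeric(stats::predict(fit$lasso, X, s = "lambda.min", type = "link"))
  }
  out <- cbind(smoother = p_gam, boosted_trees = p_xgb, lasso = p_lasso)
  clip_logit(out)
}

#' In-sample pixel features from fitted learners
#'
#' Predicts each full-data learner over every pixel-year of the covariate
#' stack, on the logit scale (clipped at +-12). Normally called through
#' [fit_child_learners()], which stores the result; exposed for refreshing
#' features on a new covariate stack (e.g. additional years).
#'
#' @param fits the `fits` element of a `stacked_features` object (one fit
#'   set per region), or a single fit set.
#' @param covariates a `covariate_stack`.
#' @param grid the `pixel_grid` (for region assignment).
#' @return a P x T x 3 array of logit-scale predictions.
#' @export
predict_pixel_features <- function(fits, covariates, grid) {
  stopifnot(inherits(covariates, "covariate_stack"))
  P <- nrow(grid$coords); Tn <- length(covariates$years)
  K <- dim(covariates$values)[3]
  if (!is.null(fits$covariate_names) || !is.null(fits$constant)) {
    fits <- list(`1` = fits)
  }
  out <- array(NA_real_, dim = c(P, Tn, 3),
               dimnames = list(NULL, NULL, c("smoother", "boosted_trees", "lasso")))
  for (rg in names(fits)) {
    rpx <- if (length(fits) == 1) seq_len(P) else which(grid$region_id == as.integer(rg))
    Xpix <- matrix(NA_real_, length(rpx) * Tn, K)
    for (k in seq_len(K)) Xpix[, k] <- as.vector(covariates$values[rpx, , k])
    colnames(Xpix) <- covariates$names
    pf <- predict_learners(fits[[rg]], Xpix)
    for (l in 1:3) out[rpx, , l] <- matrix(pf[, l], length(rpx), Tn)
  }
  if (any(!is.finite(out))) stop("pixel features contain non-finite values")
  out
}
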