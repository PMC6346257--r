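#' Logit and inverse-logit
#'
#' Logit transforms with epsilon-clipping at the boundaries. All latent-scale
#' quantities in the package live on the logit scale; `eps` guards prevalences
#' of exactly 0 or 1 (e.g. empirical proportions) before transformation.
#'
#' @param p probabilities in \[0, 1\].
#' @param x real values.
#' @param eps clip `p` into `[eps, 1 - eps]` before transforming.
#' @return `logit` returns real values; `invlogit` returns values in (0, 1).
#' @export
logit <- function(p, eps = 1e-6) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' @rdname logit
#' @export
invlogit <- function(x) 1 / (1 + exp(-x))

## clip a logit-scale value into +-bound (used before storing learner
## predictions and before inverting to prevalence)
clip_logit <- function(x, bound = 12) pmin(pmax(x, -bound), bound)

`%||%` <- function(a, b) if (is.null(a)) b else a

## weighted mean that tolerates all-zero weights by erroring loudly
wmean <- function(x, w) {
  sw <- sum(w)
  if (!is.finite(sw) || sw <= 0) stop("weights must sum to a positive number")
  sum(x * w) / sw
}

## derive a reproducible child seed from a parent seed and a stream label;
## kept below 2^31 so it is a valid R integer seed
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

## evaluate `expr` under a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## silence only the "non-integer #successes" warning that proportion+weights
## binomial fits legitimately raise
quiet_binomial <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("non-integer", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
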