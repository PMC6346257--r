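## small shared fixtures, built once per test session
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

## an 8x8, 2-country world with 17 years (2000-2016)
tiny_world <- function() {
  memo("tiny_world", make_world(world_config(
    n_rows = 8, n_cols = 8, years = 2000:2016, country_rows = 1,
    country_cols = 2, admin1_rows = 2, admin1_cols = 1,
    admin2_rows = 2, admin2_cols = 2, pop_mean = 40),
    seed = 42))
}

## deterministic point-observation table on a given grid
manual_point_obs <- function(grid, pix, year, N, C, weight = 1,
                             indicator = "stunting") {
  as_cluster_obs(data.frame(
    cluster_id = seq_along(pix), indicator = indicator,
    x = grid$coords[pix, 1], y = grid$coords[pix, 2],
    polygon_id = NA_integer_, year = year, month = 6L,
    N = N, C = C, weight = weight))
}

## a bare posterior cube from explicit prevalence draws
manual_cube <- function(prev, years, indicator = "stunting", raked = FALSE) {
  structure(list(prevalence = prev, indicator = indicator, raked = raked,
                 years = years, n_draws = dim(prev)[1], clip_count = 0L),
            class = "posterior_cube")
}

## dense multivariate-normal log density (independent oracle implementation)
mvn_loglik <- function(y, C) {
  as.numeric(-0.5 * determinant(C, logarithm = TRUE)$modulus -
               0.5 * t(y) %*% solve(C, y) - length(y) / 2 * log(2 * pi))
}
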