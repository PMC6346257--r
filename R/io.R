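#' Write a pixel layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a 6-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of values from the top
#' row down, readable by GDAL, terra and QGIS. Coordinates are the package's
#' abstract pixel units.
#'
#' @param values numeric vector, one value per pixel (grid order).
#' @param grid the `pixel_grid`.
#' @param path output path (conventionally `.asc`).
#' @param nodata sentinel written for `NA` (default -9999).
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(length(values) == nrow(grid$coords))
  m <- matrix(values, grid$n_rows, grid$n_cols, byrow = TRUE)
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           "xllcorner 0", "yllcorner 0",
           sprintf("cellsize %g", grid$pixel_size),
           sprintf("NODATA_value %g", nodata))
  ## .asc rows run north to south: top row first
  body <- apply(m[grid$n_rows:1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` path.
#' @return list with `values` (matrix, row 1 = southernmost), `cellsize`,
#'   `nodata` (converted to `NA`).
#' @export
read_ascii_grid <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(trimws(ln[1:6]), "\\s+")
  hv <- stats::setNames(vapply(hdr, function(x) as.numeric(x[2]), numeric(1)),
                        tolower(vapply(hdr, `[`, character(1), 1)))
  body <- do.call(rbind, lapply(ln[-(1:6)], function(s) {
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  }))
  body[body == hv[["nodata_value"]]] <- NA_real_
  list(values = body[nrow(body):1, , drop = FALSE],
       cellsize = hv[["cellsize"]], nodata = hv[["nodata_value"]])
}

#' Write admin boundaries as GeoJSON
#'
#' Emits one rectangle-union polygon feature per admin unit (units are
#' unions of pixel blocks, so boundaries are the bounding outline of the
#' unit's pixels; exact for the default rectangular partitions). Coordinates
#' are pixel units.
#'
#' @param grid the `pixel_grid`.
#' @param level "country", "admin1", "admin2" or "region".
#' @param path output `.geojson` path.
#' @export
write_boundaries_geojson <- function(grid, level, path) {
  ids <- switch(level, country = grid$country_id, admin1 = grid$admin1_id,
                admin2 = grid$admin2_id, region = grid$region_id,
                stop("unknown level: ", level))
  feats <- lapply(sort(unique(ids)), function(u) {
    sel <- ids == u
    x0 <- min(grid$coords[sel, 1]) - 0.5; x1 <- max(grid$coords[sel, 1]) + 0.5
    y0 <- min(grid$coords[sel, 2]) - 0.5; y1 <- max(grid$coords[sel, 2]) + 0.5
    list(type = "Feature",
         properties = list(level = level, unit_id = u),
         geometry = list(type = "Polygon",
                         coordinates = list(list(c(x0, y0), c(x1, y0),
                                                 c(x1, y1), c(x0, y1),
                                                 c(x0, y0)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the synthetic world to disk
#'
#' Rasters (population per year, covariates per year, id layers, mask) as
#' ESRI ASCII grids, boundaries as GeoJSON, and the configuration as YAML.
#'
#' @param world list with `grid` and `covariates` from [make_world()].
#' @param dir output directory (created).
#' @return invisible vector of written paths.
#' @export
write_world <- function(world, dir) {
  grid <- world$grid; covs <- world$covariates
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(v, nm) {
    p <- file.path(dir, nm)
    write_ascii_grid(v, grid, p)
    paths <<- c(paths, p)
  }
  for (nm in c("country_id", "admin1_id", "admin2_id", "region_id")) {
    wr(grid[[nm]], paste0(nm, ".asc"))
  }
  wr(as.numeric(grid$mask), "mask.asc")
  for (t in seq_along(grid$years)) {
    wr(grid$population[, t], sprintf("population_%d.asc", grid$years[t]))
    for (k in seq_along(covs$names)) {
      wr(covs$values[, t, k], sprintf("%s_%d.asc", covs$names[k], grid$years[t]))
    }
  }
  for (lv in c("country", "admin1", "admin2")) {
    p <- file.path(dir, paste0(lv, ".geojson"))
    write_boundaries_geojson(grid, lv, p)
    paths <- c(paths, p)
  }
  yaml::write_yaml(unclass(grid$config), file.path(dir, "world_config.yaml"))
  paths <- c(paths, file.path(dir, "world_config.yaml"))
  invisible(paths)
}
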