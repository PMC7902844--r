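#' Define a regular geographic grid
#'
#' Cell-center registered latitude/longitude grid. Latitude rows run
#' ascending south to north; longitude columns ascending within
#' \[-180, 180). The span in each direction must be an integer multiple of
#' the resolution.
#'
#' @param lat_min,lat_max,lon_min,lon_max Grid bounds in degrees (cell
#'   edges, not centers).
#' @param resolution Cell size in degrees (default 0.5).
#' @return A `grid_spec` object with cell-center coordinate vectors.
#' @export
grid_spec <- function(lat_min = -90, lat_max = 90, lon_min = -180,
                      lon_max = 180, resolution = 0.5) {
  stopifnot(resolution > 0, lat_min >= -90, lat_max <= 90,
            lat_min < lat_max, lon_min < lon_max)
  nlat <- (lat_max - lat_min) / resolution
  nlon <- (lon_max - lon_min) / resolution
  if (abs(nlat - round(nlat)) > 1e-9 || abs(nlon - round(nlon)) > 1e-9) {
    stop("grid span must be an integer multiple of the resolution")
  }
  nlat <- as.integer(round(nlat)); nlon <- as.integer(round(nlon))
  structure(list(
    lat_min = lat_min, lat_max = lat_max,
    lon_min = lon_min, lon_max = lon_max,
    resolution = resolution, nlat = nlat, nlon = nlon,
    lat = lat_min + (seq_len(nlat) - 0.5) * resolution,
    lon = lon_min + (seq_len(nlon) - 0.5) * resolution
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells at %g deg, lat [%g, %g], lon [%g, %g]\n",
              x$nlat, x$nlon, x$resolution, x$lat_min, x$lat_max,
              x$lon_min, x$lon_max))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a[c("lat_min", "lat_max", "lon_min", "lon_max",
                       "resolution")],
                   b[c("lat_min", "lat_max", "lon_min", "lon_max",
                       "resolution")],
                   tolerance = 1e-9))
}

#' Construct a gridded field
#'
#' A raster is a numeric matrix (rows = latitude ascending, columns =
#' longitude) on a [grid_spec()]. Masked (invalid) cells are `NA`; all
#' statistics in the package skip them rather than coercing to zero.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix `nlat x nlon`, or a scalar to fill.
#' @param units Unit string recorded with the field.
#' @param name Variable name.
#' @return A `raster` object.
#' @export
make_raster <- function(grid, values = NA_real_, units = "", name = "field") {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1) {
    values <- matrix(as.numeric(values), grid$nlat, grid$nlon)
  }
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$nlat, grid$nlon))) {
    stop(sprintf("values must be %d x %d to match the grid", grid$nlat,
                 grid$nlon))
  }
  if (any(is.infinite(values))) stop("raster values must be finite or NA")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values, units = units, name = name),
            class = "raster")
}

#' @export
print.raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster '%s' [%s]: %d x %d cells, %d valid, range [%g, %g]\n",
              x$name, x$units, nrow(x$values), ncol(x$values), length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

check_same_grid <- function(...) {
  rs <- list(...)
  g <- rs[[1]]$grid
  for (r in rs[-1]) {
    if (!grids_identical(g, r$grid)) stop("rasters are on different grids")
  }
  g
}

EARTH_RADIUS_KM <- 6371

#' Cell areas of a geographic grid
#'
#' Spherical-cap areas: `R^2 * dlon * (sin(lat_top) - sin(lat_bottom))`
#' with R = 6371 km. Areas depend only on latitude, are symmetric about
#' the equator, and sum to the sphere area `4 pi R^2` over a global grid.
#'
#' @param grid A [grid_spec()].
#' @return A raster of cell areas in km^2.
#' @export
cell_areas <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  res <- grid$resolution
  top <- (grid$lat + res / 2) * pi / 180
  bot <- (grid$lat - res / 2) * pi / 180
  band <- EARTH_RADIUS_KM^2 * (res * pi / 180) * (sin(top) - sin(bot))
  make_raster(grid, matrix(band, grid$nlat, grid$nlon), units = "km2",
              name = "cell_area")
}

#' Area-weighted mean of a field
#'
#' `sum(w * x) / sum(w)` over cells where both the field and the weights
#' are valid. Invariant under uniform rescaling of the weights.
#'
#' @param x,w Rasters on the same grid; `w` must be nonnegative.
#' @return A single number.
#' @export
area_weighted_mean <- function(x, w) {
  check_same_grid(x, w)
  ok <- !is.na(x$values) & !is.na(w$values)
  if (any(w$values[ok] < 0)) stop("weights must be nonnegative")
  sw <- sum(w$values[ok])
  if (!any(ok) || sw <= 0) {
    stop("empty domain: no jointly valid cells with positive weight")
  }
  sum(w$values[ok] * x$values[ok]) / sw
}

#' Latitudinal profile of a weighted field
#'
#' Weighted mean of `x` within latitude bands of the given width. Bands
#' with zero total weight are reported as invalid (`NA`), never as zero.
#'
#' @param x,w Rasters on the same grid.
#' @param band_width Band width in degrees; must divide the latitude span
#'   and be a multiple of the resolution.
#' @return A data.frame with `lat_lo`, `lat_hi`, `lat_mid`, `mean`,
#'   `weight`.
#' @export
latitudinal_profile <- function(x, w, band_width = 1) {
  g <- check_same_grid(x, w)
  nb <- (g$lat_max - g$lat_min) / band_width
  if (abs(nb - round(nb)) > 1e-9) {
    stop("band_width must divide the latitude span")
  }
  nb <- round(nb)
  rows_per_band <- band_width / g$resolution
  if (abs(rows_per_band - round(rows_per_band)) > 1e-9) {
    stop("band_width must be a multiple of the grid resolution")
  }
  rows_per_band <- round(rows_per_band)
  band_of_row <- rep(seq_len(nb), each = rows_per_band)
  out <- data.frame(
    lat_lo = g$lat_min + (seq_len(nb) - 1) * band_width,
    lat_hi = g$lat_min + seq_len(nb) * band_width
  )
  out$lat_mid <- (out$lat_lo + out$lat_hi) / 2
  out$mean <- NA_real_
  out$weight <- 0
  for (b in seq_len(nb)) {
    rows <- which(band_of_row == b)
    xv <- x$values[rows, , drop = FALSE]
    wv <- w$values[rows, , drop = FALSE]
    ok <- !is.na(xv) & !is.na(wv)
    sw <- sum(wv[ok])
    out$weight[b] <- sw
    if (any(ok) && sw > 0) out$mean[b] <- sum(wv[ok] * xv[ok]) / sw
  }
  out
}
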