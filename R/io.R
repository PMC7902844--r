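#' Write a raster to a CF-style NetCDF file
#'
#' One double-precision variable on `lat`/`lon` coordinate variables,
#' cell-center registered, with a `units` attribute and `_FillValue` for
#' masked cells. Values round-trip losslessly at float64 precision.
#'
#' @param x A raster.
#' @param path Output file path (`.nc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  stopifnot(inherits(x, "raster"))
  g <- x$grid
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  fill <- 9.969209968386869e36
  var <- ncdf4::ncvar_def(x$name, x$units, list(dlon, dlat), missval = fill,
                          prec = "double")
  nc <- ncdf4::nc_create(path, list(var))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, var, t(x$values))
  ncdf4::ncatt_put(nc, 0, "resolution_deg", g$resolution, prec = "double")
  invisible(path)
}

#' Read a raster written by [write_raster()]
#'
#' @param path NetCDF file path.
#' @param grid Optional [grid_spec()] the file must match; a mismatch in
#'   either dimension is an error naming the offending dimension.
#' @param name Variable to read; defaults to the first non-coordinate
#'   variable.
#' @return A raster; `_FillValue` cells come back as masked (`NA`).
#' @export
read_raster <- function(path, grid = NULL, name = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  if (is.null(name)) name <- names(nc$var)[1]
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  res_att <- ncdf4::ncatt_get(nc, 0, "resolution_deg")
  res <- if (res_att$hasatt) res_att$value else diff(lat[1:2])
  g <- grid_spec(lat_min = min(lat) - res / 2, lat_max = max(lat) + res / 2,
                 lon_min = min(lon) - res / 2, lon_max = max(lon) + res / 2,
                 resolution = res)
  if (!is.null(grid)) {
    if (g$nlat != grid$nlat || abs(g$lat_min - grid$lat_min) > 1e-9 ||
        abs(g$resolution - grid$resolution) > 1e-9) {
      stop(sprintf("raster file '%s': latitude dimension does not match the declared grid", path))
    }
    if (g$nlon != grid$nlon || abs(g$lon_min - grid$lon_min) > 1e-9) {
      stop(sprintf("raster file '%s': longitude dimension does not match the declared grid", path))
    }
    g <- grid
  }
  vals <- ncdf4::ncvar_get(nc, name, collapse_degen = FALSE)
  units <- nc$var[[name]]$units
  make_raster(g, t(matrix(as.numeric(vals), g$nlon, g$nlat)), units = units,
              name = name)
}

#' Write / read a plain CSV table
#'
#' Thin wrappers fixing the conventions used throughout the package:
#' header row, no row names, full float64 precision.
#'
#' @param x A data.frame.
#' @param path CSV file path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_table <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(col) sprintf("%.17g", col))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("table '%s' does not exist", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}
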