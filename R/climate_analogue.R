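#' Area-weighted percentile (step-CDF convention)
#'
#' Smallest value `v` such that the normalized cumulative weight of
#' observations `<= v` reaches `q`. No interpolation: the result is
#' always one of the input values, which makes the estimator exactly
#' reproducible by a sort-and-scan oracle.
#'
#' @param values Numeric vector.
#' @param weights Nonnegative weights, at least one positive.
#' @param q Percentile fraction in (0, 1).
#' @return One of `values`.
#' @export
weighted_percentile <- function(values, weights, q = 0.95) {
  stopifnot(length(values) == length(weights), q > 0, q < 1)
  ok <- !is.na(values) & !is.na(weights)
  values <- values[ok]; weights <- weights[ok]
  if (any(weights < 0)) stop("weights must be nonnegative")
  tot <- sum(weights)
  if (length(values) == 0 || tot <= 0) {
    stop("empty domain: no observations with positive weight")
  }
  o <- order(values)
  cw <- cumsum(weights[o]) / tot
  values[o][which(cw >= q)[1]]
}

#' Partition cropland into equal-area climate zones
#'
#' Bin edges are area-weighted quantiles of growing degree days and of
#' precipitation over cropped cells, so each marginal bin holds
#' approximately equal crop area (within one cell's area). Zones are the
#' cross-product of the two marginal binnings.
#'
#' @param gdd,precip Rasters of growing degree days and annual
#'   precipitation.
#' @param crop A crop layer (its `harvested_area` is the area weight).
#' @param n_gdd_bins,n_precip_bins Number of marginal bins (>= 2 each).
#' @return A `zone_scheme`: interior edges per variable and a `zone_id`
#'   raster over cropped cells.
#' @export
build_zone_scheme <- function(gdd, precip, crop, n_gdd_bins = 10,
                              n_precip_bins = 10) {
  stopifnot(n_gdd_bins >= 2, n_precip_bins >= 2)
  g <- check_same_grid(gdd, precip, crop$harvested_area)
  w <- crop$harvested_area$values
  cropped <- !is.na(w) & w > 0 & !is.na(gdd$values) & !is.na(precip$values)
  if (!any(cropped)) stop("no cropped cells with positive area")

  marginal_edges <- function(vals, label, nb) {
    v <- vals[cropped]
    if (length(unique(v)) < nb) {
      stop(sprintf("fewer distinct %s values than bins", label))
    }
    e <- vapply(seq_len(nb - 1) / nb, function(q) {
      weighted_percentile(v, w[cropped], q)
    }, numeric(1))
    if (any(diff(e) <= 0)) {
      stop(sprintf("degenerate %s bin edges: values too concentrated", label))
    }
    e
  }
  gdd_edges <- marginal_edges(gdd$values, "gdd", n_gdd_bins)
  precip_edges <- marginal_edges(precip$values, "precip", n_precip_bins)

  # bin k holds values in (edge_{k-1}, edge_k]; the top bin is open above
  gbin <- findInterval(gdd$values, gdd_edges, left.open = TRUE) + 1L
  pbin <- findInterval(precip$values, precip_edges, left.open = TRUE) + 1L
  zone <- matrix((gbin - 1L) * n_precip_bins + pbin, g$nlat, g$nlon)
  zone[!cropped] <- NA_integer_
  structure(list(
    n_gdd_bins = as.integer(n_gdd_bins),
    n_precip_bins = as.integer(n_precip_bins),
    gdd_edges = gdd_edges, precip_edges = precip_edges,
    zone_id = make_raster(g, zone, units = "id", name = "zone_id")
  ), class = "zone_scheme")
}

#' Attainable yields per climate zone
#'
#' Irrigated attainable yield is the area-weighted 95th percentile of all
#' observations in the zone (including irrigated and fractionally
#' irrigated areas). Rainfed attainable yield is the same percentile
#' restricted to observations from political units with less than
#' `rainfed_admin_threshold` of crop area irrigated. Zones with fewer
#' than `min_obs` qualifying observations are invalid (`NA`), never zero.
#'
#' @param obs Point-yield table with a `zone_id` column (see
#'   [gen_point_yields()] for the other columns).
#' @param q Percentile (default 0.95).
#' @param rainfed_admin_threshold Irrigated-fraction cutoff defining a
#'   rainfed political unit (default 0.10).
#' @param min_obs Minimum qualifying observations for a valid attainable.
#' @return A data.frame with one row per zone: `zone_id`,
#'   `irrigated_attainable`, `rainfed_attainable`, `n_obs_irr`, `n_obs_rf`.
#' @export
attainable_by_zone <- function(obs, q = 0.95, rainfed_admin_threshold = 0.10,
                               min_obs = 5) {
  stopifnot(all(c("zone_id", "yield_t_ha", "area_km2",
                  "admin_irr_fraction") %in% names(obs)))
  obs <- obs[!is.na(obs$zone_id), ]
  zones <- sort(unique(obs$zone_id))
  out <- data.frame(zone_id = zones, irrigated_attainable = NA_real_,
                    rainfed_attainable = NA_real_, n_obs_irr = 0L,
                    n_obs_rf = 0L)
  idx <- split(seq_len(nrow(obs)), obs$zone_id)
  for (k in seq_along(zones)) {
    i <- idx[[as.character(zones[k])]]
    out$n_obs_irr[k] <- length(i)
    if (length(i) >= min_obs) {
      out$irrigated_attainable[k] <-
        weighted_percentile(obs$yield_t_ha[i], obs$area_km2[i], q)
    }
    j <- i[obs$admin_irr_fraction[i] < rainfed_admin_threshold]
    out$n_obs_rf[k] <- length(j)
    if (length(j) >= min_obs) {
      out$rainfed_attainable[k] <-
        weighted_percentile(obs$yield_t_ha[j], obs$area_km2[j], q)
    }
  }
  out
}

#' Climate-analogue estimate of the irrigation yield gain
#'
#' For each square zone count `b` in `bin_range`, builds a `b x b`
#' equal-area GDD-by-precipitation zone scheme, computes zone attainable
#' yields, maps them back to member cells, and forms
#' `delta_y = (irrigated - rainfed) / irrigated` (floored at 0). The
#' final estimate is the unweighted mean across replicates; cells invalid
#' in a replicate (no qualifying rainfed observations in their zone) are
#' skipped in that replicate.
#'
#' @param obs Point-yield table (see [gen_point_yields()]).
#' @param gdd,precip Climate rasters used for zoning.
#' @param crop Crop layer.
#' @param bin_range Integer pair: smallest and largest square bin count
#'   (default `c(10, 20)`, i.e. 100 to 400 zones in 11 replicates).
#' @param q,rainfed_admin_threshold,min_obs Passed to
#'   [attainable_by_zone()].
#' @return A `ca_estimate`: `delta_y` raster (replicate mean),
#'   `per_replicate_spread` raster (sd across replicates), `n_replicates`.
#' @export
ca_delta_y <- function(obs, gdd, precip, crop, bin_range = c(10, 20),
                       q = 0.95, rainfed_admin_threshold = 0.10,
                       min_obs = 5) {
  g <- check_same_grid(gdd, precip, crop$harvested_area)
  bins <- seq(bin_range[1], bin_range[2])
  n <- g$nlat * g$nlon
  sum_dy <- numeric(n)
  sum_dy2 <- numeric(n)
  n_rep <- integer(n)
  for (b in bins) {
    scheme <- build_zone_scheme(gdd, precip, crop, b, b)
    obs_b <- obs
    obs_b$zone_id <- scheme$zone_id$values[obs_b$cell_id]
    att <- attainable_by_zone(obs_b, q = q,
                              rainfed_admin_threshold = rainfed_admin_threshold,
                              min_obs = min_obs)
    valid <- !is.na(att$irrigated_attainable) &
      !is.na(att$rainfed_attainable) & att$irrigated_attainable > 0
    att_dy <- pmax(0, (att$irrigated_attainable - att$rainfed_attainable) /
                     att$irrigated_attainable)
    lookup <- rep(NA_real_, max(att$zone_id))
    lookup[att$zone_id[valid]] <- att_dy[valid]
    zid <- scheme$zone_id$values
    cell_dy <- ifelse(is.na(zid), NA_real_, lookup[ifelse(is.na(zid), 1L, zid)])
    ok <- !is.na(cell_dy)
    sum_dy[ok] <- sum_dy[ok] + cell_dy[ok]
    sum_dy2[ok] <- sum_dy2[ok] + cell_dy[ok]^2
    n_rep[ok] <- n_rep[ok] + 1L
  }
  mean_dy <- ifelse(n_rep > 0, sum_dy / n_rep, NA_real_)
  var_dy <- ifelse(n_rep > 1,
                   pmax(0, (sum_dy2 - sum_dy^2 / n_rep) / (n_rep - 1)),
                   NA_real_)
  structure(list(
    delta_y = make_raster(g, matrix(mean_dy, g$nlat, g$nlon), units = "1",
                          name = "delta_y_ca"),
    per_replicate_spread = make_raster(g, matrix(sqrt(var_dy), g$nlat,
                                                 g$nlon),
                                       units = "1", name = "ca_spread"),
    n_replicates = length(bins)
  ), class = "ca_estimate")
}
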