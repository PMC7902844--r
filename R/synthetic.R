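#' Configuration of the synthetic world
#'
#' The generator emulates the statistical structure of the gridded inputs
#' the analysis consumes: a latent irrigation yield-gain field (`delta_y`)
#' driven by mean annual precipitation (MAP) and evaporative demand (PET),
#' a crop-model ensemble observing it with member-specific multiplicative
#' bias and spatially correlated noise, a near-unbiased but noisier
#' empirical observation of it, point yield observations for the
#' climate-analogue estimator, and basin-pooled renewable discharge.
#'
#' Defaults encode the study conditions the pipeline is meant to recover:
#' 10 ensemble members whose global-mean `delta_y` overshoots the truth by
#' a factor of about 2 with a factor-4 spread between the lowest and
#' highest member, an empirical observation with negligible bias but only
#' moderate pattern correlation, and a `delta_y` field decreasing in MAP
#' and (mildly) increasing in evaporative demand.
#'
#' @param grid A [grid_spec()] (default: global 2 degrees).
#' @param seed Integer seed; the whole world is a deterministic function
#'   of the config.
#' @param n_members Number of ensemble members.
#' @param member_gain,member_offset,member_noise_sd Per-member
#'   multiplicative bias, additive bias, and noise scale on `delta_y`.
#' @param ca_noise_sd Pointwise sd of the empirical observation's
#'   spatially correlated noise (fraction units).
#' @param deltay_map_scale E-folding scale of `delta_y` in MAP (mm).
#' @param deltay_pet_gain Dimensionless modulation of `delta_y` by
#'   standardized PET.
#' @param runoff_coefficient Fraction of precipitation that becomes basin
#'   discharge.
#' @param n_basins Number of Voronoi-seeded basins.
#' @param irrigation_efficiency Crop irrigation efficiency in (0, 1].
#' @param smooth_sigma Gaussian kernel width (cells) of all spatially
#'   correlated noise.
#' @param crop Crop identifier ("wheat" or "maize").
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(grid = grid_spec(resolution = 2),
                             seed = 1L,
                             n_members = 10L,
                             member_gain = NULL,
                             member_offset = NULL,
                             member_noise_sd = NULL,
                             ca_noise_sd = 0.22,
                             deltay_map_scale = 450,
                             deltay_pet_gain = 0.25,
                             runoff_coefficient = 0.35,
                             n_basins = 60L,
                             irrigation_efficiency = 0.5,
                             smooth_sigma = 1.5,
                             crop = "wheat") {
  stopifnot(n_members >= 2, ca_noise_sd >= 0,
            runoff_coefficient > 0, runoff_coefficient <= 1,
            irrigation_efficiency > 0, irrigation_efficiency <= 1)
  if (is.null(member_gain)) {
    # geometric ladder: factor-4 member spread, arithmetic mean ~ 2
    member_gain <- exp(seq(log(0.85), log(4.2), length.out = n_members))
  }
  if (is.null(member_offset)) {
    member_offset <- seq(-0.01, 0.05, length.out = n_members)
  }
  if (is.null(member_noise_sd)) {
    member_noise_sd <- seq(0.03, 0.10, length.out = n_members)
  }
  stopifnot(length(member_gain) == n_members,
            length(member_offset) == n_members,
            length(member_noise_sd) == n_members,
            all(member_noise_sd >= 0))
  structure(list(
    grid = grid, seed = as.integer(seed), n_members = as.integer(n_members),
    member_gain = member_gain, member_offset = member_offset,
    member_noise_sd = member_noise_sd, ca_noise_sd = ca_noise_sd,
    deltay_map_scale = deltay_map_scale, deltay_pet_gain = deltay_pet_gain,
    runoff_coefficient = runoff_coefficient, n_basins = as.integer(n_basins),
    irrigation_efficiency = irrigation_efficiency,
    smooth_sigma = smooth_sigma, crop = crop
  ), class = "synthetic_config")
}

#' Generate synthetic climate forcing
#'
#' Smooth latitude-driven fields plus spatially correlated noise: mean
#' annual precipitation (wet tropics, dry subtropics, mid-latitude storm
#' belt), mean temperature with a latitude-dependent seasonal cycle,
#' relative humidity, growing degree days (base 5 degrees C), and annual
#' potential evapotranspiration from the modified Haude equation applied
#' to the monthly temperature and humidity fields.
#'
#' @param config A [synthetic_config()].
#' @return A `climate_fields` object: rasters `map` (mm/yr), `pet`
#'   (mm/yr), `gdd` (degC day), `tmean` (degC), `rh` (%), plus 12-element
#'   lists `tmean_monthly` and `rh_monthly`.
#' @export
gen_climate <- function(config) {
  g <- config$grid
  set.seed(config$seed + 11L)
  latm <- matrix(g$lat, g$nlat, g$nlon)
  alat <- abs(latm)

  map <- 50 + 2600 * exp(-(latm / 18)^2) +
    900 * exp(-((alat - 52) / 14)^2) +
    spatial_noise(g, sd = 350, smooth_sigma = config$smooth_sigma)
  map <- clamp(map, 50, 3000)

  tmean <- 27 - 0.35 * alat +
    spatial_noise(g, sd = 2, smooth_sigma = config$smooth_sigma)
  tmean <- clamp(tmean, -5, 30)

  rh <- 85 - 35 * exp(-((alat - 25) / 12)^2) +
    spatial_noise(g, sd = 5, smooth_sigma = config$smooth_sigma)
  rh <- clamp(rh, 20, 100)

  amp <- 3 + 17 * alat / 90
  phase <- ifelse(latm >= 0, 7, 1) # warmest month: July north, January south
  tmean_monthly <- vector("list", 12)
  rh_monthly <- vector("list", 12)
  for (m in 1:12) {
    tm <- tmean + amp * cos(2 * pi * (m - phase) / 12)
    tmean_monthly[[m]] <- make_raster(g, tm, units = "degC",
                                      name = sprintf("tmean_m%02d", m))
    rhm <- clamp(rh - 4 * cos(2 * pi * (m - phase) / 12), 15, 100)
    rh_monthly[[m]] <- make_raster(g, rhm, units = "%",
                                   name = sprintf("rh_m%02d", m))
  }

  gdd <- Reduce(`+`, lapply(1:12, function(m) {
    pmax(tmean_monthly[[m]]$values - 5, 0) * days_in_month[m]
  }))

  pet <- haude_pet(tmean_monthly, rh_monthly)

  structure(list(
    grid = g,
    map = make_raster(g, map, units = "mm/yr", name = "map"),
    tmean = make_raster(g, tmean, units = "degC", name = "tmean"),
    rh = make_raster(g, rh, units = "%", name = "rh"),
    gdd = make_raster(g, gdd, units = "degC day", name = "gdd"),
    pet = pet,
    tmean_monthly = tmean_monthly, rh_monthly = rh_monthly
  ), class = "climate_fields")
}

# Crop layer: smooth suitability mask within climatically plausible cells,
# harvested area as a smooth fraction of cell area, 3x3-cell admin units
# with a Beta-distributed irrigation fraction (nearly half below the 10%
# rainfed cutoff).
gen_crop_layer <- function(config, climate) {
  g <- config$grid
  set.seed(config$seed + 23L)
  suit <- spatial_noise(g, sd = 1, smooth_sigma = config$smooth_sigma + 1)
  feasible <- climate$gdd$values > 900 & climate$map$values > 150
  thr <- stats::quantile(suit[feasible], 0.30, names = FALSE)
  cropped <- feasible & suit > thr
  if (sum(cropped) < 50) stop("synthetic world has too little cropland")

  frac <- clamp(0.25 + spatial_noise(g, sd = 0.12,
                                     smooth_sigma = config$smooth_sigma),
                0.02, 0.6)
  area <- cell_areas(g)$values
  harvested <- ifelse(cropped, frac * area, 0)

  block <- 3L
  bi <- (seq_len(g$nlat) - 1L) %/% block
  bj <- (seq_len(g$nlon) - 1L) %/% block
  admin <- outer(bi, bj, function(a, b) a * (max(bj) + 1L) + b + 1L)
  storage.mode(admin) <- "integer"
  n_admin <- max(admin)
  irr_admin <- stats::rbeta(n_admin, 0.5, 2.0)
  irr <- matrix(irr_admin[admin], g$nlat, g$nlon)

  structure(list(
    crop = config$crop,
    harvested_area = make_raster(g, harvested, units = "km2",
                                 name = "harvested_area"),
    irrigation_fraction = make_raster(g, irr, units = "1",
                                      name = "irrigation_fraction"),
    admin_unit_id = make_raster(g, admin, units = "id", name = "admin_unit"),
    cropped = cropped
  ), class = "crop_layer")
}

#' Generate the latent truth bundle
#'
#' The ground-truth yield-gain field is
#' `delta_y = clip(exp(-MAP / lambda_P) * (1 + lambda_E * PET_std), 0, 0.95)`
#' over cropland: it decays with precipitation supply and is modulated
#' upward by standardized evaporative demand. True net irrigation water
#' demand is proportional to `delta_y` times the annual climatic water
#' deficit. Basins are a seeded Voronoi partition; basin discharge is the
#' runoff coefficient times basin-integrated precipitation volume.
#'
#' @param config A [synthetic_config()].
#' @param climate Output of [gen_climate()] on the same grid.
#' @return A `truth_bundle`: `delta_y_true` (fraction, cropland only),
#'   `demand_true` (mm/yr), `crop` (crop layer), `climate`, `basins`
#'   (basin-id raster + discharge table in km^3/yr).
#' @export
gen_truth <- function(config, climate) {
  g <- config$grid
  if (!grids_identical(g, climate$grid)) stop("climate not on config grid")
  crop <- gen_crop_layer(config, climate)
  cropped <- crop$cropped

  pet <- climate$pet$values
  pet_std <- (pet - mean(pet[cropped])) / stats::sd(pet[cropped])
  dy <- exp(-climate$map$values / config$deltay_map_scale) *
    (1 + config$deltay_pet_gain * pet_std)
  dy <- clamp(dy, 0, 0.95)
  dy[!cropped] <- NA_real_

  deficit <- pmax(pet - 0.6 * climate$map$values, 0)
  demand <- dy * deficit
  demand[!cropped] <- NA_real_

  set.seed(config$seed + 37L)
  seeds_lat <- stats::runif(config$n_basins, g$lat_min, g$lat_max)
  seeds_lon <- stats::runif(config$n_basins, g$lon_min, g$lon_max)
  latm <- matrix(g$lat, g$nlat, g$nlon)
  lonm <- matrix(g$lon, g$nlat, g$nlon, byrow = TRUE)
  # chord distance on the unit sphere; longitude wrap handled naturally
  best <- matrix(Inf, g$nlat, g$nlon)
  basin <- matrix(1L, g$nlat, g$nlon)
  to_xyz <- function(lat, lon) {
    la <- lat * pi / 180; lo <- lon * pi / 180
    cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  }
  cells <- to_xyz(as.vector(latm), as.vector(lonm))
  seeds <- to_xyz(seeds_lat, seeds_lon)
  for (b in seq_len(config$n_basins)) {
    d <- (cells[, 1] - seeds[b, 1])^2 + (cells[, 2] - seeds[b, 2])^2 +
      (cells[, 3] - seeds[b, 3])^2
    upd <- d < best
    best[upd] <- d[upd]
    basin[upd] <- b
  }
  area <- cell_areas(g)$values
  runoff_km3 <- config$runoff_coefficient * climate$map$values * area * 1e-6
  by_basin <- tapply(as.vector(runoff_km3),
                     factor(as.vector(basin), levels = seq_len(config$n_basins)),
                     sum)
  by_basin[is.na(by_basin)] <- 0
  discharge <- data.frame(
    basin_id = seq_len(config$n_basins),
    discharge_km3yr = as.vector(by_basin)
  )

  structure(list(
    delta_y_true = make_raster(g, dy, units = "1", name = "delta_y_true"),
    demand_true = make_raster(g, demand, units = "mm/yr",
                              name = "demand_true"),
    crop = crop,
    climate = climate,
    basins = list(
      basin_id = make_raster(g, basin, units = "id", name = "basin_id"),
      discharge = discharge
    )
  ), class = "truth_bundle")
}

#' Generate a synthetic ensemble stack
#'
#' Member `m` observes the truth field as
#' `clip(gain_m * truth + offset_m + noise_m, lo, hi)` with spatially
#' correlated noise. With default gains the ensemble global mean
#' overshoots the truth by roughly a factor of 2 and members span a
#' factor of about 4 -- the regime the fusion step must correct.
#'
#' @param config A [synthetic_config()].
#' @param truth Output of [gen_truth()].
#' @param variable `"delta_y"` (fraction, clipped to \[0, 0.98\]) or
#'   `"demand"` (mm/yr, clipped below at 0).
#' @return An [ensemble_stack()].
#' @export
gen_ensemble <- function(config, truth, variable = c("delta_y", "demand")) {
  variable <- match.arg(variable)
  g <- config$grid
  base <- if (variable == "delta_y") truth$delta_y_true$values
          else truth$demand_true$values
  set.seed(config$seed + if (variable == "delta_y") 53L else 59L)
  members <- vector("list", config$n_members)
  for (m in seq_len(config$n_members)) {
    if (variable == "delta_y") {
      v <- config$member_gain[m] * base + config$member_offset[m] +
        spatial_noise(g, sd = config$member_noise_sd[m],
                      smooth_sigma = config$smooth_sigma)
      v <- clamp(v, 0, 0.98)
      units <- "1"
    } else {
      v <- config$member_gain[m] * base +
        spatial_noise(g, sd = 40 * config$member_noise_sd[m] / 0.05,
                      smooth_sigma = config$smooth_sigma)
      v <- pmax(v, 0)
      units <- "mm/yr"
    }
    v[is.na(base)] <- NA_real_
    members[[m]] <- make_raster(g, v, units = units,
                                name = sprintf("member_%02d", m))
  }
  ensemble_stack(sprintf("member_%02d", seq_len(config$n_members)),
                 members, variable = variable)
}

#' Generate the empirical (climate-analogue-like) observation
#'
#' Truth plus zero-mean spatially correlated noise, clipped to
#' \[0, 0.98\] and then iteratively re-centred so the clipping does not
#' leave a mean bias: the empirical estimator this emulates is nearly
#' unbiased in the mean but substantially noisier in spatial pattern than
#' the truth.
#'
#' @param config A [synthetic_config()].
#' @param truth Output of [gen_truth()].
#' @return A raster of observed `delta_y` on cropland.
#' @export
gen_ca_observation <- function(config, truth) {
  g <- config$grid
  t_v <- truth$delta_y_true$values
  set.seed(config$seed + 71L)
  obs <- t_v + spatial_noise(g, sd = config$ca_noise_sd,
                             smooth_sigma = config$smooth_sigma)
  ok <- !is.na(t_v)
  mt <- mean(t_v[ok])
  if (config$ca_noise_sd > 0) {
    for (i in 1:8) {
      obs <- clamp(obs, 0, 0.98)
      obs <- obs - (mean(obs[ok]) - mt)
    }
  }
  obs <- clamp(obs, 0, 0.98)
  obs[!ok] <- NA_real_
  make_raster(g, obs, units = "1", name = "delta_y_ca")
}

#' Generate point yield observations for the climate-analogue estimator
#'
#' Each cropped cell contributes up to two observations: an irrigated one
#' (area = harvested area times the admin unit's irrigation fraction)
#' drawn around a smooth potential-yield surface in GDD and MAP, and a
#' rainfed one (the remaining area) at `irrigated * (1 - delta_y_true)`
#' plus noise. Rows carry the admin irrigation fraction so the "<10%
#' irrigated political unit" rainfed rule is exercisable downstream.
#'
#' @param config A [synthetic_config()].
#' @param truth Output of [gen_truth()].
#' @return A data.frame with `cell_id`, `admin_unit_id`, `yield_t_ha`,
#'   `area_km2`, `irrigated_flag`, `admin_irr_fraction`.
#' @export
gen_point_yields <- function(config, truth) {
  crop <- truth$crop
  cl <- truth$climate
  cropped <- which(crop$cropped)
  set.seed(config$seed + 89L)
  gdd <- cl$gdd$values[cropped]
  map <- cl$map$values[cropped]
  dy <- truth$delta_y_true$values[cropped]
  ypot <- 3 + 8 * exp(-((gdd - 3500) / 2500)^2) + 1.5 * pmin(map, 1500) / 1500
  y_irr <- pmax(ypot * (1 + stats::rnorm(length(cropped), 0, 0.04)), 0.1)
  y_rf <- pmax(y_irr * (1 - dy) * (1 + stats::rnorm(length(cropped), 0, 0.04)),
               0.05)
  harv <- crop$harvested_area$values[cropped]
  irrf <- crop$irrigation_fraction$values[cropped]
  admin <- crop$admin_unit_id$values[cropped]
  obs <- rbind(
    data.frame(cell_id = cropped, admin_unit_id = admin, yield_t_ha = y_irr,
               area_km2 = harv * irrf, irrigated_flag = TRUE,
               admin_irr_fraction = irrf),
    data.frame(cell_id = cropped, admin_unit_id = admin, yield_t_ha = y_rf,
               area_km2 = harv * (1 - irrf), irrigated_flag = FALSE,
               admin_irr_fraction = irrf)
  )
  obs <- obs[obs$area_km2 > 1e-9, ]
  rownames(obs) <- NULL
  obs
}

#' Generate the complete synthetic world
#'
#' Convenience wrapper running every generator stage under one config.
#'
#' @param config A [synthetic_config()].
#' @return A list with `config`, `climate`, `truth`, `ensemble` (delta_y
#'   stack), `demand_ensemble`, `ca_obs`, `obs` (point-yield table).
#' @export
gen_world <- function(config = synthetic_config()) {
  climate <- gen_climate(config)
  truth <- gen_truth(config, climate)
  list(
    config = config,
    climate = climate,
    truth = truth,
    ensemble = gen_ensemble(config, truth, "delta_y"),
    demand_ensemble = gen_ensemble(config, truth, "demand"),
    ca_obs = gen_ca_observation(config, truth),
    obs = gen_point_yields(config, truth)
  )
}
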