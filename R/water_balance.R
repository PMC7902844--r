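#' Balance configuration
#'
#' @param delta_y_min Minimum yield gain for a cell to demand irrigation
#'   (default 0.10).
#' @param max_runoff_fraction Static accessible fraction of basin
#'   discharge (default 0.30; the analysis sweeps 0.20-0.40).
#' @param rainfed_only Restrict demand to rainfed cells (irrigation
#'   fraction below `rainfed_cutoff`); default `TRUE`.
#' @param rainfed_cutoff Irrigated-fraction cutoff defining rainfed
#'   cropland (default 0.10, shared with the climate-analogue rule).
#' @param whole_basin_unserved Count every demanding cell of a deficit
#'   basin as unserved (default `TRUE`: full yield-gap closure is
#'   impossible basin-wide). `FALSE` counts only cells with a positive
#'   pro-rata deficit (identical sets under pro-rata allocation, kept as
#'   an explicit switch).
#' @return A `balance_config` list.
#' @export
balance_config <- function(delta_y_min = 0.10, max_runoff_fraction = 0.30,
                           rainfed_only = TRUE, rainfed_cutoff = 0.10,
                           whole_basin_unserved = TRUE) {
  stopifnot(delta_y_min > 0, delta_y_min < 1,
            max_runoff_fraction > 0, max_runoff_fraction <= 1)
  structure(list(delta_y_min = delta_y_min,
                 max_runoff_fraction = max_runoff_fraction,
                 rainfed_only = rainfed_only,
                 rainfed_cutoff = rainfed_cutoff,
                 whole_basin_unserved = whole_basin_unserved),
            class = "balance_config")
}

#' Gross irrigation demand from net crop water demand
#'
#' Net demand is the crop water requirement at 100% irrigation
#' efficiency; dividing by the crop-specific efficiency gives the gross
#' withdrawal requirement from surface water.
#'
#' @param net_demand Raster of net demand (mm/yr).
#' @param efficiency Irrigation efficiency in (0, 1].
#' @return An `irrigation_demand` list with `net_demand`, `gross_demand`,
#'   `efficiency`.
#' @export
irrigation_demand <- function(net_demand, efficiency = 0.5) {
  stopifnot(efficiency > 0, efficiency <= 1)
  g <- net_demand$grid
  gross <- make_raster(g, net_demand$values / efficiency, units = "mm/yr",
                       name = "gross_demand")
  structure(list(net_demand = net_demand, gross_demand = gross,
                 efficiency = efficiency), class = "irrigation_demand")
}

#' Cells demanding irrigation
#'
#' A cell demands irrigation when its yield gain reaches the minimum
#' threshold, it carries harvested area, and (by default) it is rainfed.
#'
#' @param delta_y Yield-gain raster.
#' @param crop Crop layer.
#' @param config A [balance_config()].
#' @return A list: logical `mask` matrix and total demanding `area_mha`.
#' @export
demanding_cells <- function(delta_y, crop, config = balance_config()) {
  check_same_grid(delta_y, crop$harvested_area)
  harv <- crop$harvested_area$values
  mask <- !is.na(delta_y$values) & delta_y$values >= config$delta_y_min &
    !is.na(harv) & harv > 0
  if (config$rainfed_only) {
    irrf <- crop$irrigation_fraction$values
    mask <- mask & !is.na(irrf) & irrf < config$rainfed_cutoff
  }
  list(mask = mask, area_mha = sum(harv[mask]) * 1e-4) # km2 -> Mha
}

#' Basin-scale balance of irrigation demand against discharge
#'
#' Demand is pooled annually per basin: basin demand is the sum of gross
#' cell demand volumes (mm/yr x km2 x 1e-6 = km3/yr) over demanding
#' cells; accessible supply is `max_runoff_fraction` times basin
#' discharge. A basin whose demand fits its supply is fully served. In a
#' deficit basin water is allocated pro-rata to demand, each demanding
#' cell keeps a deficit of `gross_demand * (1 - supply/demand)`, and the
#' basin's demanding cells count as unserved (their yield gap cannot be
#' fully closed).
#'
#' @param demand An [irrigation_demand()].
#' @param demanding Output of [demanding_cells()].
#' @param basins Basin list: `basin_id` raster and `discharge` table
#'   (`basin_id`, `discharge_km3yr`).
#' @param crop Crop layer (areas over which demand volumes apply).
#' @param config A [balance_config()].
#' @return A `balance_result`: `unserved_area_mha`, `unserved_mask`,
#'   `deficit` raster (mm/yr), `basin_table` (per-basin demand, supply,
#'   discharge, deficit, served flag).
#' @export
basin_balance <- function(demand, demanding, basins, crop,
                          config = balance_config()) {
  g <- check_same_grid(demand$gross_demand, basins$basin_id,
                       crop$harvested_area)
  mask <- demanding$mask
  bid <- basins$basin_id$values
  if (any(mask & is.na(bid))) stop("demanding cell with no basin assigned")
  harv <- crop$harvested_area$values
  gross <- demand$gross_demand$values
  vol <- ifelse(mask, gross * harv * 1e-6, 0) # km3/yr per cell
  vol[is.na(vol)] <- 0

  ids <- basins$discharge$basin_id
  dem_by_basin <- tapply(as.vector(vol), factor(as.vector(bid), levels = ids),
                         sum)
  dem_by_basin[is.na(dem_by_basin)] <- 0
  supply <- config$max_runoff_fraction * basins$discharge$discharge_km3yr
  served <- dem_by_basin <= supply
  shortfall_frac <- ifelse(served | dem_by_basin <= 0, 0,
                           1 - supply / dem_by_basin)

  frac_cell <- matrix(shortfall_frac[match(as.vector(bid), ids)],
                      g$nlat, g$nlon)
  deficit <- ifelse(mask, gross * frac_cell, 0)
  deficit[is.na(deficit)] <- 0
  unserved_mask <- if (config$whole_basin_unserved) {
    mask & frac_cell > 0
  } else {
    mask & deficit > 0
  }
  basin_table <- data.frame(
    basin_id = ids,
    demand_km3yr = as.vector(dem_by_basin),
    supply_km3yr = supply,
    discharge_km3yr = basins$discharge$discharge_km3yr,
    deficit_km3yr = as.vector(pmax(dem_by_basin - supply, 0)),
    served = as.vector(served)
  )
  structure(list(
    unserved_area_mha = sum(harv[unserved_mask]) * 1e-4,
    unserved_mask = unserved_mask,
    deficit = make_raster(g, deficit, units = "mm/yr", name = "deficit"),
    basin_table = basin_table,
    config = config
  ), class = "balance_result")
}

#' Unserved-area sweep over both balance thresholds
#'
#' Recomputes the unserved cropland area for every combination of the
#' minimum yield-gain threshold and the accessible runoff fraction.
#' Unserved area is monotone non-increasing along both axes.
#'
#' @param delta_y Yield-gain raster.
#' @param demand An [irrigation_demand()].
#' @param basins Basin list (see [basin_balance()]).
#' @param crop Crop layer.
#' @param dy_grid,frac_grid Threshold grids within (0, 1).
#' @param config Base [balance_config()] supplying the remaining options.
#' @return A matrix of unserved area (Mha), rows = `dy_grid`, columns =
#'   `frac_grid`, with dimnames.
#' @export
threshold_sweep <- function(delta_y, demand, basins, crop,
                            dy_grid = seq(0.05, 0.25, by = 0.05),
                            frac_grid = seq(0.2, 0.4, by = 0.05),
                            config = balance_config()) {
  out <- matrix(NA_real_, length(dy_grid), length(frac_grid),
                dimnames = list(sprintf("dy_%g", dy_grid),
                                sprintf("frac_%g", frac_grid)))
  for (i in seq_along(dy_grid)) {
    for (j in seq_along(frac_grid)) {
      cfg <- config
      cfg$delta_y_min <- dy_grid[i]
      cfg$max_runoff_fraction <- frac_grid[j]
      dem_cells <- demanding_cells(delta_y, crop, cfg)
      res <- basin_balance(demand, dem_cells, basins, crop, cfg)
      out[i, j] <- res$unserved_area_mha
    }
  }
  out
}

#' Per-basin demand-to-discharge summary
#'
#' Basin demand as a percentage of total (unthresholded) discharge,
#' sorted descending. Zero-discharge basins with positive demand are
#' flagged infinite rather than erroring.
#'
#' @param result A `balance_result`.
#' @return A data.frame: `basin_id`, `demand_km3yr`, `discharge_km3yr`,
#'   `demand_to_discharge_pct`.
#' @export
basin_summary <- function(result) {
  bt <- result$basin_table
  ratio <- ifelse(bt$discharge_km3yr > 0,
                  100 * bt$demand_km3yr / bt$discharge_km3yr,
                  ifelse(bt$demand_km3yr > 0, Inf, 0))
  out <- data.frame(basin_id = bt$basin_id,
                    demand_km3yr = bt$demand_km3yr,
                    discharge_km3yr = bt$discharge_km3yr,
                    demand_to_discharge_pct = ratio)
  out[order(-out$demand_to_discharge_pct), , drop = FALSE]
}
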