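# One-basin toy: 4 cells, easily hand-checked volumes.
toy_balance <- function(discharge = 100, dy = c(0.05, 0.15, 0.30, 0.08),
                        gross_mm = c(200, 400, 800, 100),
                        area_km2 = rep(25000, 4), efficiency = 1) {
  g <- grid_spec(0, 1, 0, 4, 1)
  crop <- list(
    crop = "wheat",
    harvested_area = make_raster(g, matrix(area_km2, 1, 4)),
    irrigation_fraction = make_raster(g, 0),
    admin_unit_id = make_raster(g, 1),
    cropped = matrix(TRUE, 1, 4)
  )
  class(crop) <- "crop_layer"
  basins <- list(basin_id = make_raster(g, 1),
                 discharge = data.frame(basin_id = 1,
                                        discharge_km3yr = discharge))
  net <- make_raster(g, matrix(gross_mm * efficiency, 1, 4),
                     units = "mm/yr")
  list(g = g, crop = crop, basins = basins,
       delta_y = make_raster(g, matrix(dy, 1, 4)),
       demand = irrigation_demand(net, efficiency))
}

test_that("demanding cells apply the yield-gain threshold", {
  tb <- toy_balance()
  cells <- demanding_cells(tb$delta_y, tb$crop,
                           balance_config(delta_y_min = 0.10))
  expect_equal(sum(cells$mask), 2) # exactly dy = 0.15 and 0.30
  expect_equal(cells$area_mha, 2 * 25000 * 1e-4)

  # threshold above every gain: empty set
  none <- demanding_cells(tb$delta_y, tb$crop,
                          balance_config(delta_y_min = 0.5))
  expect_equal(sum(none$mask), 0)

  # threshold near zero: all cropped rainfed cells demand
  all_cells <- demanding_cells(tb$delta_y, tb$crop,
                               balance_config(delta_y_min = 1e-6))
  expect_equal(sum(all_cells$mask), 4)
})

test_that("gross demand divides net demand by efficiency", {
  g <- grid_spec(0, 1, 0, 2, 1)
  net <- make_raster(g, matrix(c(100, 50), 1, 2), units = "mm/yr")
  dem <- irrigation_demand(net, efficiency = 0.5)
  expect_equal(dem$gross_demand$values, matrix(c(200, 100), 1, 2))
  expect_true(all(dem$gross_demand$values >= dem$net_demand$values))
})

test_that("basin balance allocates pro-rata under shortage", {
  # demanding cells 2 and 3: volumes 0.4*25000e-6*1e6... in km3:
  # 400mm*25000km2*1e-6 = 10; 800mm*25000km2*1e-6 = 20; total 30
  cfg <- balance_config(delta_y_min = 0.10, max_runoff_fraction = 0.3)
  tb <- toy_balance(discharge = 100)
  cells <- demanding_cells(tb$delta_y, tb$crop, cfg)
  res <- basin_balance(tb$demand, cells, tb$basins, tb$crop, cfg)
  expect_equal(res$basin_table$demand_km3yr, 30)
  expect_equal(res$basin_table$supply_km3yr, 30)
  expect_true(res$basin_table$served)
  expect_equal(res$unserved_area_mha, 0)
  expect_true(all(res$deficit$values == 0))

  # raise demand to 40 km3 (16 + 24): basin deficit 10, each cell loses 25%
  tb2 <- toy_balance(discharge = 100,
                     gross_mm = c(200, 640, 960, 100))
  cells2 <- demanding_cells(tb2$delta_y, tb2$crop, cfg)
  res2 <- basin_balance(tb2$demand, cells2, tb2$basins, tb2$crop, cfg)
  expect_equal(res2$basin_table$demand_km3yr, 40)
  expect_equal(res2$basin_table$deficit_km3yr, 10)
  expect_equal(res2$deficit$values[1, 2], 640 * 0.25)
  expect_equal(res2$deficit$values[1, 3], 960 * 0.25)
  expect_equal(res2$unserved_area_mha, 2 * 25000 * 1e-4)

  # full access and slack supply: nothing unserved
  cfg_all <- balance_config(delta_y_min = 0.10, max_runoff_fraction = 1)
  res3 <- basin_balance(tb2$demand, cells2, tb2$basins, tb2$crop, cfg_all)
  expect_equal(res3$unserved_area_mha, 0)
})

test_that("water is conserved within each basin", {
  w <- default_world()
  fit <- fit_bma_em(w$ensemble, w$ca_obs)
  dy <- bma_predict(w$ensemble, fit)$mean
  net <- reanalyze_demand(w$demand_ensemble, fit)
  dem <- irrigation_demand(net, 0.5)
  cfg <- balance_config()
  cells <- demanding_cells(dy, w$truth$crop, cfg)
  res <- basin_balance(dem, cells, w$truth$basins, w$truth$crop, cfg)
  harv <- w$truth$crop$harvested_area$values
  bid <- w$truth$basins$basin_id$values
  for (b in res$basin_table$basin_id) {
    in_b <- cells$mask & bid == b
    demand_b <- res$basin_table$demand_km3yr[res$basin_table$basin_id == b]
    if (demand_b == 0) next
    deficit_b <- sum(res$deficit$values[in_b] * harv[in_b]) * 1e-6
    allocated_b <- demand_b - deficit_b
    supply_b <- res$basin_table$supply_km3yr[res$basin_table$basin_id == b]
    # allocated + deficit = demand, and allocation never exceeds supply
    expect_lt(abs(allocated_b + deficit_b - demand_b) / demand_b, 1e-9)
    expect_lte(allocated_b, supply_b * (1 + 1e-9))
  }
})

test_that("unserved area is monotone along both threshold axes", {
  w <- default_world()
  fit <- fit_bma_em(w$ensemble, w$ca_obs)
  dy <- bma_predict(w$ensemble, fit)$mean
  net <- reanalyze_demand(w$demand_ensemble, fit)
  dem <- irrigation_demand(net, 0.5)
  sweep <- threshold_sweep(dy, dem, w$truth$basins, w$truth$crop,
                           dy_grid = seq(0.05, 0.25, by = 0.05),
                           frac_grid = seq(0.2, 0.4, by = 0.05))
  expect_true(all(apply(sweep, 1, diff) <= 1e-9)) # along runoff fraction
  expect_true(all(apply(sweep, 2, diff) <= 1e-9)) # along delta_y_min

  # full-access column bounds every other column from below
  full <- threshold_sweep(dy, dem, w$truth$basins, w$truth$crop,
                          dy_grid = c(0.1), frac_grid = c(0.3, 1.0))
  expect_lte(full[1, 2], full[1, 1])

  # threshold above the global maximum gain leaves nothing unserved
  hi <- threshold_sweep(dy, dem, w$truth$basins, w$truth$crop,
                        dy_grid = c(0.99), frac_grid = c(0.3))
  expect_equal(as.numeric(hi), 0)
})

test_that("doubling efficiency halves gross demand and never hurts", {
  w <- default_world()
  fit <- fit_bma_em(w$ensemble, w$ca_obs)
  dy <- bma_predict(w$ensemble, fit)$mean
  net <- reanalyze_demand(w$demand_ensemble, fit)
  d1 <- irrigation_demand(net, 0.4)
  d2 <- irrigation_demand(net, 0.8)
  expect_equal(d2$gross_demand$values, d1$gross_demand$values / 2)
  cfg <- balance_config()
  cells <- demanding_cells(dy, w$truth$crop, cfg)
  u1 <- basin_balance(d1, cells, w$truth$basins, w$truth$crop,
                      cfg)$unserved_area_mha
  u2 <- basin_balance(d2, cells, w$truth$basins, w$truth$crop,
                      cfg)$unserved_area_mha
  expect_lte(u2, u1)
})

test_that("basin summaries report demand-to-discharge ratios", {
  g <- grid_spec(0, 1, 0, 2, 1)
  crop <- structure(list(crop = "wheat",
                         harvested_area = make_raster(g, 10000),
                         irrigation_fraction = make_raster(g, 0),
                         admin_unit_id = make_raster(g, 1),
                         cropped = matrix(TRUE, 1, 2)),
                    class = "crop_layer")
  basins <- list(basin_id = make_raster(g, matrix(c(1, 2), 1, 2)),
                 discharge = data.frame(basin_id = 1:2,
                                        discharge_km3yr = c(1, 0)))
  # cell 1: 300 mm on 10000 km2 = 3 km3 demand on discharge 1 -> 300%
  dem <- irrigation_demand(make_raster(g, matrix(c(300, 100), 1, 2)), 1)
  dy <- make_raster(g, matrix(c(0.5, 0.5), 1, 2))
  cfg <- balance_config()
  cells <- demanding_cells(dy, crop, cfg)
  res <- basin_balance(dem, cells, basins, crop, cfg)
  summ <- basin_summary(res)
  expect_equal(summ$demand_to_discharge_pct[summ$basin_id == 1], 300)
  # zero-discharge basin with demand flags infinite, not an error
  expect_true(is.infinite(summ$demand_to_discharge_pct[summ$basin_id == 2]))
  # sorted descending
  expect_equal(summ$basin_id, c(2, 1))

  # zero-demand basin reports 0%
  dy0 <- make_raster(g, matrix(c(0.5, 0.01), 1, 2))
  basins0 <- list(basin_id = basins$basin_id,
                  discharge = data.frame(basin_id = 1:2,
                                         discharge_km3yr = c(1, 5)))
  res0 <- basin_balance(dem, demanding_cells(dy0, crop, cfg), basins0, crop,
                        cfg)
  summ0 <- basin_summary(res0)
  expect_equal(summ0$demand_to_discharge_pct[summ0$basin_id == 2], 0)
})
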