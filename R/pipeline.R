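#' Pipeline run configuration
#'
#' Bundles the stage list, output directory, seed, and per-stage options
#' for an end-to-end run. All stage randomness derives from the run seed
#' through fixed per-stage offsets, so a config reproduces its outputs
#' bit-identically.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Run-level integer seed.
#' @param stages Ordered subset of
#'   `c("generate", "ca", "bma", "evaluate", "drivers", "balance")`.
#' @param synthetic A [synthetic_config()]; its seed is overridden by
#'   `seed`.
#' @param balance A [balance_config()].
#' @param bma_method `"em"` or `"mcmc"`.
#' @param window Moving-window size in degrees for the driver stage
#'   (odd multiple of the grid resolution).
#' @param bin_range Zone-count range for the climate-analogue stage.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("generate", "ca", "bma", "evaluate",
                                  "drivers", "balance"),
                       synthetic = synthetic_config(),
                       balance = balance_config(),
                       bma_method = c("em", "mcmc"),
                       window = 10, bin_range = c(10, 20)) {
  all_stages <- c("generate", "ca", "bma", "evaluate", "drivers", "balance")
  stopifnot(all(stages %in% all_stages))
  bma_method <- match.arg(bma_method)
  synthetic$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages[order(match(stages, all_stages))],
                 synthetic = synthetic, balance = balance,
                 bma_method = bma_method, window = window,
                 bin_range = bin_range),
            class = "run_config")
}

config_fingerprint <- function(config) {
  s <- config$synthetic
  flat <- c(
    seed = config$seed, stages = paste(config$stages, collapse = ","),
    bma_method = config$bma_method, window = config$window,
    bin_range = paste(config$bin_range, collapse = "-"),
    resolution = s$grid$resolution, n_members = s$n_members,
    gains = paste(sprintf("%.10g", s$member_gain), collapse = ","),
    ca_noise = s$ca_noise_sd, map_scale = s$deltay_map_scale,
    pet_gain = s$deltay_pet_gain, runoff = s$runoff_coefficient,
    basins = s$n_basins, eff = s$irrigation_efficiency, crop = s$crop,
    dy_min = config$balance$delta_y_min,
    runoff_frac = config$balance$max_runoff_fraction
  )
  fnv1a_hash(paste(names(flat), flat, sep = "=", collapse = ";"))
}

stage_path <- function(config, file) file.path(config$out_dir, file)

require_artifact <- function(config, file, produced_by) {
  p <- stage_path(config, file)
  if (!file.exists(p)) {
    stop(sprintf("missing artifact '%s': run stage '%s' first", file,
                 produced_by))
  }
  p
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order against one output
#' directory: `generate` writes the synthetic world (climate, truth,
#' ensemble stacks, observation, yield table, basins), `ca` the
#' climate-analogue estimate, `bma` the fitted weights and reanalyzed
#' yield gain and demand, `evaluate` the skill table of every estimate
#' against the generator truth, `drivers` the moving-window attribution,
#' and `balance` the demand-supply accounting. A YAML run record with the
#' config fingerprint, seed, stage wall times, and an md5 manifest of all
#' data outputs is written at the end.
#'
#' @param config A [run_config()].
#' @return The run record, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  record <- list(fingerprint = config_fingerprint(config),
                 seed = config$seed,
                 stages = as.list(stats::setNames(rep(NA_real_,
                                                      length(config$stages)),
                                                  config$stages)))
  g <- config$synthetic$grid

  for (stage in config$stages) {
    t0 <- proc.time()[["elapsed"]]
    switch(stage,
      generate = {
        world <- gen_world(config$synthetic)
        write_raster(world$truth$delta_y_true,
                     stage_path(config, "delta_y_true.nc"))
        write_raster(world$truth$demand_true,
                     stage_path(config, "demand_true.nc"))
        write_raster(world$climate$map, stage_path(config, "map.nc"))
        write_raster(world$climate$pet, stage_path(config, "pet.nc"))
        write_raster(world$climate$gdd, stage_path(config, "gdd.nc"))
        write_raster(world$truth$crop$harvested_area,
                     stage_path(config, "harvested_area.nc"))
        write_raster(world$truth$crop$irrigation_fraction,
                     stage_path(config, "irrigation_fraction.nc"))
        write_raster(world$truth$crop$admin_unit_id,
                     stage_path(config, "admin_unit_id.nc"))
        write_raster(world$truth$basins$basin_id,
                     stage_path(config, "basin_id.nc"))
        write_table(world$truth$basins$discharge,
                    stage_path(config, "discharge.csv"))
        write_raster(world$ca_obs, stage_path(config, "delta_y_ca_obs.nc"))
        for (m in seq_along(world$ensemble$members)) {
          write_raster(world$ensemble$members[[m]],
                       stage_path(config, sprintf("ens_delta_y_%02d.nc", m)))
          write_raster(world$demand_ensemble$members[[m]],
                       stage_path(config, sprintf("ens_demand_%02d.nc", m)))
        }
        write_table(world$obs, stage_path(config, "point_yields.csv"))
      },
      ca = {
        gdd <- read_raster(require_artifact(config, "gdd.nc", "generate"), g)
        map <- read_raster(require_artifact(config, "map.nc", "generate"), g)
        crop <- read_crop_layer(config, g)
        obs <- read_table(require_artifact(config, "point_yields.csv",
                                           "generate"))
        est <- ca_delta_y(obs, gdd, map, crop, bin_range = config$bin_range)
        write_raster(est$delta_y, stage_path(config, "delta_y_ca_est.nc"))
        write_raster(est$per_replicate_spread,
                     stage_path(config, "delta_y_ca_spread.nc"))
      },
      bma = {
        obs <- read_raster(require_artifact(config, "delta_y_ca_obs.nc",
                                            "generate"), g)
        stack <- read_stack(config, "ens_delta_y_%02d.nc", "delta_y", g)
        weights <- if (config$bma_method == "em") {
          fit_bma_em(stack, obs)
        } else {
          fit_bma_mcmc(stack, obs, seed = config$seed + 101L)
        }
        rea <- bma_predict(stack, weights)
        write_raster(rea$mean, stage_path(config, "delta_y_reanalysis.nc"))
        write_raster(rea$sd, stage_path(config, "delta_y_reanalysis_sd.nc"))
        demand_stack <- read_stack(config, "ens_demand_%02d.nc", "demand", g)
        demand <- reanalyze_demand(demand_stack, weights)
        write_raster(demand, stage_path(config, "demand_reanalysis.nc"))
        write_table(data.frame(member = weights$member_ids, w = weights$w),
                    stage_path(config, "bma_weights.csv"))
        yaml::write_yaml(list(method = weights$method,
                              sigma = weights$sigma,
                              n_iter = weights$n_iter,
                              converged = weights$converged,
                              log_likelihood = weights$log_likelihood),
                         stage_path(config, "bma_fit.yaml"))
      },
      evaluate = {
        truth <- read_raster(require_artifact(config, "delta_y_true.nc",
                                              "generate"), g)
        cands <- list(
          ca_observation = read_raster(
            require_artifact(config, "delta_y_ca_obs.nc", "generate"), g),
          ensemble_mean = {
            stack <- read_stack(config, "ens_delta_y_%02d.nc", "delta_y", g)
            eq <- structure(list(w = rep(1 / length(stack$members),
                                         length(stack$members)),
                                 sigma = 1e-8, method = "equal",
                                 member_ids = stack$member_ids),
                            class = "bma_weights")
            bma_predict(stack, eq)$mean
          },
          bma_reanalysis = read_raster(
            require_artifact(config, "delta_y_reanalysis.nc", "bma"), g)
        )
        if (file.exists(stage_path(config, "delta_y_ca_est.nc"))) {
          cands$ca_estimate <- read_raster(
            stage_path(config, "delta_y_ca_est.nc"), g)
        }
        write_table(evaluate_against_reference(cands, truth),
                    stage_path(config, "evaluation.csv"))
      },
      drivers = {
        dy <- read_raster(require_artifact(config, "delta_y_reanalysis.nc",
                                           "bma"), g)
        climate <- list(
          grid = g,
          map = read_raster(require_artifact(config, "map.nc", "generate"),
                            g),
          pet = read_raster(require_artifact(config, "pet.nc", "generate"),
                            g)
        )
        crop <- read_crop_layer(config, g)
        # attribute only cropped cells
        dy$values[!(crop$harvested_area$values > 0)] <- NA_real_
        dmap <- moving_window_drivers(dy, climate, window = config$window)
        write_raster(dmap$r_map, stage_path(config, "driver_r_map.nc"))
        write_raster(dmap$r_pet, stage_path(config, "driver_r_pet.nc"))
        write_raster(dmap$p_map, stage_path(config, "driver_p_map.nc"))
        write_raster(dmap$p_pet, stage_path(config, "driver_p_pet.nc"))
        dom <- dominance_and_area_curve(dmap, crop)
        write_raster(dom$dominance, stage_path(config, "dominance.nc"))
        write_table(dom$curve, stage_path(config, "driver_area_curve.csv"))
      },
      balance = {
        dy <- read_raster(require_artifact(config, "delta_y_reanalysis.nc",
                                           "bma"), g)
        net <- read_raster(require_artifact(config, "demand_reanalysis.nc",
                                            "bma"), g)
        crop <- read_crop_layer(config, g)
        basins <- list(
          basin_id = read_raster(require_artifact(config, "basin_id.nc",
                                                  "generate"), g),
          discharge = read_table(require_artifact(config, "discharge.csv",
                                                  "generate"))
        )
        dem <- irrigation_demand(net,
                                 config$synthetic$irrigation_efficiency)
        cells <- demanding_cells(dy, crop, config$balance)
        res <- basin_balance(dem, cells, basins, crop, config$balance)
        write_raster(res$deficit, stage_path(config, "deficit.nc"))
        write_table(res$basin_table, stage_path(config, "basin_table.csv"))
        write_table(basin_summary(res),
                    stage_path(config, "basin_summary.csv"))
        sweep <- threshold_sweep(dy, dem, basins, crop,
                                 config = config$balance)
        sweep_df <- data.frame(delta_y_min = rep(rownames(sweep),
                                                 ncol(sweep)),
                               runoff_fraction = rep(colnames(sweep),
                                                     each = nrow(sweep)),
                               unserved_mha = as.vector(sweep))
        write_table(sweep_df, stage_path(config, "unserved_sweep.csv"))
        yaml::write_yaml(list(unserved_area_mha = res$unserved_area_mha,
                              demanding_area_mha = cells$area_mha),
                         stage_path(config, "balance_summary.yaml"))
      }
    )
    record$stages[[stage]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  files <- setdiff(list.files(config$out_dir), "run_record.yaml")
  manifest <- as.list(tools::md5sum(file.path(config$out_dir, files)))
  names(manifest) <- files
  record$manifest <- manifest
  yaml::write_yaml(record, stage_path(config, "run_record.yaml"))
  invisible(record)
}

read_crop_layer <- function(config, g) {
  harv <- read_raster(require_artifact(config, "harvested_area.nc",
                                       "generate"), g)
  structure(list(
    crop = config$synthetic$crop,
    harvested_area = harv,
    irrigation_fraction = read_raster(
      require_artifact(config, "irrigation_fraction.nc", "generate"), g),
    admin_unit_id = read_raster(
      require_artifact(config, "admin_unit_id.nc", "generate"), g),
    cropped = !is.na(harv$values) & harv$values > 0
  ), class = "crop_layer")
}

read_stack <- function(config, pattern, variable, g) {
  n <- config$synthetic$n_members
  members <- lapply(seq_len(n), function(m) {
    read_raster(require_artifact(config, sprintf(pattern, m), "generate"), g)
  })
  ensemble_stack(sprintf("member_%02d", seq_len(n)), members,
                 variable = variable)
}
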