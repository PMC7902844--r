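#' Saturation vapor pressure (Magnus form)
#'
#' `e_s(T) = 6.11 * 10^(7.5 T / (237.3 + T))` hPa, for air temperature in
#' degrees Celsius.
#'
#' @param t Temperature in degC (vector or matrix), within \[-60, 60\].
#' @return Saturation vapor pressure in hPa, same shape as `t`.
#' @export
saturation_vapor_pressure <- function(t) {
  stopifnot(all(t >= -60 & t <= 60, na.rm = TRUE))
  6.11 * 10^(7.5 * t / (237.3 + t))
}

#' Default monthly Haude coefficients
#'
#' The classic monthly Haude coefficients k (mm per day per hPa of
#' vapor-pressure deficit) with the standard 7 mm/day cap on daily PET.
#'
#' @param k Twelve monthly coefficients (January to December).
#' @param cap Daily PET ceiling in mm/day.
#' @return A `haude_coefficients` list.
#' @export
haude_coefficients <- function(k = c(0.22, 0.22, 0.22, 0.29, 0.29, 0.28,
                                     0.26, 0.25, 0.23, 0.22, 0.22, 0.22),
                               cap = 7) {
  stopifnot(length(k) == 12, all(k > 0), cap > 0)
  structure(list(k = k, cap = cap), class = "haude_coefficients")
}

#' Annual potential evapotranspiration (modified Haude)
#'
#' Daily PET for month m is `min(cap, k_m * e_s(T_m) * (1 - RH_m/100))`:
#' a monthly coefficient times the vapor-pressure deficit, capped. The
#' annual total sums daily PET over calendar-month lengths (365-day
#' year). PET is zero at saturation (RH = 100%), non-decreasing in
#' temperature and non-increasing in relative humidity.
#'
#' @param tmean_monthly,rh_monthly Lists of 12 monthly rasters (or plain
#'   matrices) of mean temperature (degC) and relative humidity (%).
#' @param coeffs A [haude_coefficients()].
#' @return A raster (or matrix, matching the input type) of annual PET in
#'   mm/yr.
#' @export
haude_pet <- function(tmean_monthly, rh_monthly,
                      coeffs = haude_coefficients()) {
  stopifnot(inherits(coeffs, "haude_coefficients"))
  if (length(tmean_monthly) != 12 || length(rh_monthly) != 12) {
    stop("haude_pet needs 12 monthly temperature and humidity fields")
  }
  as_mat <- function(x) if (inherits(x, "raster")) x$values else x
  grid <- if (inherits(tmean_monthly[[1]], "raster")) {
    tmean_monthly[[1]]$grid
  } else NULL
  annual <- 0
  for (m in 1:12) {
    tm <- as_mat(tmean_monthly[[m]])
    rh <- as_mat(rh_monthly[[m]])
    daily <- pmin(coeffs$k[m] * saturation_vapor_pressure(tm) *
                    (1 - rh / 100),
                  coeffs$cap)
    annual <- annual + pmax(daily, 0) * days_in_month[m]
  }
  if (is.null(grid)) annual
  else make_raster(grid, annual, units = "mm/yr", name = "pet")
}

#' Partial correlation with a single linear control
#'
#' Correlation between `x` and `y` after linearly removing `z` from both;
#' equals the correlation of the two regression residuals. Two-tailed
#' p-value from the t transform on `n - 3` degrees of freedom. When `z`
#' has exactly zero sample covariance with both `x` and `y` this reduces
#' to the plain Pearson correlation.
#'
#' @param x,y,z Numeric vectors of equal length (n >= 4), finite.
#' @return A list with `r`, `p`, `n`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, n >= 4)
  if (anyNA(x) || anyNA(y) || anyNA(z)) stop("inputs must be finite")
  if (stats::sd(z) == 0 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined partial correlation: constant input")
  }
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, z)
  ryz <- stats::cor(y, z)
  den2 <- (1 - rxz^2) * (1 - ryz^2)
  if (den2 <= .Machine$double.eps) {
    stop("undefined partial correlation: control is collinear")
  }
  r <- (rxy - rxz * ryz) / sqrt(den2)
  r <- min(max(r, -1), 1)
  tt <- r * sqrt((n - 3) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 3)
  list(r = r, p = p, n = n)
}

#' Moving-window attribution of the yield gain to climate drivers
#'
#' For every valid cell of the yield-gain map, collects the jointly valid
#' cells inside a centred square window and computes two partial
#' correlations across space: gain vs precipitation controlling for PET
#' (`r_map`) and gain vs PET controlling for precipitation (`r_pet`),
#' each with a two-tailed p-value. Windows are truncated at the
#' latitudinal domain edge; longitude wraps on global grids. Cells whose
#' window holds fewer than `min_cells` valid cells (or degenerate
#' variance) are masked.
#'
#' @param delta_y Yield-gain raster, already masked to cropland.
#' @param climate A `climate_fields` object (uses `map` and `pet`).
#' @param window Window size in degrees; must be an odd multiple of the
#'   grid resolution and span at least 3 cells.
#' @param min_cells Minimum jointly valid cells per window (default 10).
#' @return A `driver_map`: rasters `r_map`, `r_pet`, `p_map`, `p_pet`,
#'   `n_window`.
#' @export
moving_window_drivers <- function(delta_y, climate, window = 3.5,
                                  min_cells = 10) {
  g <- check_same_grid(delta_y, climate$map, climate$pet)
  k <- window / g$resolution
  if (abs(k - round(k)) > 1e-9 || round(k) %% 2 != 1) {
    stop("window must be an odd multiple of the grid resolution")
  }
  k <- as.integer(round(k))
  if (k < 3) stop("window must span at least 3 cells")
  half <- (k - 1L) %/% 2L
  wrap <- abs((g$lon_max - g$lon_min) - 360) < 1e-9

  dy <- delta_y$values
  mp <- climate$map$values
  pe <- climate$pet$values
  valid <- !is.na(dy) & !is.na(mp) & !is.na(pe)
  nlat <- g$nlat; nlon <- g$nlon

  # Windowed sums of every needed moment via summed-area tables: columns
  # are padded (wrapped or zero) by `half`, rows truncated by index
  # clamping, so each call is O(cells) regardless of window size.
  box <- function(M) {
    M[!valid] <- 0
    Mp <- if (wrap) {
      cbind(M[, (nlon - half + 1):nlon, drop = FALSE], M,
            M[, seq_len(half), drop = FALSE])
    } else {
      cbind(matrix(0, nlat, half), M, matrix(0, nlat, half))
    }
    S <- apply(Mp, 2, cumsum)
    S <- t(apply(S, 1, cumsum))
    Z <- rbind(0, cbind(0, S))
    i <- matrix(seq_len(nlat), nlat, nlon)
    j <- matrix(seq_len(nlon), nlat, nlon, byrow = TRUE)
    r1 <- pmax(i - half, 1L); r2 <- pmin(i + half, nlat)
    c1 <- j; c2 <- j + 2L * half # padded column coordinates
    Z[cbind(as.vector(r2) + 1L, as.vector(c2) + 1L)] -
      Z[cbind(as.vector(r1), as.vector(c2) + 1L)] -
      Z[cbind(as.vector(r2) + 1L, as.vector(c1))] +
      Z[cbind(as.vector(r1), as.vector(c1))]
  }
  n <- box(matrix(1, nlat, nlon))
  sx <- box(dy); sy <- box(mp); sz <- box(pe)
  sxx <- box(dy^2); syy <- box(mp^2); szz <- box(pe^2)
  sxy <- box(dy * mp); sxz <- box(dy * pe); syz <- box(mp * pe)
  vx <- sxx / n - (sx / n)^2
  vy <- syy / n - (sy / n)^2
  vz <- szz / n - (sz / n)^2
  cxy <- sxy / n - (sx / n) * (sy / n)
  cxz <- sxz / n - (sx / n) * (sz / n)
  cyz <- syz / n - (sy / n) * (sz / n)
  eps <- 1e-12
  good <- as.vector(valid) & n >= min_cells & vx > eps & vy > eps & vz > eps
  vx <- pmax(vx, 0); vy <- pmax(vy, 0); vz <- pmax(vz, 0)
  rxy <- ifelse(good, cxy / sqrt(vx * vy), NA_real_)
  rxz <- ifelse(good, cxz / sqrt(vx * vz), NA_real_)
  ryz <- ifelse(good, cyz / sqrt(vy * vz), NA_real_)
  pc_of <- function(r12, r13, r23) {
    den2 <- (1 - r13^2) * (1 - r23^2)
    r <- ifelse(den2 > eps, (r12 - r13 * r23) / sqrt(den2), NA_real_)
    r <- pmin(pmax(r, -1), 1)
    tt <- r * sqrt(pmax(n - 3, 0) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = pmax(n - 3, 1))
    list(r = r, p = p)
  }
  pm <- pc_of(rxy, rxz, ryz) # gain vs MAP | PET
  pp <- pc_of(rxz, rxy, ryz) # gain vs PET | MAP
  shape <- function(v) matrix(v, nlat, nlon)
  r_map <- shape(pm$r); p_map <- shape(pm$p)
  r_pet <- shape(pp$r); p_pet <- shape(pp$p)
  n_win <- shape(ifelse(as.vector(valid), n, NA_real_))
  structure(list(
    r_map = make_raster(g, r_map, units = "1", name = "r_map"),
    r_pet = make_raster(g, r_pet, units = "1", name = "r_pet"),
    p_map = make_raster(g, p_map, units = "1", name = "p_map"),
    p_pet = make_raster(g, p_pet, units = "1", name = "p_pet"),
    n_window = make_raster(g, n_win, units = "cells", name = "n_window"),
    window = window, min_cells = min_cells
  ), class = "driver_map")
}

#' Driver dominance and area-fraction curve
#'
#' For each threshold `t`, a cell is precipitation-controlled when
#' `|r_map| >= t` and `|r_map| > |r_pet|` (symmetrically for PET), and
#' co-dominant when both exceed `t` and the absolute coefficients differ
#' by less than 0.05. Percentages of cropland area are harvested-area
#' weighted; co-dominant area is counted once, in its own column.
#'
#' @param drivers A `driver_map`.
#' @param crop Crop layer supplying harvested-area weights.
#' @param thresholds Vector of |r| thresholds in (0, 1) for the curve.
#' @param dominance_threshold Threshold used for the returned dominance
#'   raster (default 0: classify every attributed cell).
#' @return A list: `dominance` raster (0 none, 1 MAP, 2 PET, 3
#'   co-dominant) and `curve` data.frame (`threshold`, `pct_map`,
#'   `pct_pet`, `pct_codominant`).
#' @export
dominance_and_area_curve <- function(drivers, crop,
                                     thresholds = seq(0.1, 0.9, by = 0.1),
                                     dominance_threshold = 0) {
  g <- check_same_grid(drivers$r_map, crop$harvested_area)
  am <- abs(drivers$r_map$values)
  ap <- abs(drivers$r_pet$values)
  w <- crop$harvested_area$values
  valid <- !is.na(am) & !is.na(ap) & !is.na(w) & w > 0
  wtot <- sum(w[valid])

  classify <- function(t) {
    cls <- matrix(0, g$nlat, g$nlon)
    co <- valid & am >= t & ap >= t & abs(am - ap) < 0.05
    m_dom <- valid & !co & am >= t & am > ap
    p_dom <- valid & !co & ap >= t & ap > am
    cls[m_dom] <- 1; cls[p_dom] <- 2; cls[co] <- 3
    cls[!valid] <- NA_real_
    cls
  }
  curve <- do.call(rbind, lapply(thresholds, function(t) {
    cls <- classify(t)
    data.frame(
      threshold = t,
      pct_map = 100 * sum(w[valid & cls == 1]) / wtot,
      pct_pet = 100 * sum(w[valid & cls == 2]) / wtot,
      pct_codominant = 100 * sum(w[valid & cls == 3]) / wtot
    )
  }))
  list(dominance = make_raster(g, classify(dominance_threshold),
                               units = "class", name = "dominance"),
       curve = curve)
}

#' Harvested-area fractions with significant drivers
#'
#' Percentage of cropland (harvested-area weighted, over cells where the
#' attribution is defined) where the yield gain is significantly
#' partially correlated with precipitation, and with PET.
#'
#' @param drivers A `driver_map`.
#' @param crop Crop layer.
#' @param alpha Significance level (default 0.05).
#' @return A list with `pct_map_significant`, `pct_pet_significant`.
#' @export
driver_significance_fractions <- function(drivers, crop, alpha = 0.05) {
  check_same_grid(drivers$p_map, crop$harvested_area)
  w <- crop$harvested_area$values
  valid <- !is.na(drivers$p_map$values) & !is.na(drivers$p_pet$values) &
    !is.na(w) & w > 0
  wtot <- sum(w[valid])
  if (wtot <= 0) stop("no attributed cropland cells")
  list(
    pct_map_significant =
      100 * sum(w[valid & drivers$p_map$values < alpha]) / wtot,
    pct_pet_significant =
      100 * sum(w[valid & drivers$p_pet$values < alpha]) / wtot
  )
}
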