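#' Mean-squared-deviation decomposition
#'
#' Decomposes the mean squared deviation between two maps into squared
#' bias plus mean squared variation (pattern error):
#' `MSD = mean((x - y)^2)`, `SB = (mean(x) - mean(y))^2`,
#' `MSV = mean(((x - mean(x)) - (y - mean(y)))^2)`, so `MSD = SB + MSV`
#' identically. Computed unweighted over jointly valid cells.
#'
#' @param x,y Rasters on one grid with at least 2 jointly valid cells.
#' @return A list with `msd`, `sb`, `msv`, `n_cells`.
#' @export
msd_decompose <- function(x, y) {
  check_same_grid(x, y)
  ok <- !is.na(x$values) & !is.na(y$values)
  n <- sum(ok)
  if (n < 2) stop("empty domain: need at least 2 jointly valid cells")
  xv <- x$values[ok]; yv <- y$values[ok]
  msd <- mean((xv - yv)^2)
  sb <- (mean(xv) - mean(yv))^2
  msv <- mean(((xv - mean(xv)) - (yv - mean(yv)))^2)
  list(msd = msd, sb = sb, msv = msv, n_cells = n)
}

#' Pattern correlation between two maps
#'
#' Pearson correlation over jointly valid cells, with a two-tailed
#' p-value from the t transform on `n - 2` degrees of freedom.
#'
#' @param x,y Rasters on one grid; >= 3 jointly valid cells and nonzero
#'   variance in both.
#' @return A list with `r`, `p`, `n`.
#' @export
pattern_correlation <- function(x, y) {
  check_same_grid(x, y)
  ok <- !is.na(x$values) & !is.na(y$values)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 jointly valid cells")
  xv <- x$values[ok]; yv <- y$values[ok]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("undefined correlation: zero variance")
  }
  r <- stats::cor(xv, yv)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Evaluate candidate maps against a reference
#'
#' Computes the MSD decomposition and pattern correlation of each
#' candidate against the reference on the intersection mask of all maps,
#' so every candidate is scored on the same cells.
#'
#' @param candidates Named list of rasters.
#' @param reference Reference raster.
#' @return A data.frame with one row per candidate: `candidate`, `n`,
#'   `msd`, `sb`, `msv`, `r`, `p`.
#' @export
evaluate_against_reference <- function(candidates, reference) {
  stopifnot(length(candidates) >= 1, !is.null(names(candidates)))
  g <- do.call(check_same_grid, c(candidates, list(reference)))
  common <- !is.na(reference$values)
  for (cand in candidates) common <- common & !is.na(cand$values)
  mask <- ifelse(common, 1, NA_real_)
  ref <- make_raster(g, reference$values * mask, units = reference$units)
  rows <- lapply(names(candidates), function(nm) {
    cnd <- make_raster(g, candidates[[nm]]$values * mask,
                       units = candidates[[nm]]$units)
    d <- msd_decompose(cnd, ref)
    pc <- pattern_correlation(cnd, ref)
    data.frame(candidate = nm, n = d$n_cells, msd = d$msd, sb = d$sb,
               msv = d$msv, r = pc$r, p = pc$p)
  })
  do.call(rbind, rows)
}

#' Fraction conversions for reporting
#'
#' The yield gain is stored as a fraction internally and reported in
#' percentage points; conversions are exact factors of 100 (squared
#' quantities use 100^2).
#'
#' @param x Numeric (fractions or squared fractions).
#' @return Numeric in percentage points (or pp^2).
#' @export
as_percent <- function(x) 100 * x

#' @rdname as_percent
#' @export
as_percent_squared <- function(x) 1e4 * x
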