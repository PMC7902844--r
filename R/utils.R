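# Internal numeric helpers shared across modules.

# Separable Gaussian smoothing of a matrix field. Rows (latitude) are
# truncated at the domain edge with kernel renormalization; columns
# (longitude) wrap when the grid spans 360 degrees.
gaussian_smooth <- function(m, sigma, wrap_lon = TRUE) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth_dim <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    acc <- matrix(0, nrow(m), ncol(m))
    wacc <- matrix(0, nrow(m), ncol(m))
    for (j in -r:r) {
      wt <- k[j + r + 1]
      idx <- seq_len(n) + j
      if (!along_rows && wrap_lon) idx <- ((idx - 1) %% n) + 1
      ok <- idx >= 1 & idx <= n
      if (!any(ok)) next
      if (along_rows) {
        acc[ok, ] <- acc[ok, ] + wt * m[idx[ok], , drop = FALSE]
        wacc[ok, ] <- wacc[ok, ] + wt
      } else {
        acc[, ok] <- acc[, ok] + wt * m[, idx[ok], drop = FALSE]
        wacc[, ok] <- wacc[, ok] + wt
      }
    }
    acc / wacc
  }
  smooth_dim(smooth_dim(m, TRUE), FALSE)
}

# Spatially correlated noise field: Gaussian-smoothed white noise,
# rescaled so the pointwise (empirical) sd equals `sd`. Consumes the
# current RNG stream; callers seed it.
spatial_noise <- function(grid, sd = 1, smooth_sigma = 1.5) {
  wrap <- abs((grid$lon_max - grid$lon_min) - 360) < 1e-9
  z <- matrix(stats::rnorm(grid$nlat * grid$nlon), grid$nlat, grid$nlon)
  z <- gaussian_smooth(z, smooth_sigma, wrap_lon = wrap)
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s
  z * sd
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Row-wise log-sum-exp for a matrix of log terms (NA terms are skipped).
row_logsumexp <- function(lg) {
  mx <- apply(lg, 1, max, na.rm = TRUE)
  mx + log(rowSums(exp(lg - mx), na.rm = TRUE))
}

# FNV-1a 32-bit hash of a character scalar; used to fingerprint run
# configurations without external dependencies.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime, split to stay exact in
    # double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

days_in_month <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
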