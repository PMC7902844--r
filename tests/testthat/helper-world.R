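# Shared fixtures, built once per test run.

# Default synthetic world at the package's standard 2-degree study
# resolution.
default_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_world(synthetic_config(seed = 1))
    cache
  }
})

# Small fast world for property sweeps.
small_config <- function(seed = 1, ...) {
  synthetic_config(grid = grid_spec(resolution = 4), seed = seed,
                   n_basins = 20L, ...)
}

# 2-member, 50-cell toy fusion problems used by the EM / grid-search /
# MCMC agreement checks. The default offset gives an interior optimum; a
# larger offset separates the members enough that the posterior
# concentrates sharply.
toy_fusion_2member <- function(seed = 42, offset = 0.08) {
  g <- grid_spec(0, 5, 0, 10, 1)
  set.seed(seed)
  n <- 50
  tv <- matrix(stats::runif(n, 0.1, 0.6), 5, 10)
  obs <- make_raster(g, tv + stats::rnorm(n, 0, 0.05))
  m1 <- make_raster(g, tv + stats::rnorm(n, 0, 0.04))
  m2 <- make_raster(g, tv + offset + stats::rnorm(n, 0, 0.08))
  list(stack = ensemble_stack(c("a", "b"), list(m1, m2)), obs = obs)
}

toy_fusion_3member <- function(seed = 11) {
  g <- grid_spec(0, 5, 0, 10, 1)
  set.seed(seed)
  n <- 50
  tv <- matrix(stats::runif(n, 0.1, 0.6), 5, 10)
  obs <- make_raster(g, tv + stats::rnorm(n, 0, 0.06))
  m1 <- make_raster(g, tv + stats::rnorm(n, 0, 0.05))
  m2 <- make_raster(g, tv + stats::rnorm(n, 0, 0.05))
  m3 <- make_raster(g, tv + 0.05 + stats::rnorm(n, 0, 0.07))
  list(stack = ensemble_stack(c("a", "b", "c"), list(m1, m2, m3)),
       obs = obs)
}

# Brute-force weighted percentile: scan unique values ascending, return
# the first whose cumulative weight share reaches q.
oracle_weighted_percentile <- function(values, weights, q) {
  tot <- sum(weights)
  for (v in sort(unique(values))) {
    if (sum(weights[values <= v]) / tot >= q) return(v)
  }
  stop("unreachable")
}

# Simplex grid search maximizing the BMA log-likelihood at fixed sigma.
grid_search_weights <- function(stack, obs, sigma, step = 0.001) {
  k <- length(stack$members)
  ok <- !is.na(obs$values)
  M <- vapply(stack$members, function(r) r$values[ok], numeric(sum(ok)))
  o <- obs$values[ok]
  D <- vapply(seq_len(k), function(i) stats::dnorm(o, M[, i], sigma),
              numeric(length(o)))
  m <- round(1 / step)
  if (k == 2) {
    W <- cbind(0:m, m - (0:m)) / m
  } else if (k == 3) {
    i <- unlist(lapply(0:m, function(a) rep(a, m - a + 1)))
    j <- unlist(lapply(0:m, function(a) 0:(m - a)))
    W <- cbind(i, j, m - i - j) / m
  } else stop("grid search supports 2 or 3 members")
  best <- -Inf
  bw <- NULL
  for (ch in split(seq_len(nrow(W)), (seq_len(nrow(W)) - 1) %/% 60000)) {
    s <- rowSums(log(W[ch, , drop = FALSE] %*% t(D)))
    kbest <- which.max(s)
    if (s[kbest] > best) {
      best <- s[kbest]
      bw <- W[ch[kbest], ]
    }
  }
  bw
}
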