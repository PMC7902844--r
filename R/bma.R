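#' Bundle ensemble member fields
#'
#' @param member_ids Character vector of member identifiers.
#' @param members List of rasters, one per member, all on one grid.
#' @param variable Which quantity the members carry (`"delta_y"` or
#'   `"demand"`).
#' @return An `ensemble_stack`.
#' @export
ensemble_stack <- function(member_ids, members, variable = "delta_y") {
  stopifnot(length(member_ids) == length(members), length(members) >= 1)
  g <- do.call(check_same_grid, members)
  structure(list(member_ids = member_ids, members = members,
                 variable = variable, grid = g),
            class = "ensemble_stack")
}

#' @export
print.ensemble_stack <- function(x, ...) {
  cat(sprintf("ensemble_stack (%s): %d members on %d x %d grid\n",
              x$variable, length(x$members), x$grid$nlat, x$grid$nlon))
  invisible(x)
}

# Matrix view (cells x members) over cells where the observation is valid.
stack_matrix <- function(stack, obs) {
  check_same_grid(stack$members[[1]], obs)
  ok <- !is.na(obs$values)
  M <- vapply(stack$members, function(r) r$values[ok],
              numeric(sum(ok)))
  list(M = as.matrix(M), o = obs$values[ok], ok = ok)
}

#' BMA mixture log-likelihood
#'
#' `sum_cells log sum_i w_i N(O_cell | M_i_cell, sigma^2)`; cells are
#' weighted equally and masked cells skipped. Where a member is masked at
#' a cell its component is dropped and the remaining weights renormalized
#' for that cell.
#'
#' @param stack An [ensemble_stack()].
#' @param obs Observation raster on the same grid.
#' @param w Member weights on the simplex.
#' @param sigma Likelihood scale (> 0), in the units of the field.
#' @return Log-likelihood (a single number).
#' @export
bma_log_likelihood <- function(stack, obs, w, sigma) {
  stopifnot(length(w) == length(stack$members), all(w >= 0), sigma > 0)
  sm <- stack_matrix(stack, obs)
  if (length(sm$o) == 0) stop("empty domain: no jointly valid cells")
  w <- w / sum(w)
  n <- length(sm$o)
  k <- ncol(sm$M)
  kernel <- matrix(stats::dnorm(sm$o, sm$M, sigma, log = TRUE), n, k)
  lg <- kernel + rep(log(w), each = n)
  avail <- !is.na(sm$M)
  if (!all(avail)) {
    # per-cell weight renormalization over available members
    wm <- matrix(w, n, k, byrow = TRUE)
    wm[!avail] <- 0
    lg <- kernel + log(wm / rowSums(wm))
  }
  keep <- rowSums(avail) > 0
  sum(row_logsumexp(lg[keep, , drop = FALSE]))
}

#' Fit BMA weights by expectation-maximization
#'
#' Gaussian mixture with member-specific means (the member fields) and a
#' single shared scale `sigma`: E-step computes per-cell membership
#' responsibilities, M-step sets each weight to its mean responsibility
#' and `sigma` to the responsibility-weighted RMS residual. The
#' log-likelihood is non-decreasing across iterations; iteration stops
#' when its change falls below `tol`.
#'
#' @param stack An [ensemble_stack()] (>= 2 members).
#' @param obs Observation raster (>= 10 jointly valid cells).
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Iteration cap; exceeding it returns
#'   `converged = FALSE` with the last state.
#' @return A `bma_weights` object: `w`, `sigma`, `method`, `n_iter`,
#'   `converged`, `log_likelihood`, `ll_trace`, `member_ids`.
#' @export
fit_bma_em <- function(stack, obs, tol = 1e-8, max_iter = 500) {
  stopifnot(length(stack$members) >= 2)
  sm <- stack_matrix(stack, obs)
  keep <- rowSums(!is.na(sm$M)) > 0
  M <- sm$M[keep, , drop = FALSE]
  o <- sm$o[keep]
  n <- length(o)
  if (n < 10) stop("need at least 10 jointly valid cells")
  k <- ncol(M)
  resid <- M - o
  w <- rep(1 / k, k)
  sigma <- max(stats::sd(as.vector(resid), na.rm = TRUE), 1e-8)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  avail <- !is.na(M)
  R2 <- resid^2
  R2[!avail] <- 0 # masked components carry zero responsibility below
  for (iter in seq_len(max_iter)) {
    # Gaussian log kernel from the precomputed squared residuals
    lg <- -0.5 * log(2 * pi * sigma^2) - R2 / (2 * sigma^2) +
      rep(log(w), each = n)
    lg[!avail] <- -Inf
    mx <- lg[, 1]
    for (cc in seq_len(k)[-1]) mx <- pmax(mx, lg[, cc])
    lse <- mx + log(rowSums(exp(lg - mx)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    z <- exp(lg - lse)
    w <- colSums(z) / sum(z)
    w <- pmax(w, 1e-300)
    w <- w / sum(w)
    sigma <- max(sqrt(sum(z * R2) / sum(z)), 1e-8)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  structure(list(w = as.numeric(w), sigma = sigma, method = "em",
                 n_iter = iter, converged = converged,
                 log_likelihood = ll_trace[length(ll_trace)],
                 ll_trace = ll_trace, member_ids = stack$member_ids),
            class = "bma_weights")
}

# log density of a Dirichlet(alpha) at w (both on the open simplex)
ddirichlet_log <- function(w, alpha) {
  sum((alpha - 1) * log(w)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

#' Fit BMA weights by Metropolis sampling
#'
#' Random-walk Metropolis on `(w, log sigma)` with a uniform prior over
#' the weight simplex. Weight proposals are Dirichlet perturbations
#' centred on the current weights; the asymmetric-kernel Hastings
#' correction is applied. The chain is initialized at the EM point
#' estimate; reported weights are the posterior mean over post-burn-in
#' samples.
#'
#' @param stack,obs As for [fit_bma_em()].
#' @param n_samples Total chain length.
#' @param burn_in Samples discarded before averaging.
#' @param seed Integer seed: identical inputs and seed give identical
#'   output.
#' @param proposal_conc Dirichlet proposal concentration (larger =
#'   smaller steps).
#' @param sigma_step SD of the log-sigma random-walk step.
#' @return A `bma_weights` object with `method = "mcmc"` and an
#'   `acceptance_rate` diagnostic (healthy chains fall in \[0.1, 0.6\]).
#' @export
fit_bma_mcmc <- function(stack, obs, n_samples = 4000, burn_in = 1000,
                         seed = 1L, proposal_conc = 150, sigma_step = 0.15) {
  em <- fit_bma_em(stack, obs)
  set.seed(as.integer(seed))
  k <- length(em$w)
  eps <- 1e-6
  w <- pmax(em$w, eps); w <- w / sum(w)
  ls <- log(em$sigma)
  ll <- bma_log_likelihood(stack, obs, w, exp(ls))
  draws_w <- matrix(NA_real_, n_samples, k)
  draws_s <- numeric(n_samples)
  n_acc <- 0
  for (s in seq_len(n_samples)) {
    a_fwd <- proposal_conc * w + 0.5
    gam <- stats::rgamma(k, shape = a_fwd)
    w_new <- pmax(gam / sum(gam), 1e-12)
    w_new <- w_new / sum(w_new)
    a_rev <- proposal_conc * w_new + 0.5
    ls_new <- ls + stats::rnorm(1, 0, sigma_step)
    ll_new <- bma_log_likelihood(stack, obs, w_new, exp(ls_new))
    log_alpha <- ll_new - ll +
      ddirichlet_log(w, a_rev) - ddirichlet_log(w_new, a_fwd)
    if (is.finite(log_alpha) && log(stats::runif(1)) < log_alpha) {
      w <- w_new; ls <- ls_new; ll <- ll_new
      n_acc <- n_acc + 1
    }
    draws_w[s, ] <- w
    draws_s[s] <- exp(ls)
  }
  acc <- n_acc / n_samples
  if (acc < 0.01) {
    stop(sprintf(paste0("pathological acceptance rate %.4f; adjust ",
                        "proposal_conc or sigma_step"), acc))
  }
  post <- seq(burn_in + 1, n_samples)
  w_mean <- colMeans(draws_w[post, , drop = FALSE])
  w_mean <- w_mean / sum(w_mean)
  structure(list(w = as.numeric(w_mean), sigma = mean(draws_s[post]),
                 method = "mcmc", n_iter = n_samples, converged = TRUE,
                 log_likelihood = ll, acceptance_rate = acc,
                 em_init = em$w, member_ids = stack$member_ids),
            class = "bma_weights")
}

#' @export
print.bma_weights <- function(x, ...) {
  cat(sprintf("bma_weights (%s): sigma = %.4g, logLik = %.4g\n",
              x$method, x$sigma, x$log_likelihood))
  print(round(stats::setNames(x$w, x$member_ids), 4))
  invisible(x)
}

#' Posterior-weighted reanalysis of an ensemble
#'
#' Per cell: mean `sum_i w_i M_i` and posterior predictive spread
#' `sqrt(sum_i w_i (M_i - mean)^2 + sigma^2)` (mixture spread). Cells
#' where a member is masked use the remaining members with renormalized
#' weights.
#'
#' @param stack An [ensemble_stack()].
#' @param weights A `bma_weights` object fitted to a compatible stack.
#' @return A `reanalysis`: rasters `mean` and `sd`, plus the weights.
#' @export
bma_predict <- function(stack, weights) {
  stopifnot(inherits(weights, "bma_weights"),
            length(weights$w) == length(stack$members))
  g <- stack$grid
  n <- g$nlat * g$nlon
  M <- vapply(stack$members, function(r) as.vector(r$values), numeric(n))
  avail <- !is.na(M)
  wm <- matrix(weights$w, n, ncol(M), byrow = TRUE)
  wm[!avail] <- 0
  tot <- rowSums(wm)
  wm <- wm / ifelse(tot > 0, tot, 1)
  M0 <- ifelse(avail, M, 0)
  mu <- rowSums(wm * M0)
  mu[tot == 0] <- NA_real_
  v <- rowSums(wm * (M0 - mu)^2, na.rm = TRUE) + weights$sigma^2
  v[tot == 0] <- NA_real_
  structure(list(
    mean = make_raster(g, matrix(mu, g$nlat, g$nlon),
                       units = stack$members[[1]]$units,
                       name = paste0(stack$variable, "_reanalysis")),
    sd = make_raster(g, matrix(sqrt(v), g$nlat, g$nlon),
                     units = stack$members[[1]]$units,
                     name = paste0(stack$variable, "_reanalysis_sd")),
    weights = weights
  ), class = "reanalysis")
}

#' Reanalyze water demand with yield-gain weights
#'
#' Applies weights fitted on the yield-gain fields to the member water
#' demand fields without refitting, keeping the reanalyzed demand
#' consistent with the reanalyzed yield gain.
#'
#' @param demand_stack An [ensemble_stack()] of member demand fields; its
#'   member ids must match those the weights were fitted on.
#' @param weights A `bma_weights` object.
#' @return The weighted-mean demand raster.
#' @export
reanalyze_demand <- function(demand_stack, weights) {
  if (!identical(demand_stack$member_ids, weights$member_ids)) {
    stop("demand stack member ids do not match the fitted weights")
  }
  bma_predict(demand_stack, weights)$mean
}
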