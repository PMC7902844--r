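test_that("the mixture log-likelihood matches direct evaluation", {
  g <- grid_spec(0, 1, 0, 3, 1)
  obs <- make_raster(g, matrix(c(0.2, 0.4, 0.6), 1, 3))
  m1 <- make_raster(g, matrix(c(0.25, 0.35, 0.55), 1, 3))
  m2 <- make_raster(g, matrix(c(0.1, 0.5, 0.7), 1, 3))
  st <- ensemble_stack(c("a", "b"), list(m1, m2))
  w <- c(0.3, 0.7); sigma <- 0.1
  direct <- sum(log(
    w[1] * dnorm(c(0.2, 0.4, 0.6), c(0.25, 0.35, 0.55), sigma) +
      w[2] * dnorm(c(0.2, 0.4, 0.6), c(0.1, 0.5, 0.7), sigma)
  ))
  expect_equal(bma_log_likelihood(st, obs, w, sigma), direct,
               tolerance = 1e-12)

  # single member reduces to a Gaussian log-density sum
  st1 <- ensemble_stack("a", list(m1))
  expect_equal(bma_log_likelihood(st1, obs, 1, sigma),
               sum(dnorm(c(0.2, 0.4, 0.6), c(0.25, 0.35, 0.55), sigma,
                         log = TRUE)),
               tolerance = 1e-12)

  # duplicating a member and splitting its weight changes nothing
  st3 <- ensemble_stack(c("a", "a2", "b"), list(m1, m1, m2))
  expect_equal(bma_log_likelihood(st3, obs, c(0.15, 0.15, 0.7), sigma),
               bma_log_likelihood(st, obs, w, sigma), tolerance = 1e-12)

  allna <- make_raster(g, NA_real_)
  expect_error(bma_log_likelihood(st, allna, w, sigma), "empty domain")
})

test_that("EM concentrates weight on a member matching the observation", {
  g <- grid_spec(0, 5, 0, 10, 1)
  set.seed(21)
  tv <- matrix(runif(50, 0.2, 0.5), 5, 10)
  obs <- make_raster(g, tv)
  m1 <- make_raster(g, tv + rnorm(50, 0, 0.001))
  m2 <- make_raster(g, tv + 0.5) # offset by >> 10 sigma
  st <- ensemble_stack(c("good", "bad"), list(m1, m2))
  fit <- fit_bma_em(st, obs)
  expect_gt(fit$w[1], 0.99)

  # two identical members split the weight evenly
  st2 <- ensemble_stack(c("a", "b"), list(m1, m1))
  fit2 <- fit_bma_em(st2, obs)
  expect_equal(fit2$w, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("EM log-likelihood is monotone and matches the simplex grid search", {
  toy2 <- toy_fusion_2member()
  em2 <- fit_bma_em(toy2$stack, toy2$obs)
  expect_true(all(diff(em2$ll_trace) >= -1e-7))
  gw2 <- grid_search_weights(toy2$stack, toy2$obs, em2$sigma)
  expect_lt(max(abs(em2$w - gw2)), 0.01)

  toy3 <- toy_fusion_3member()
  em3 <- fit_bma_em(toy3$stack, toy3$obs)
  expect_true(all(diff(em3$ll_trace) >= -1e-7))
  gw3 <- grid_search_weights(toy3$stack, toy3$obs, em3$sigma)
  expect_lt(max(abs(em3$w - gw3)), 0.01)
})

test_that("the Metropolis sampler is seeded, healthy, and agrees with EM", {
  toy <- toy_fusion_2member(42, offset = 0.25)
  mc1 <- fit_bma_mcmc(toy$stack, toy$obs, seed = 7)
  mc2 <- fit_bma_mcmc(toy$stack, toy$obs, seed = 7)
  expect_identical(mc1$w, mc2$w)
  expect_gt(mc1$acceptance_rate, 0.05)

  em <- fit_bma_em(toy$stack, toy$obs)
  expect_lt(max(abs(mc1$w - em$w)), 0.05)

  # near-perfect member among biased ones takes almost all posterior mass
  g <- grid_spec(0, 5, 0, 10, 1)
  set.seed(31)
  tv <- matrix(runif(50, 0.2, 0.5), 5, 10)
  obs <- make_raster(g, tv + rnorm(50, 0, 0.001))
  st <- ensemble_stack(c("good", "b1", "b2"),
                       list(make_raster(g, tv),
                            make_raster(g, tv + 0.4),
                            make_raster(g, tv - 0.3)))
  mc <- fit_bma_mcmc(st, obs, seed = 5)
  expect_gt(mc$w[1], 0.9)
})

test_that("prediction is the weighted mixture mean with mixture spread", {
  g <- grid_spec(0, 1, 0, 2, 1)
  m1 <- make_raster(g, matrix(c(0.2, 0.3), 1, 2))
  m2 <- make_raster(g, matrix(c(0.6, 0.5), 1, 2))
  st <- ensemble_stack(c("a", "b"), list(m1, m2))
  wts <- structure(list(w = c(0.25, 0.75), sigma = 0.05, method = "em",
                        member_ids = c("a", "b")), class = "bma_weights")
  pred <- bma_predict(st, wts)
  expect_equal(pred$mean$values[1, 1], 0.25 * 0.2 + 0.75 * 0.6) # = 0.5
  expect_equal(pred$mean$values[1, 2], 0.25 * 0.3 + 0.75 * 0.5)
  expected_sd <- sqrt(0.25 * (0.2 - 0.5)^2 + 0.75 * (0.6 - 0.5)^2 + 0.05^2)
  expect_equal(pred$sd$values[1, 1], expected_sd, tolerance = 1e-12)

  # all weight on one member reproduces it
  wts1 <- structure(list(w = c(1, 0), sigma = 0.01, method = "em",
                         member_ids = c("a", "b")), class = "bma_weights")
  expect_equal(bma_predict(st, wts1)$mean$values, m1$values)

  # equal weights give the ensemble average
  wts2 <- structure(list(w = c(0.5, 0.5), sigma = 0.01, method = "em",
                         member_ids = c("a", "b")), class = "bma_weights")
  expect_equal(bma_predict(st, wts2)$mean$values, (m1$values + m2$values) / 2)

  # linearity: scaling the stack scales the mean
  st_scaled <- ensemble_stack(c("a", "b"),
                              list(make_raster(g, m1$values * 3),
                                   make_raster(g, m2$values * 3)))
  expect_equal(bma_predict(st_scaled, wts)$mean$values,
               pred$mean$values * 3, tolerance = 1e-12)
})

test_that("demand reanalysis reuses the yield-gain weights without refit", {
  g <- grid_spec(0, 1, 0, 2, 1)
  d1 <- make_raster(g, matrix(100, 1, 2), units = "mm/yr")
  d2 <- make_raster(g, matrix(200, 1, 2), units = "mm/yr")
  st <- ensemble_stack(c("a", "b"), list(d1, d2), variable = "demand")
  wts <- structure(list(w = c(0.5, 0.5), sigma = 0.1, method = "em",
                        member_ids = c("a", "b")), class = "bma_weights")
  out <- reanalyze_demand(st, wts)
  expect_equal(out$values, matrix(150, 1, 2))

  wts_bad <- wts; wts_bad$member_ids <- c("a", "zzz")
  expect_error(reanalyze_demand(st, wts_bad), "member ids")
})

test_that("weights order by inverse member noise on synthetic ensembles", {
  hits <- 0
  n_rep <- 50
  for (s in seq_len(n_rep)) {
    cfg <- synthetic_config(grid = grid_spec(resolution = 4), seed = s,
                            n_members = 3,
                            member_gain = c(1, 1, 1),
                            member_offset = c(0, 0, 0),
                            member_noise_sd = c(0.02, 0.05, 0.10),
                            ca_noise_sd = 0.02,
                            n_basins = 10L)
    cl <- gen_climate(cfg)
    tr <- gen_truth(cfg, cl)
    ens <- gen_ensemble(cfg, tr)
    obs <- gen_ca_observation(cfg, tr)
    fit <- fit_bma_em(ens, obs)
    if (all(order(fit$w, decreasing = TRUE) == 1:3)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("the reanalysis beats or matches the best single member", {
  w <- default_world()
  fit <- fit_bma_em(w$ensemble, w$ca_obs)
  rea <- bma_predict(w$ensemble, fit)
  msd_members <- vapply(w$ensemble$members, function(m) {
    msd_decompose(m, w$truth$delta_y_true)$msd
  }, numeric(1))
  msd_rea <- msd_decompose(rea$mean, w$truth$delta_y_true)$msd
  expect_lte(msd_rea, 1.05 * min(msd_members))
})
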