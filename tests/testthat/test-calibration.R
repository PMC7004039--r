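test_that("the variance-normalized deviation behaves like an efficiency", {
  set.seed(12)
  obs <- matrix(runif(60, 0, 0.8), 20, 3)
  # perfect predictions
  fit <- nmsd(obs, obs)
  expect_equal(fit$deviation, 0)
  expect_equal(fit$H2, 1)
  # noisy predictions are penalized
  expect_gt(nmsd(obs + 0.1, obs)$deviation, 0)
  # predicting each type's mean gives exactly zero efficiency
  pred <- matrix(colMeans(obs), 20, 3, byrow = TRUE)
  expect_equal(nmsd(pred, obs)$H2, 0)
})

test_that("the old-field objective is zero on exact data and order-invariant", {
  spec <- synth_oldfield_spec(n_sites = 25, noise_sd = 0, seed = 4)
  obs <- generate_oldfield(spec)
  f <- oldfield_objective(obs, spec$params, free = "c1",
                          init_covers = spec$init_covers)
  expect_equal(f(spec$params$c[1]), 0, tolerance = 1e-8)
  expect_gt(f(0.08), 0)
  # shuffling records leaves the objective unchanged
  g <- oldfield_objective(obs[sample(nrow(obs)), ], spec$params, free = "c1",
                          init_covers = spec$init_covers)
  expect_equal(g(0.06), f(0.06))
  expect_error(oldfield_objective(obs[0, ], spec$params), "empty")
})

test_that("duplicating every site doubles the raw deviation", {
  spec <- synth_oldfield_spec(n_sites = 15, noise_sd = 0.05, seed = 8)
  obs <- generate_oldfield(spec)
  f1 <- oldfield_objective(obs, spec$params, free = "c1",
                           init_covers = spec$init_covers)
  f2 <- oldfield_objective(rbind(obs, obs), spec$params, free = "c1",
                           init_covers = spec$init_covers)
  expect_equal(f2(0.047), 2 * f1(0.047), tolerance = 1e-8)
})

test_that("annealing minimizes a quadratic bowl and tracks its best point", {
  bowl <- function(x) sum((x - c(0.3, -0.2))^2)
  res <- anneal(bowl, par0 = c(0.9, 0.9), lower = c(-1, -1),
                upper = c(1, 1), control = anneal_control(steps = 5000),
                seed = 2)
  expect_lt(max(abs(res$par - c(0.3, -0.2))), 1e-2)
  # best-ever is never worse than the last accepted point
  expect_lte(res$value, res$value_last)
  expect_true(all(diff(res$trace$best) <= 0))
  # same seed, same trace
  res2 <- anneal(bowl, par0 = c(0.9, 0.9), lower = c(-1, -1),
                 upper = c(1, 1), control = anneal_control(steps = 5000),
                 seed = 2)
  expect_identical(res$trace, res2$trace)
  expect_error(anneal(function(x) NaN, 0, -1, 1), "finite")
})

test_that("annealing agrees with an independent stochastic optimizer", {
  # cross-check on a 2-parameter calibration surface against optim(SANN):
  # our annealer must do at least as well as the reference implementation
  # and land on the generating colonization rate
  spec <- synth_oldfield_spec(n_sites = 20, noise_sd = 0.02, seed = 5)
  obs <- generate_oldfield(spec)
  f <- oldfield_objective(obs, spec$params, free = c("c1", "c2"),
                          init_covers = spec$init_covers, dt = 1 / 24)
  ours <- anneal(f, c(0.1, 0.1), lower = c(0.005, 0.005),
                 upper = c(0.3, 0.3),
                 control = anneal_control(steps = 1500), seed = 3)
  set.seed(3)
  ref <- optim(c(0.1, 0.1), function(x) f(pmin(pmax(x, 0.005), 0.3)),
               method = "SANN",
               control = list(maxit = 1500, parscale = c(0.02, 0.02)))
  expect_lte(ours$value, ref$value + 1e-9)
  expect_lt(abs(ours$par[1] - 0.047) / 0.047, 0.15)
  # both optimizers agree the start point is far from optimal
  expect_lt(ref$value, f(c(0.1, 0.1)))
})

test_that("noise-free synthetic data are recovered with negligible bias", {
  spec <- synth_oldfield_spec(n_sites = 40, noise_sd = 0, seed = 21)
  obs <- generate_oldfield(spec)
  fit <- calibrate_oldfield(obs, free = "c1", lower = 0.01, upper = 0.2,
                            init_covers = spec$init_covers,
                            control = anneal_control(steps = 1200,
                                                     proposal_frac = 0.02),
                            seed = 6)
  expect_lt(abs(fit$par - 0.047) / 0.047, 0.01)
  expect_gt(fit$H2, 0.999)
})

test_that("fire-plot calibration pins the grass fire-response parameters", {
  spec <- synth_fireplot_spec(noise_sd = 0, seed = 31)
  obs <- generate_fireplots(spec)
  f <- fireplot_objective(obs, attr(obs, "schedules"), spec$params,
                          free = c("r6", "c6"),
                          init_covers = spec$init_covers)
  # truth is a global minimum of the objective surface
  expect_equal(f(c(0.4, 0.22)), 0, tolerance = 1e-6)
  expect_gt(f(c(0.2, 0.22)), f(c(0.4, 0.22)))
  expect_gt(f(c(0.4, 0.10)), f(c(0.4, 0.22)))
})

test_that("Monte Carlo envelopes cover the best fit and collapse without noise", {
  spec <- synth_oldfield_spec(n_sites = 12, noise_sd = 0, seed = 13)
  obs <- generate_oldfield(spec)
  env <- mc_uncertainty(obs, n_draws = 3, noise_sd = 0,
                        free = "c1", lower = 0.02, upper = 0.12,
                        control = anneal_control(steps = 250),
                        time_grid = seq(0, 60, by = 5), seed = 17,
                        dt = 1 / 24)
  expect_true(all(env$lower <= env$best + 1e-9))
  expect_true(all(env$upper >= env$best - 1e-9))
  # site bootstrap of noise-free data keeps the envelope tight
  expect_lt(max(env$upper - env$lower), 0.05)
  expect_error(mc_uncertainty(obs, n_draws = 1), "at least 2")
})
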