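test_that("no-fire integrations land on the closed-form equilibrium", {
  p <- plant_params()
  sim <- quick_nofire(p)
  endpoint <- unlist(sim$trajectory[nrow(sim$trajectory),
                                    c("Q", "P", "R", "U", "C", "B")])
  expect_equal(unname(endpoint), unname(equilibrium_no_fire(p)),
               tolerance = 1e-3)
  # single-type start converges to the single-species value
  sim1 <- quick_nofire(p, b0 = c(0.2, 0, 0, 0, 0, 0))
  expect_equal(sim1$trajectory$Q[1001], 1 - p$m[1] / p$c[1],
               tolerance = 1e-6)
  expect_equal(nrow(sim$fires), 0L)
})

test_that("runs are bit-reproducible under a seed and invariant-safe", {
  cfg <- run_config(duration = 400, seed = 99,
                    b0 = initial_communities()$mixed)
  a <- simulate_fires(config = cfg)
  b <- simulate_fires(config = cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$fires, b$fires)
  expect_simplex(a$trajectory)
  c2 <- simulate_fires(config = run_config(duration = 400, seed = 100,
                                           b0 = initial_communities()$mixed))
  expect_false(identical(a$fires, c2$fires))
})

test_that("halving the step leaves 1000-yr no-fire endpoints unchanged to 1e-6", {
  p <- plant_params()
  e1 <- quick_nofire(p, dt = 1 / 365)$trajectory[1001, 2:7]
  e2 <- quick_nofire(p, dt = 1 / 730)$trajectory[1001, 2:7]
  expect_lt(max(abs(unlist(e1) - unlist(e2))), 1e-6)
})

test_that("the fire log records consistent pre/post covers and intervals", {
  sim <- simulate_fires(config = run_config(duration = 3000, seed = 5,
                                            b0 = initial_communities()$mixed))
  f <- sim$fires
  expect_gt(nrow(f), 1)
  expect_named(f, c("t", "interval",
                    paste0("pre_", c("Q", "P", "R", "U", "C", "B")),
                    paste0("post_", c("Q", "P", "R", "U", "C", "B"))))
  p <- sim$params
  for (i in 1:6)
    expect_equal(f[[paste0("post_", p$names[i])]],
                 p$r[i] * f[[paste0("pre_", p$names[i])]])
  # first fire of a never-burned run has no preceding interval
  expect_true(is.na(f$interval[1]))
  if (nrow(f) > 1)
    expect_equal(f$interval[-1], diff(f$t), tolerance = 1e-8)
  expect_true(all(f$interval[-1] >= 2 - 1e-9))
})

test_that("scheduled burns fire exactly on time and pine reburns are sterile", {
  cfg <- run_config(duration = 40, fires = "scheduled",
                    fire_times = c(12, 17),
                    b0 = c(0, 0.3, 0, 0, 0, 0.2), tau0 = Inf)
  sim <- simulate_fires(config = cfg)
  expect_equal(sim$fires$t, c(12, 17), tolerance = 1 / 365)
  # first burn: mature stand (never burned), pine killed, grass resprouts
  expect_equal(sim$fires$post_P, c(0, 0))
  expect_equal(sim$fires$post_B[1], 0.4 * sim$fires$pre_B[1])
  # 5 yr later the stand is immature: no pine seeds, pines never return
  tr <- sim$trajectory
  expect_equal(tr$S_P[which.min(abs(tr$t - 13))], sim$fires$pre_P[1])
  expect_equal(tr$S_P[which.min(abs(tr$t - 18))], 0)
  expect_lt(max(tr$P[tr$t > 17]), 1e-6)
})

test_that("both waiting-time constructions give the exponential mean when covers are held", {
  # on bare ground the hazard is the constant epsilon, so realized
  # intervals must average 1/epsilon in either hazard mode
  for (mode in c("frozen", "instantaneous")) {
    cfg <- run_config(duration = 3e5, sample_every = 1000,
                      b0 = rep(0, 6), seed = 31, hazard_mode = mode,
                      dt = 1 / 12)
    p <- plant_params(epsilon = 0.01)
    sim <- simulate_fires(p, cfg)
    iv <- sim$fires$interval[-1]
    expect_gt(length(iv), 1000)
    expect_equal(mean(iv), 100, tolerance = 0.1)
  }
})
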