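test_that("fire hazard follows the cover-weighted flammability", {
  p <- plant_params()
  # bare ground burns at the baseline rate: mean return time 10^4 yr
  expect_equal(fire_hazard(rep(0, 6), p), 1e-4)
  # full grass cover: mean return ~10 yr
  expect_equal(1 / fire_hazard(c(0, 0, 0, 0, 0, 1), p), 1 / (0.1 + 1e-4))
  # mixed oak/grass stand, hand-computed
  lam <- fire_hazard(c(0.9, 0, 0, 0, 0, 0.05), p)
  expect_equal(lam, 0.9 / 400 + 0.05 / 10 + 1e-4)
  expect_equal(1 / lam, 136, tolerance = 0.01)
  # the vegetation term scales exactly with the flammability multiplier
  p3 <- apply_scenario(p, flam_mult = 3)
  b <- c(0.2, 0.1, 0.05, 0.05, 0.1, 0.2)
  expect_equal(fire_hazard(b, p3) - p$epsilon,
               3 * (fire_hazard(b, p) - p$epsilon))
})

test_that("waiting times are exponential with the prescribed mean and 2-yr floor", {
  set.seed(101)
  draws <- replicate(10000, sample_next_fire(0.01, t_last = 0,
                                             min_interval = 0))
  expect_gt(mean(draws), 95)
  expect_lt(mean(draws), 105)
  # a huge hazard cannot produce intervals under the enforced minimum
  set.seed(102)
  fast <- replicate(200, sample_next_fire(50, t_last = 10))
  expect_true(all(fast - 10 >= 2))
  expect_true(any(fast - 10 == 2))
  # bare-ground hazard: mean return time ~10^4 yr
  set.seed(103)
  slow <- replicate(4000, sample_next_fire(1e-4, t_last = 0))
  expect_equal(mean(slow), 1e4, tolerance = 0.05)
  # a time-varying hazard obeys the time-rescaling construction:
  # lambda(t) = 2t integrates to t^2, so waits are sqrt(Exp(1))
  set.seed(104)
  w <- replicate(2000, sample_next_fire(function(t) 2 * t, t_last = 0,
                                        min_interval = 0, dt = 1e-3))
  expect_equal(mean(w^2), 1, tolerance = 0.08)
})

test_that("fires kill seeders, spare a fraction of resprouters, and cue the pine bank", {
  p <- plant_params()
  rules <- seed_bank_rules()
  s <- ecosystem_state(b = c(0.5, 0.2, 0.1, 0, 0, 0.1), tau_fire = Inf)
  post <- apply_fire(s, p, rules)
  expect_equal(post$b, c(0.45, 0, 0, 0, 0, 0.04))
  expect_equal(post$tau_fire, 0)
  # mature pine stand releases its canopy bank
  m <- ecosystem_state(b = c(0, 0.6, 0, 0, 0, 0), tau_fire = 30)
  expect_equal(apply_fire(m, p, rules)$S[1], 0.6)
  # a reburn before maturity leaves no pine seeds
  y <- ecosystem_state(b = c(0, 0.6, 0, 0, 0, 0), tau_fire = 5)
  expect_equal(apply_fire(y, p, rules)$S[1], 0)
  # fires never increase cover
  expect_true(all(post$b <= s$b))
})

test_that("seed banks decay, saturate, and expire as specified", {
  rules <- seed_bank_rules()
  # pure decay with no standing shrubs
  s <- ecosystem_state(b = rep(0, 6), S = c(0, 1, 2, 3), tau_fire = 0)
  S5 <- seedbank_step(s, rules, dt = 5)
  expect_equal(S5[2:4], c(1, 2, 3) * exp(-0.2 * 5))
  # constant shrub cover drives the bank to production/decay * cover
  s2 <- ecosystem_state(b = c(0, 0, 0.3, 0, 0, 0), S = c(0, 0, 0, 0),
                        tau_fire = 0)
  Sbig <- seedbank_step(s2, rules, dt = 500)
  expect_equal(Sbig[2], 1 * 0.3 / 0.2, tolerance = 1e-8)
  # pine seeds released at a fire expire after ~2 yr
  s3 <- ecosystem_state(b = rep(0, 6), S = c(0.6, 0, 0, 0), tau_fire = 0)
  expect_equal(seedbank_step(s3, rules, dt = 1)[1], 0.6)
  expect_equal(seedbank_step(s3, rules, dt = 2.5)[1], 0)
})

test_that("post-fire establishment rates partition the conversion rate", {
  p <- plant_params()
  # a lone pine bank receives the whole conversion rate
  a <- postfire_alpha(c(0.4, 0, 0, 0), p)
  expect_equal(a, c(0, 0.014, 0, 0, 0, 0))
  # exhausted banks give no establishment
  expect_equal(postfire_alpha(rep(0, 4), p), rep(0, 6))
  # any positive banks: rates sum exactly to C
  set.seed(7)
  for (k in 1:30) {
    S <- runif(4, 0, 2) * rbinom(4, 1, 0.7)
    a <- postfire_alpha(S, p)
    expect_equal(a[c(1, 6)], c(0, 0))
    expect_true(isTRUE(all.equal(sum(a), 0.014)) ||
                  isTRUE(all.equal(sum(a), 0)))
  }
  # banks at or below the numerical floor count as exhausted
  expect_equal(postfire_alpha(c(1e-12, 0, 0, 0), p), rep(0, 6))
})
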