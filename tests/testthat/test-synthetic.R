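test_that("noise-free chronosequences lie on the generating trajectory", {
  spec <- synth_oldfield_spec(n_sites = 30, noise_sd = 0, seed = 2)
  obs <- generate_oldfield(spec)
  expect_equal(nrow(obs), 30)
  expect_true(all(obs$time_yr >= 1 & obs$time_yr <= 100))
  cfg <- run_config(duration = 101, sample_every = 0.25, fires = "none",
                    b0 = spec$init_covers)
  tr <- simulate_fires(spec$params, cfg)$trajectory
  oak_model <- approx(tr$t, tr$Q, xout = obs$time_yr)$y
  expect_equal(obs$cover_Q, oak_model, tolerance = 1e-6)
  # the generating truth travels with the data for recovery experiments
  expect_equal(attr(obs, "truth")$c, plant_params()$c)
})

test_that("noisy observations stay on the cover simplex", {
  obs <- generate_oldfield(synth_oldfield_spec(noise_sd = 0.3, seed = 3))
  cov <- as.matrix(obs[paste0("cover_", c("Q", "P", "R", "U", "C", "B"))])
  expect_equal(nrow(obs), 73)
  expect_true(all(cov >= 0 & cov <= 1))
  expect_true(all(rowSums(cov) <= 1 + 1e-9))
})

test_that("oak in a century-capped chronosequence stays below its equilibrium", {
  obs <- generate_oldfield(synth_oldfield_spec(noise_sd = 0, seed = 6))
  # oak crosses 0.5 only at ~105 yr, past the 100-yr age cap, so even the
  # oldest synthetic site sits well below the 0.947 equilibrium
  expect_lt(max(obs$cover_Q), 0.5)
  expect_gt(max(obs$cover_Q), 0.3)
})

test_that("synthetic fire plots burn on schedule", {
  spec <- synth_fireplot_spec(noise_sd = 0, seed = 9)
  obs <- generate_fireplots(spec)
  expect_equal(nrow(obs), 4 * 20)
  # right after each scheduled burn seeders are absent and grass is scorched
  one <- obs[obs$site == 3, ]  # burned at 5 and 10 yr
  pre <- one[one$time_yr == 5, ]
  post <- one[one$time_yr == 6, ]
  expect_lt(post$cover_P, 0.02)  # pines killed, barely re-established
  expect_lt(post$cover_B, pre$cover_B)
  # two burns 5 yr apart leave no viable pine seed: pines stay absent
  expect_lt(max(one$cover_P[one$time_yr > 10]), 1e-6)
})

test_that("without burns the fire-plot generator matches the chronosequence model", {
  spec <- synth_fireplot_spec(n_sites = 1, schedules = list(`1` = numeric()),
                              sampling_times = 1:15, noise_sd = 0, seed = 4)
  fp <- generate_fireplots(spec)
  cfg <- run_config(duration = 16, sample_every = 0.1, fires = "none",
                    b0 = spec$init_covers)
  tr <- simulate_fires(spec$params, cfg)$trajectory
  # oak and pine dynamics are independent of the (fire-mode-only)
  # establishment term, so the two generators must agree on them exactly;
  # shrub and grass covers pick up the small continuous establishment flux
  for (ty in c("Q", "P")) {
    model <- approx(tr$t, tr[[ty]], xout = 1:15)$y
    expect_equal(fp[[paste0("cover_", ty)]], model, tolerance = 1e-6,
                 info = ty)
  }
  # the continuous establishment flux (total C = 0.014/yr into free space)
  # lets the fire-mode run drift from the pure competition model in the
  # shrub/grass covers at a bounded rate
  model_B <- approx(tr$t, tr$B, xout = 1:15)$y
  expect_lt(max(abs(fp$cover_B - model_B)[1:8]), 0.02)
})

test_that("observation files round-trip losslessly", {
  obs <- generate_oldfield(synth_oldfield_spec(n_sites = 10, seed = 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_observations(obs, f)
  back <- read_observations(f)
  expect_equal(back$time_yr, obs$time_yr, tolerance = 1e-12)
  for (cl in paste0("cover_", c("Q", "P", "R", "U", "C", "B")))
    expect_equal(back[[cl]], obs[[cl]], tolerance = 1e-12, info = cl)
})
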