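# shared helpers for the suite

expect_simplex <- function(traj, slack = 1e-6) {
  b <- as.matrix(traj[, c("Q", "P", "R", "U", "C", "B")])
  expect_true(all(b >= -slack))
  expect_true(all(rowSums(b) <= 1 + slack))
}

# a quick no-fire run used by several tests; the pure competition model has
# no quasi-extinction rule, so transiently suppressed types may recover
quick_nofire <- function(params = plant_params(), duration = 1000,
                         b0 = initial_communities()$abandoned, dt = 1 / 365) {
  simulate_fires(params, run_config(duration = duration, dt = dt,
                                    fires = "none", b0 = b0,
                                    extinct_threshold = 0))
}

# draw a random parameter set whose no-fire equilibrium is numerically
# well-conditioned: every type is either clearly persisting or clearly
# excluded (all approach/decay rates >= rate_min), so a 1000-yr integration
# resolves the equilibrium to the tested tolerance
draw_conditioned_params <- function(rate_min = 0.015, max_tries = 200) {
  for (k in seq_len(max_tries)) {
    p <- plant_params(c = runif(6, 0.05, 0.3), m = runif(6, 0.002, 0.03))
    # margins of the sequential equilibrium recursion, before truncation
    b <- numeric(6)
    marg <- numeric(6)
    ok <- TRUE
    for (i in 1:6) {
      s <- 0
      j <- which(b[seq_len(i - 1)] > 0)
      if (length(j)) s <- sum(b[j] * (1 + p$c[j] / p$c[i]))
      marg[i] <- 1 - p$m[i] / p$c[i] - s
      b[i] <- max(0, marg[i])
      if (abs(marg[i]) * p$c[i] < rate_min) { ok <- FALSE; break }
    }
    if (ok) return(p)
  }
  stop("could not draw a well-conditioned parameter set")
}
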