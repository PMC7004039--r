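#' Variance-normalized mean-square deviation and goodness of fit
#'
#' Deviation between predicted and observed covers, pooled over plant types
#' after per-type normalization by the observed variance:
#' `D = sum_types sum_records (pred - obs)^2 / var_type(obs)`.
#' The associated goodness of fit is the efficiency
#' `H2 = 1 - D / sum_types n_type`, which equals 1 for a perfect fit, 0 for
#' a predictor that returns each type's observed mean, and can be negative
#' for worse predictors. Types with zero observed variance are skipped.
#'
#' @param pred Matrix of predicted covers (records x types).
#' @param obs Matrix of observed covers, same shape.
#' @return A list with `deviation` and `H2`.
#' @export
nmsd <- function(pred, obs) {
  pred <- as.matrix(pred)
  obs <- as.matrix(obs)
  stopifnot(identical(dim(pred), dim(obs)))
  dev <- 0
  ntot <- 0
  for (j in seq_len(ncol(obs))) {
    o <- obs[, j]
    n <- length(o)
    sstot <- sum((o - mean(o))^2)
    if (sstot <= 0) next  # uninformative type
    dev <- dev + sum((pred[, j] - o)^2) * n / sstot
    ntot <- ntot + n
  }
  list(deviation = dev, H2 = 1 - dev / ntot)
}

# Predict covers at the observation times of an old-field set: the no-fire
# competition model run once from the abandonment initial covers, linearly
# interpolated at each record's age.
predict_oldfield <- function(obs, params, init_covers, dt = 1 / 365,
                             sample_every = 0.25) {
  ages <- obs$time_yr
  cfg <- run_config(duration = max(ages) + sample_every, dt = dt,
                    sample_every = sample_every, fires = "none",
                    b0 = init_covers)
  tr <- simulate_fires(params, cfg)$trajectory
  vapply(PLANT_TYPES,
         function(ty) approx(tr$t, tr[[ty]], xout = ages, rule = 2)$y,
         numeric(length(ages)))
}

# Predict covers for fire-plot series: each plot simulated with its imposed
# burn schedule (deterministic events), establishment machinery active.
predict_fireplots <- function(obs, params, schedules, init_covers,
                              rules = seed_bank_rules(), dt = 1 / 365,
                              sample_every = 0.1) {
  out <- matrix(NA_real_, nrow(obs), 6, dimnames = list(NULL, PLANT_TYPES))
  for (site in unique(obs$site)) {
    sel <- obs$site == site
    times <- obs$time_yr[sel]
    cfg <- run_config(duration = max(times) + sample_every, dt = dt,
                      sample_every = sample_every, fires = "scheduled",
                      fire_times = schedules[[as.character(site)]],
                      b0 = init_covers)
    tr <- simulate_fires(params, cfg, rules)$trajectory
    for (ty in PLANT_TYPES)
      out[sel, ty] <- approx(tr$t, tr[[ty]], xout = times, rule = 2)$y
  }
  out
}

#' Calibration objective for old-field data
#'
#' Builds the scalar objective minimized by the annealer: given values for
#' the free parameters, run the no-fire competition model from the
#' configured abandonment initial covers and return the variance-normalized
#' mean-square deviation from the observations (see [nmsd()]).
#'
#' @param obs An observation set (see [read_observations()]) of kind
#'   `old-field`.
#' @param params Baseline [plant_params()]; free parameters overwrite it.
#' @param free Names of the free parameters, from
#'   `c1,c2,c3,c4,c5,c6,r1,r6,C_conv`.
#' @param init_covers Covers assumed at abandonment (t = 0).
#' @param types Plant types entering the deviation (default Q..C; the grass
#'   is calibrated against fire data, not the chronosequence).
#' @param dt Integration step for the model runs.
#' @return A function `f(par)` returning the deviation; its environment also
#'   exposes `h2(par)`.
#' @export
oldfield_objective <- function(obs, params = plant_params(),
                               free = paste0("c", 1:5),
                               init_covers = initial_communities()$abandoned,
                               types = PLANT_TYPES[1:5], dt = 1 / 365) {
  if (nrow(obs) == 0) stop("empty observation set")
  obs_mat <- as.matrix(obs[paste0("cover_", PLANT_TYPES)])
  colnames(obs_mat) <- PLANT_TYPES
  sel <- match(types, PLANT_TYPES)
  fit <- function(par) {
    p <- set_free_params(params, free, par)
    pred <- predict_oldfield(obs, p, init_covers, dt = dt)
    nmsd(pred[, sel, drop = FALSE], obs_mat[, sel, drop = FALSE])
  }
  f <- function(par) fit(par)$deviation
  environment(f)$h2 <- function(par) fit(par)$H2
  f
}

#' Calibration objective for fire-plot data
#'
#' As [oldfield_objective()], but each plot is simulated with its imposed
#' experimental burn schedule (fires as deterministic events at the recorded
#' times, not stochastic), with the post-fire establishment machinery
#' active. Used to calibrate `C_conv`, `r6` and `c6`.
#'
#' @inheritParams oldfield_objective
#' @param schedules Named list: burn times (yr) per site.
#' @param rules [seed_bank_rules()].
#' @export
fireplot_objective <- function(obs, schedules, params = plant_params(),
                               free = c("C_conv", "r6", "c6"),
                               init_covers = initial_communities()$abandoned,
                               types = PLANT_TYPES, rules = seed_bank_rules(),
                               dt = 1 / 365) {
  if (nrow(obs) == 0) stop("empty observation set")
  obs_mat <- as.matrix(obs[paste0("cover_", PLANT_TYPES)])
  colnames(obs_mat) <- PLANT_TYPES
  sel <- match(types, PLANT_TYPES)
  fit <- function(par) {
    p <- set_free_params(params, free, par)
    pred <- predict_fireplots(obs, p, schedules, init_covers, rules, dt = dt)
    nmsd(pred[, sel, drop = FALSE], obs_mat[, sel, drop = FALSE])
  }
  f <- function(par) fit(par)$deviation
  environment(f)$h2 <- function(par) fit(par)$H2
  f
}

# Overwrite named free parameters ("c1".."c6", "m1".., "r1", "r6", "l1"..,
# "gamma2".., "C_conv", "epsilon", "flam_mult") in a plant_params object.
set_free_params <- function(params, free, par) {
  stopifnot(length(free) == length(par))
  for (k in seq_along(free)) {
    nm <- free[k]
    if (nm %in% c("C_conv", "epsilon", "flam_mult")) {
      params[[nm]] <- par[k]
    } else {
      fld <- sub("[0-9]$", "", nm)
      idx <- as.integer(sub("^[a-z_]+", "", nm))
      params[[fld]][idx] <- par[k]
    }
  }
  validate_plant_params(params)
  params
}

#' Annealing schedule
#'
#' @param T0 Initial temperature (objective units; default 1).
#' @param cooling Geometric cooling factor per step (default 0.995).
#' @param steps Number of proposal steps (default 20,000).
#' @param proposal_frac Proposal scale as a fraction of each box width
#'   (default 0.05).
#' @return A list of class `anneal_control`.
#' @export
anneal_control <- function(T0 = 1, cooling = 0.995, steps = 20000,
                           proposal_frac = 0.05) {
  structure(list(T0 = T0, cooling = cooling, steps = steps,
                 proposal_frac = proposal_frac), class = "anneal_control")
}

#' Simulated annealing over a box
#'
#' Standard simulated annealing: uniform random perturbations within the box
#' bounds (reflected at the edges), Metropolis acceptance `exp(-delta/T)`,
#' geometric cooling, best-ever tracking. Reproducible given `seed`.
#'
#' @param fn Objective function of the parameter vector, to minimize.
#' @param par0 Start point.
#' @param lower,upper Box bounds.
#' @param control An [anneal_control()].
#' @param seed Optional integer seed.
#' @param trace_every Record the trace every this many steps (0 = no trace).
#' @return A list with `par` and `value` (best ever found), the final
#'   accepted point (`par_last`, `value_last`), acceptance rate and a trace
#'   data frame (`step, T, value, best`).
#' @export
anneal <- function(fn, par0, lower, upper, control = anneal_control(),
                   seed = NULL, trace_every = 100) {
  if (!is.null(seed)) set.seed(seed)
  par0 <- as.numeric(par0)
  d <- length(par0)
  stopifnot(length(lower) == d, length(upper) == d, all(upper > lower),
            all(par0 >= lower), all(par0 <= upper))
  f0 <- fn(par0)
  if (!is.finite(f0)) stop("objective not finite at the start point")
  width <- upper - lower
  cur <- par0; fcur <- f0
  best <- par0; fbest <- f0
  Temp <- control$T0
  n_acc <- 0L
  tr <- list()
  for (step in seq_len(control$steps)) {
    prop <- cur + runif(d, -1, 1) * control$proposal_frac * width
    # reflect at the box boundary
    prop <- ifelse(prop < lower, 2 * lower - prop, prop)
    prop <- ifelse(prop > upper, 2 * upper - prop, prop)
    prop <- pmin(pmax(prop, lower), upper)
    fprop <- fn(prop)
    if (is.finite(fprop) &&
        (fprop <= fcur || runif(1) < exp(-(fprop - fcur) / Temp))) {
      cur <- prop; fcur <- fprop
      n_acc <- n_acc + 1L
      if (fcur < fbest) { best <- cur; fbest <- fcur }
    }
    Temp <- Temp * control$cooling
    if (trace_every > 0 && step %% trace_every == 0)
      tr[[length(tr) + 1L]] <- data.frame(step = step, T = Temp,
                                          value = fcur, best = fbest)
  }
  list(par = best, value = fbest, par_last = cur, value_last = fcur,
       acceptance_rate = n_acc / control$steps,
       trace = if (length(tr)) do.call(rbind, tr)
               else data.frame(step = integer(), T = numeric(),
                               value = numeric(), best = numeric()))
}

#' Calibrate colonization rates on old-field data
#'
#' The chronosequence calibration: minimizes the variance-normalized
#' deviation of the no-fire competition model from old-field cover records
#' over the colonization rates `c1..c5` (the grass `c6` is fitted on fire
#' data instead, where it is well determined).
#'
#' @inheritParams oldfield_objective
#' @param lower,upper Box bounds for the free parameters.
#' @param control An [anneal_control()].
#' @param seed Optional integer seed.
#' @param dt Integration step for the model runs inside the objective.
#' @return A list of class `calibration_result`: fitted `params`, free
#'   parameter vector `par`, `value` (deviation), goodness of fit `H2`, and
#'   the annealing `trace`.
#' @export
calibrate_oldfield <- function(obs, params = plant_params(),
                               free = paste0("c", 1:5),
                               lower = rep(0.005, 5), upper = rep(0.3, 5),
                               init_covers = initial_communities()$abandoned,
                               control = anneal_control(), seed = NULL,
                               dt = 1 / 52) {
  f <- oldfield_objective(obs, params, free, init_covers, dt = dt)
  start <- pmin(pmax(sapply(seq_along(free), function(k)
    get_free_param(params, free[k])), lower), upper)
  res <- anneal(f, start, lower, upper, control, seed)
  h2 <- environment(f)$h2(res$par)
  structure(list(params = set_free_params(params, free, res$par),
                 free = free, par = res$par, value = res$value, H2 = h2,
                 acceptance_rate = res$acceptance_rate, trace = res$trace),
            class = "calibration_result")
}

#' Calibrate the fire-response parameters on fire-plot data
#'
#' Fits `C_conv` (seeder establishment conversion), `r6` (grass resprouting
#' fraction) and `c6` (grass colonization) against experimental fire-plot
#' cover series, simulating each plot's imposed burn schedule.
#'
#' @inheritParams fireplot_objective
#' @inheritParams calibrate_oldfield
#' @export
calibrate_fireplots <- function(obs, schedules, params = plant_params(),
                                free = c("C_conv", "r6", "c6"),
                                lower = c(0.001, 0.05, 0.02),
                                upper = c(0.1, 0.9, 0.5),
                                init_covers =
                                  initial_communities()$abandoned,
                                rules = seed_bank_rules(),
                                control = anneal_control(), seed = NULL,
                                dt = 1 / 52) {
  f <- fireplot_objective(obs, schedules, params, free, init_covers,
                          rules = rules, dt = dt)
  start <- pmin(pmax(sapply(seq_along(free), function(k)
    get_free_param(params, free[k])), lower), upper)
  res <- anneal(f, start, lower, upper, control, seed)
  h2 <- environment(f)$h2(res$par)
  structure(list(params = set_free_params(params, free, res$par),
                 free = free, par = res$par, value = res$value, H2 = h2,
                 acceptance_rate = res$acceptance_rate, trace = res$trace),
            class = "calibration_result")
}

get_free_param <- function(params, nm) {
  if (nm %in% c("C_conv", "epsilon", "flam_mult")) return(params[[nm]])
  fld <- sub("[0-9]$", "", nm)
  idx <- as.integer(sub("^[a-z_]+", "", nm))
  params[[fld]][idx]
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result:\n")
  print(setNames(signif(x$par, 4), x$free))
  cat(sprintf("deviation = %.4g, H2 = %.3f\n", x$value, x$H2))
  invisible(x)
}

#' Monte Carlo calibration uncertainty envelope
#'
#' Propagates observational uncertainty (e.g. from the space-for-time
#' substitution) into the fitted trajectories: the old-field calibration is
#' repeated on `n_draws` site-level bootstrap resamples perturbed with
#' additive truncated-Gaussian cover noise, and the per-type pointwise
#' min/max envelope of the refitted no-fire trajectories is returned
#' alongside the best fit on the original data.
#'
#' @inheritParams calibrate_oldfield
#' @param n_draws Number of Monte Carlo draws (>= 2).
#' @param noise_sd Cover noise standard deviation (default 0.05).
#' @param time_grid Times (yr) at which the envelope is evaluated.
#' @param seed Integer seed.
#' @return A list with `time`, `lower` and `upper` (matrices, time x type),
#'   `best` (the best-fit trajectory matrix) and `fits` (the per-draw
#'   parameter vectors).
#' @export
mc_uncertainty <- function(obs, n_draws = 20, noise_sd = 0.05,
                           params = plant_params(), free = paste0("c", 1:5),
                           lower = rep(0.005, 5), upper = rep(0.3, 5),
                           init_covers = initial_communities()$abandoned,
                           control = anneal_control(steps = 2000),
                           time_grid = seq(0, 100, by = 1), seed = 1,
                           dt = 1 / 52) {
  if (n_draws < 2) stop("'n_draws' must be at least 2")
  set.seed(seed)
  traj_of <- function(p) {
    cfg <- run_config(duration = max(time_grid) + 1, dt = dt,
                      sample_every = 1, fires = "none", b0 = init_covers)
    tr <- simulate_fires(p, cfg)$trajectory
    vapply(PLANT_TYPES,
           function(ty) approx(tr$t, tr[[ty]], xout = time_grid, rule = 2)$y,
           numeric(length(time_grid)))
  }
  best_fit <- calibrate_oldfield(obs, params, free, lower, upper,
                                 init_covers, control,
                                 seed = sample.int(1e6, 1), dt = dt)
  best <- traj_of(best_fit$params)
  lo <- best
  hi <- best
  fits <- matrix(NA_real_, n_draws, length(free),
                 dimnames = list(NULL, free))
  cov_cols <- paste0("cover_", PLANT_TYPES)
  for (k in seq_len(n_draws)) {
    sites <- unique(obs$site)
    pick <- sample(sites, length(sites), replace = TRUE)
    res <- do.call(rbind, lapply(pick, function(s) obs[obs$site == s, ]))
    if (noise_sd > 0) {
      for (cl in cov_cols)
        res[[cl]] <- pmin(pmax(res[[cl]] +
                                 rnorm(nrow(res), 0, noise_sd), 0), 1)
      tot <- rowSums(res[cov_cols])
      over <- tot > 1
      res[over, cov_cols] <- res[over, cov_cols] / tot[over]
    }
    fit <- calibrate_oldfield(res, params, free, lower, upper, init_covers,
                              control, seed = sample.int(1e6, 1), dt = dt)
    fits[k, ] <- fit$par
    trk <- traj_of(fit$params)
    lo <- pmin(lo, trk)
    hi <- pmax(hi, trk)
  }
  list(time = time_grid, lower = lo, upper = hi, best = best, fits = fits)
}
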