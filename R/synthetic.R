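#' Synthetic observation specifications
#'
#' Define the statistical structure of synthetic cover observations used to
#' exercise the calibration pipeline without external data.
#' `synth_oldfield_spec` emulates an old-field chronosequence: sites with
#' ages drawn uniformly over the age range (space-for-time substitution),
#' observed as noisy samples of a no-fire model trajectory.
#' `synth_fireplot_spec` emulates experimentally burned plots followed
#' through time, each with an imposed burn schedule.
#'
#' @param n_sites Number of sites (defaults: 73 old-field, 4 fire plots).
#' @param age_range Range of site ages (yr since abandonment), default 1-100.
#' @param noise_sd Truncated-Gaussian cover noise SD (cover units,
#'   default 0.05).
#' @param params Generating [plant_params()] (recorded as the truth for
#'   recovery tests).
#' @param init_covers Covers at abandonment.
#' @param seed Integer seed.
#' @return A list of class `synth_spec`.
#' @export
synth_oldfield_spec <- function(n_sites = 73, age_range = c(1, 100),
                                noise_sd = 0.05, params = plant_params(),
                                init_covers =
                                  initial_communities()$abandoned,
                                seed = 1) {
  stopifnot(n_sites >= 1, noise_sd >= 0, age_range[1] >= 0,
            age_range[2] > age_range[1])
  structure(list(kind = "old-field", n_sites = n_sites,
                 age_range = age_range, noise_sd = noise_sd,
                 params = params, init_covers = init_covers, seed = seed),
            class = "synth_spec")
}

#' @param schedules Named list of burn-time vectors (yr), one per site;
#'   default one or two burns within the first 15 yr.
#' @param sampling_times Observation times (yr) for every plot, default
#'   annual sampling for 20 yr.
#' @param rules [seed_bank_rules()] used by the generating simulations.
#' @rdname synth_oldfield_spec
#' @export
synth_fireplot_spec <- function(n_sites = 4,
                                schedules = list(`1` = 6, `2` = 11,
                                                 `3` = c(5, 10),
                                                 `4` = c(7, 14)),
                                sampling_times = 1:20, noise_sd = 0.05,
                                params = plant_params(),
                                init_covers =
                                  initial_communities()$abandoned,
                                rules = seed_bank_rules(), seed = 1) {
  stopifnot(n_sites >= 1, noise_sd >= 0,
            length(schedules) == n_sites)
  if (any(unlist(schedules) > max(sampling_times)))
    stop("burn times must lie inside the sampling window")
  structure(list(kind = "fire-plot", n_sites = n_sites,
                 schedules = schedules, sampling_times = sampling_times,
                 noise_sd = noise_sd, params = params,
                 init_covers = init_covers, rules = rules, seed = seed),
            class = "synth_spec")
}

# add truncated-Gaussian noise, clip to [0,1], renormalize records whose
# total cover exceeds 1
perturb_covers <- function(mat, noise_sd) {
  if (noise_sd > 0)
    mat <- mat + matrix(rnorm(length(mat), 0, noise_sd), nrow(mat))
  mat <- pmin(pmax(mat, 0), 1)
  tot <- rowSums(mat)
  over <- tot > 1
  mat[over, ] <- mat[over, ] / tot[over]
  mat
}

as_observation_set <- function(site, kind, time_yr, covers) {
  out <- data.frame(site = site, kind = kind, time_yr = time_yr)
  covers <- as.data.frame(covers)
  names(covers) <- paste0("cover_", PLANT_TYPES)
  out <- cbind(out, covers)
  class(out) <- c("observation_set", "data.frame")
  out
}

#' Generate a synthetic old-field chronosequence
#'
#' Draws site ages uniformly over the spec's age range, evaluates the
#' no-fire competition model trajectory from the abandonment initial covers
#' and adds truncated-Gaussian noise per type; covers are clipped to
#' `[0, 1]` and any record whose total exceeds 1 is renormalized. The
#' generating parameter set is attached as `attr(, "truth")` for recovery
#' experiments.
#'
#' @param spec A [synth_oldfield_spec()].
#' @return An `observation_set` data frame (`site, kind, time_yr,
#'   cover_Q..cover_B`).
#' @export
generate_oldfield <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$kind == "old-field")
  set.seed(spec$seed)
  ages <- sort(runif(spec$n_sites, spec$age_range[1], spec$age_range[2]))
  obs <- data.frame(time_yr = ages)
  pred <- predict_oldfield(obs, spec$params, spec$init_covers)
  covers <- perturb_covers(pred, spec$noise_sd)
  out <- as_observation_set(seq_len(spec$n_sites), "old-field", ages, covers)
  attr(out, "truth") <- spec$params
  out
}

#' Generate synthetic fire-plot series
#'
#' Simulates each plot with its imposed burn schedule (fires as
#' deterministic events at the scheduled times), samples covers at the
#' spec's sampling times and perturbs them as in [generate_oldfield()].
#' With no burns and zero noise this coincides with the old-field generator
#' evaluated at the same times.
#'
#' @param spec A [synth_fireplot_spec()].
#' @return An `observation_set` data frame; the burn schedules are attached
#'   as `attr(, "schedules")` and the generating parameters as
#'   `attr(, "truth")`.
#' @export
generate_fireplots <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"), spec$kind == "fire-plot")
  set.seed(spec$seed)
  site <- rep(seq_len(spec$n_sites), each = length(spec$sampling_times))
  time_yr <- rep(spec$sampling_times, spec$n_sites)
  obs <- data.frame(site = site, time_yr = time_yr)
  pred <- predict_fireplots(obs, spec$params, spec$schedules,
                            spec$init_covers, spec$rules)
  covers <- perturb_covers(pred, spec$noise_sd)
  out <- as_observation_set(site, "fire-plot", time_yr, covers)
  attr(out, "truth") <- spec$params
  attr(out, "schedules") <- spec$schedules
  out
}
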