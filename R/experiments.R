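#' The 48-cell aridity scenario grid
#'
#' Full factorial over the three implicit climate effects: oak post-fire
#' resprouting `r1` in \{0.9, 0.75, 0.6\}, oak colonization `c1` over four
#' values spanning 0.047 down to 0.011 /yr, and a community-wide
#' flammability multiplier over four values spanning 1 to 3. Only the
#' endpoints of the `c1` and flammability ranges are fixed by design; the
#' default intermediates are geometrically spaced for `c1` (0.029, 0.018)
#' and 1.2 and 1.5 for flammability, all configurable. The first row is the
#' baseline (historical climate) cell, equal to the standard parameter set.
#'
#' @param r1 Oak resprouting fractions.
#' @param c1 Oak colonization rates (1/yr).
#' @param flam Flammability multipliers.
#' @return A data frame with columns `scenario, r1, c1, flam_mult` (48 rows
#'   under the defaults); harsher aridity toward larger row indices within
#'   each factor.
#' @export
scenario_grid <- function(r1 = c(0.9, 0.75, 0.6),
                          c1 = c(0.047, 0.029, 0.018, 0.011),
                          flam = c(1, 1.2, 1.5, 3)) {
  g <- expand.grid(flam_mult = flam, c1 = c1, r1 = r1,
                   KEEP.OUT.ATTRS = FALSE)[, c("r1", "c1", "flam_mult")]
  data.frame(scenario = seq_len(nrow(g)), g)
}

#' Apply an aridity scenario to a parameter set
#'
#' @param base A [plant_params()] set.
#' @param r1,c1,flam_mult Scenario values; `NULL` leaves the baseline value.
#' @param c_all Optional full colonization-vector override (length 6).
#' @return The modified `plant_params`.
#' @export
apply_scenario <- function(base = plant_params(), r1 = NULL, c1 = NULL,
                           flam_mult = NULL, c_all = NULL) {
  if (!is.null(c_all)) base$c <- as.numeric(c_all)
  if (!is.null(c1)) base$c[1] <- c1
  if (!is.null(r1)) base$r[1] <- r1
  if (!is.null(flam_mult)) base$flam_mult <- flam_mult
  validate_plant_params(base)
  base
}

#' The bistable aridity scenario
#'
#' The intermediate-aridity cell at which forest and open shrubland are
#' alternative stochastically stable states: `r1 = 0.60`, flammability
#' 1.2-fold the baseline, and `c1 = 0.018` /yr, the third (geometric) value
#' of the colonization grid. The cell's `c1` is bounded on both sides by the
#' model itself: a persistent forest needs `c1` well above the oak mortality
#' rate `m1 = 1/400`, while a persistent shrubland burning every ~27 yr
#' needs the per-fire-cycle oak multiplier `r1 * exp((c1 - m1) T)` below 1,
#' i.e. `c1` below about 0.021. Values outside that window (such as a
#' literal 0.0023, at which oak cover can only decline) are accepted via the
#' `c1` argument but give monostable dynamics.
#'
#' @param base A [plant_params()] set.
#' @param c1 Oak colonization rate for the cell.
#' @return A `plant_params` set.
#' @export
bistable_scenario <- function(base = plant_params(), c1 = 0.018) {
  apply_scenario(base, r1 = 0.60, c1 = c1, flam_mult = 1.2)
}

#' Long-term scenario experiments
#'
#' Runs each scenario cell from each initial community for `n_rep`
#' replicates of `duration` years with stochastic fires, and summarizes each
#' run (final covers over the last 20%, fire-interval statistics, time to
#' oak dominance, classified state). A cell is flagged bistable when its
#' replicates diverge in classified state. Set `mc_inits > 0` to add that
#' many random initial-cover draws per cell (a scaled-down Monte Carlo over
#' initial conditions).
#'
#' @param scenarios A [scenario_grid()] data frame (or subset of rows).
#' @param inits Named list of initial cover vectors (default the reference
#'   [initial_communities()]).
#' @param n_rep Replicates per cell x initial community.
#' @param duration Run length (yr, default 10,000).
#' @param dt Integration step (yr).
#' @param seed Base seed; per-run seeds are derived deterministically.
#' @param base Baseline [plant_params()].
#' @param rules [seed_bank_rules()].
#' @param mc_inits Number of additional random initial conditions per cell.
#' @return A data frame, one row per run: scenario factors, initial
#'   community, replicate, final covers, mean fire interval over the last
#'   20%, time to dominance, and classified state.
#' @export
run_long_term <- function(scenarios = scenario_grid(),
                          inits = initial_communities()[c("forest",
                                                          "shrubland",
                                                          "mixed")],
                          n_rep = 1, duration = 10000, dt = 1 / 365,
                          seed = 1, base = plant_params(),
                          rules = seed_bank_rules(), mc_inits = 0) {
  if (mc_inits > 0) {
    set.seed(seed)
    for (k in seq_len(mc_inits)) {
      raw <- runif(6)
      inits[[paste0("mc", k)]] <- raw / sum(raw) * runif(1, 0.05, 0.95)
    }
  }
  rows <- list()
  run_id <- 0L
  for (s in seq_len(nrow(scenarios))) {
    pars <- apply_scenario(base, r1 = scenarios$r1[s], c1 = scenarios$c1[s],
                           flam_mult = scenarios$flam_mult[s])
    for (init_name in names(inits)) {
      for (rep in seq_len(n_rep)) {
        run_id <- run_id + 1L
        cfg <- run_config(duration = duration, dt = dt, fires = "stochastic",
                          b0 = inits[[init_name]],
                          seed = (seed + 7919L * run_id) %% .Machine$integer.max)
        sm <- summarize_run(simulate_fires(pars, cfg, rules))
        rows[[run_id]] <- data.frame(
          scenario = scenarios$scenario[s], r1 = scenarios$r1[s],
          c1 = scenarios$c1[s], flam_mult = scenarios$flam_mult[s],
          init = init_name, rep = rep,
          as.list(setNames(sm$final_cover, paste0("final_", PLANT_TYPES))),
          mean_interval = sm$fire_stats$mean, n_fires = sm$fire_stats$n,
          time_to_dominance = sm$time_to_dominance,
          state = sm$classified_state)
      }
    }
  }
  out <- do.call(rbind, rows)
  bist <- tapply(out$state, out$scenario, function(s) length(unique(s)) > 1)
  out$bistable <- as.logical(bist[as.character(out$scenario)])
  rownames(out) <- NULL
  out
}

#' Short-term probabilistic experiments
#'
#' The century-scale, management-relevant view: for each scenario cell and
#' initial community, `n_runs` stochastic simulations of `duration` years
#' are run and community composition is summarized as the per-run mean oak
#' cover and mean shrub+grass cover over the last 20 yr, together with the
#' transition probabilities P(oak < 0.5), P(oak < 0.65) (forest decay) and
#' P(oak > 0.3) (oak establishment).
#'
#' @inheritParams run_long_term
#' @param n_runs Stochastic replicates per cell x initial community
#'   (default 100).
#' @param duration Run length (yr, default 100).
#' @param window Averaging window (yr, default the last 20 yr).
#' @param ramp_to Optional gradually-increasing-aridity target (see
#'   [run_config()]); applied to every run.
#' @return A list with `runs` (one row per run: factors, initial community,
#'   run index, `oak`, `shrubgrass`) and `summary` (one row per cell x
#'   initial community with the threshold probabilities).
#' @export
run_short_term <- function(scenarios = scenario_grid(),
                           inits = initial_communities()[c("forest",
                                                           "shrubland",
                                                           "mixed")],
                           n_runs = 100, duration = 100, dt = 1 / 365,
                           window = c(80, 100), seed = 1,
                           base = plant_params(), rules = seed_bank_rules(),
                           ramp_to = NULL) {
  runs <- list()
  run_id <- 0L
  for (s in seq_len(nrow(scenarios))) {
    pars <- apply_scenario(base, r1 = scenarios$r1[s], c1 = scenarios$c1[s],
                           flam_mult = scenarios$flam_mult[s])
    for (init_name in names(inits)) {
      for (k in seq_len(n_runs)) {
        run_id <- run_id + 1L
        cfg <- run_config(duration = duration, dt = dt, fires = "stochastic",
                          b0 = inits[[init_name]],
                          seed = (seed + 104729L * run_id) %%
                            .Machine$integer.max,
                          ramp_to = ramp_to)
        tr <- simulate_fires(pars, cfg, rules)$trajectory
        w <- tr$t >= window[1] & tr$t <= window[2]
        runs[[run_id]] <- data.frame(
          scenario = scenarios$scenario[s], r1 = scenarios$r1[s],
          c1 = scenarios$c1[s], flam_mult = scenarios$flam_mult[s],
          init = init_name, run = k,
          oak = mean(tr$Q[w]),
          shrubgrass = mean(tr$R[w] + tr$U[w] + tr$C[w] + tr$B[w]))
      }
    }
  }
  runs <- do.call(rbind, runs)
  key <- runs[c("scenario", "r1", "c1", "flam_mult", "init")]
  agg <- function(f) stats::aggregate(runs$oak, by = key, FUN = f)
  summary <- agg(mean)
  names(summary)[names(summary) == "x"] <- "mean_oak"
  summary$min_oak <- agg(min)$x
  summary$p_oak_lt_0.5 <- agg(function(x) mean(x < 0.5))$x
  summary$p_oak_lt_0.65 <- agg(function(x) mean(x < 0.65))$x
  summary$p_oak_gt_0.3 <- agg(function(x) mean(x > 0.3))$x
  list(runs = runs, summary = summary)
}
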