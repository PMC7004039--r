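#' Read / write observation sets
#'
#' Observation files are tab-delimited with header
#' `site, kind, time_yr, cover_Q, cover_P, cover_R, cover_U, cover_C,
#' cover_B`; `kind` is `old-field` or `fire-plot`. On ingest, covers must
#' lie in `[0, 1]` and records whose total cover exceeds 1 by at most 5%
#' are renormalized (larger violations are rejected).
#'
#' @param path File path.
#' @return For `read_observations`, an `observation_set` data frame.
#' @export
read_observations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("site", "kind", "time_yr", paste0("cover_", PLANT_TYPES))
  if (!all(need %in% names(tab)))
    stop("observation file must have columns: ", paste(need, collapse = ", "))
  if (any(tab$time_yr < 0)) stop("observation times must be >= 0")
  cov <- as.matrix(tab[paste0("cover_", PLANT_TYPES)])
  if (any(cov < 0 | cov > 1)) stop("covers must lie in [0, 1]")
  tot <- rowSums(cov)
  if (any(tot > 1.05))
    stop("total cover exceeds 1 by more than 5% in some records")
  over <- tot > 1
  if (any(over)) {
    cov[over, ] <- cov[over, ] / tot[over]
    tab[paste0("cover_", PLANT_TYPES)] <- cov
  }
  class(tab) <- c("observation_set", "data.frame")
  tab
}

#' @param obs An `observation_set` to write.
#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# configuration schema: defaults are the standard parameter set and the
# experiment settings used throughout
config_defaults <- function() {
  p <- plant_params()
  list(c = p$c, m = p$m, r = p$r, l = p$l, gamma = p$gamma,
       C_conv = p$C_conv, epsilon = p$epsilon, flam_mult = p$flam_mult,
       pine_maturity_age = 10, pine_seed_viability = 2,
       shrub_production_rate = 1, shrub_decay_rate = 0.2, bank_floor = 1e-10,
       duration = 10000, duration_no_fire = 1000, duration_short = 100,
       dt = 1 / 365, sample_every = 1, fires = "stochastic",
       b0 = initial_communities()$abandoned, min_interval = 2,
       n_replicates = 1, seed = 1,
       r1_grid = c(0.9, 0.75, 0.6), c1_grid = c(0.047, 0.029, 0.018, 0.011),
       flam_grid = c(1, 1.2, 1.5, 3))
}

#' Load a full run configuration
#'
#' Reads a JSON configuration file, fills every missing field with the
#' package defaults (the standard parameter set plus the standard experiment
#' settings), rejects unknown keys, and validates the result (rates
#' non-negative, `r` within `[0, 1]`, covers on the simplex, grids within
#' their admissible ranges). An empty or absent file yields the full
#' defaults.
#'
#' @param path Path to a JSON file, or `NULL` for pure defaults.
#' @return A named list with the validated configuration; the derived
#'   objects are available as `$params` ([plant_params()]) and `$rules`
#'   ([seed_bank_rules()]).
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, user)
  }
  params <- plant_params(c = cfg$c, m = cfg$m, r = cfg$r, l = cfg$l,
                         gamma = cfg$gamma, C_conv = cfg$C_conv,
                         epsilon = cfg$epsilon, flam_mult = cfg$flam_mult)
  rules <- seed_bank_rules(cfg$pine_maturity_age, cfg$pine_seed_viability,
                           cfg$shrub_production_rate, cfg$shrub_decay_rate,
                           cfg$bank_floor)
  if (any(cfg$r1_grid < 0 | cfg$r1_grid > 1))
    stop("'r1_grid' values must lie in [0, 1]")
  if (any(cfg$c1_grid <= 0)) stop("'c1_grid' values must be positive")
  if (any(cfg$flam_grid < 0)) stop("'flam_grid' values must be >= 0")
  if (cfg$duration <= 0 || cfg$dt <= 0) stop("durations and dt must be > 0")
  b0 <- as.numeric(cfg$b0)
  if (length(b0) != 6 || any(b0 < 0) || sum(b0) > 1 + 1e-9)
    stop("'b0' must be 6 non-negative covers with sum <= 1")
  cfg$params <- params
  cfg$rules <- rules
  cfg
}

#' Write result tables with a run manifest
#'
#' Writes each table as a tab-delimited file (floating point at 6
#' significant digits, deterministic column order) and a JSON manifest
#' alongside recording the configuration snapshot, the seeds, the package
#' version, a timestamp and the output file inventory. Re-running with the
#' same inputs reproduces byte-identical tables (the timestamp lives only in
#' the manifest).
#'
#' @param tables Named list of data frames.
#' @param outdir Output directory (created if needed).
#' @param config Configuration snapshot to embed in the manifest.
#' @param seeds Named list/vector of the seeds used by each stochastic
#'   stage.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(tables, outdir, config = list(), seeds = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], signif, digits = 6)
    f <- file.path(outdir, paste0(nm, ".tsv"))
    write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(package = "firedyn",
                   version = as.character(packageVersion("firedyn")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      usetz = TRUE),
                   seeds = seeds, config = config, files = files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Derive independent per-stage seeds from one global seed
#'
#' One global seed spawns a deterministic, collision-free integer substream
#' per named stage, so replicate-level work can be parallelized or re-run
#' in isolation without seed reuse.
#'
#' @param seed Global integer seed.
#' @param stages Character vector of stage names.
#' @return Named integer vector of per-stage seeds (all below 2^31).
#' @export
stage_seeds <- function(seed, stages) {
  setNames(vapply(seq_along(stages),
                  function(k) as.integer((seed + 2654435761 * k) %%
                                           .Machine$integer.max),
                  integer(1)),
           stages)
}
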