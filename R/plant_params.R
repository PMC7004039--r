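#' Plant-type parameter set
#'
#' Builds the parameter set for the six plant types of the Western
#' Mediterranean community, listed in inverse successional order, which is
#' also the competitive hierarchy (index 1 outcompetes all higher indices):
#' Q = evergreen *Quercus* (resprouter tree), P = *Pinus halepensis* (seeder
#' tree), R = *Rosmarinus officinalis*, U = *Ulex parviflorus*, C = *Cistus*
#' spp. (seeder shrubs), B = *Brachypodium retusum* (resprouter grass).
#' Defaults are the standard calibrated set.
#'
#' @param c Colonization rates (1/yr), length 6.
#' @param m Mortality rates, i.e. inverse life spans (1/yr), length 6.
#' @param r Fraction of pre-fire cover retained at a fire, in `[0, 1]`;
#'   seeders have 0 (all individuals killed by crown fire).
#' @param l Flammabilities (1/yr): the inverse of the mean fire return time if
#'   the whole plot were covered by that type alone.
#' @param gamma Post-fire seed germination and establishment fractions
#'   (dimensionless); only meaningful for the seeders (P, R, U, C), fixed at 0
#'   for the resprouters.
#' @param C_conv Conversion parameter of the post-fire establishment term
#'   (1/yr): the total establishment rate shared among seeders with viable
#'   seed banks.
#' @param epsilon Baseline fire hazard on bare ground (1/yr); its inverse is
#'   the bare-ground mean fire return time (10^4 yr).
#' @param flam_mult Scalar multiplier applied to the whole flammability
#'   vector (dimensionless, >= 0); used by the aridity scenarios.
#' @return An object of class `plant_params`.
#' @examples
#' pp <- plant_params()
#' pp$c[1]  # oak colonization rate
#' @export
plant_params <- function(c = base::c(0.047, 0.053, 0.045, 0.067, 0.11, 0.22),
                         m = c(1 / 400, 1 / 125, 1 / 50, 1 / 25, 1 / 15, 1 / 40),
                         r = c(0.9, 0, 0, 0, 0, 0.4),
                         l = c(1 / 400, 1 / 20, 1 / 15, 1 / 10, 1 / 10, 1 / 10),
                         gamma = c(0, 0.040, 0.0016, 0.0029, 0.00078, 0),
                         C_conv = 0.014,
                         epsilon = 1e-4,
                         flam_mult = 1) {
  p <- list(
    names = PLANT_TYPES,
    strategy = c("resprouter", "seeder", "seeder", "seeder", "seeder",
                 "resprouter"),
    c = as.numeric(c), m = as.numeric(m), r = as.numeric(r),
    l = as.numeric(l), gamma = as.numeric(gamma),
    C_conv = as.numeric(C_conv), epsilon = as.numeric(epsilon),
    flam_mult = as.numeric(flam_mult)
  )
  class(p) <- "plant_params"
  validate_plant_params(p)
  p
}

#' Validate a plant-type parameter set
#'
#' Checks lengths, non-negativity of all rates, `r` within `[0, 1]` and
#' `flam_mult >= 0`. Called by all constructors; exported for use on
#' externally read parameter tables.
#'
#' @param p A `plant_params` object.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_plant_params <- function(p) {
  stopifnot(inherits(p, "plant_params"))
  for (f in c("c", "m", "r", "l", "gamma")) {
    v <- p[[f]]
    if (length(v) != 6L || !is.numeric(v) || anyNA(v))
      stop("parameter '", f, "' must be a numeric vector of length 6")
    if (any(v < 0)) stop("parameter '", f, "' must be non-negative")
  }
  if (any(p$r > 1)) stop("'r' (fraction retained at fire) must be in [0, 1]")
  if (p$C_conv < 0 || p$epsilon < 0 || p$flam_mult < 0)
    stop("'C_conv', 'epsilon' and 'flam_mult' must be non-negative")
  invisible(p)
}

#' @export
print.plant_params <- function(x, ...) {
  cat("Plant-type parameter set (competitive order",
      paste(x$names, collapse = " > "), ")\n")
  tab <- data.frame(type = x$names, strategy = x$strategy, c = x$c, m = x$m,
                    r = x$r, l = x$l, gamma = x$gamma)
  print(tab, row.names = FALSE)
  cat(sprintf("C_conv = %g /yr, epsilon = %g /yr, flam_mult = %g\n",
              x$C_conv, x$epsilon, x$flam_mult))
  invisible(x)
}

#' Read / write a plant-type parameter table
#'
#' The table is tab-delimited with columns `type, strategy, c, m, r, l, gamma`
#' (one row per plant type, in competitive order) and the global constants
#' `C_conv`, `epsilon` and `flam_mult` stored as `#key value` header comments.
#' A packaged default mirroring the standard set ships as
#' `system.file("extdata", "standard_parameters.tsv", package = "firedyn")`.
#'
#' @param path File path.
#' @return For `read_plant_params`, a `plant_params` object.
#' @export
read_plant_params <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list(C_conv = 0.014, epsilon = 1e-4, flam_mult = 1)
  for (h in hdr) {
    parts <- strsplit(sub("^#\\s*", "", h), "\\s+")[[1]]
    if (length(parts) == 2 && parts[1] %in% names(kv))
      kv[[parts[1]]] <- as.numeric(parts[2])
  }
  tab <- read.delim(text = lines[!grepl("^#", lines)],
                    stringsAsFactors = FALSE)
  need <- c("type", "strategy", "c", "m", "r", "l", "gamma")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  if (!identical(tab$type, PLANT_TYPES))
    stop("parameter table rows must be the six types ",
         paste(PLANT_TYPES, collapse = ", "), " in competitive order")
  plant_params(c = tab$c, m = tab$m, r = tab$r, l = tab$l, gamma = tab$gamma,
               C_conv = kv$C_conv, epsilon = kv$epsilon,
               flam_mult = kv$flam_mult)
}

#' @param p A `plant_params` object to write.
#' @rdname read_plant_params
#' @export
write_plant_params <- function(p, path) {
  validate_plant_params(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#C_conv %.17g", p$C_conv),
               sprintf("#epsilon %.17g", p$epsilon),
               sprintf("#flam_mult %.17g", p$flam_mult)), con)
  tab <- data.frame(type = p$names, strategy = p$strategy, c = p$c, m = p$m,
                    r = p$r, l = p$l, gamma = p$gamma)
  write.table(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ecosystem state
#'
#' A snapshot of the community: the six cover fractions, the four seed-bank
#' levels of the seeder types (P, R, U, C, in arbitrary seed-mass units), the
#' time since the last fire and the absolute time.
#'
#' @param b Cover fractions, length 6, each >= 0 with `sum(b) <= 1`.
#' @param S Seed-bank levels for P, R, U, C. Default: pine bank 0 (no fire has
#'   released the canopy bank) and shrub banks at their between-fire steady
#'   state `production/decay * cover` for the default bank rules.
#' @param tau_fire Time since the last fire (yr); `Inf` if never burned.
#' @param t Absolute time (yr).
#' @return An object of class `ecosystem_state`.
#' @export
ecosystem_state <- function(b, S = NULL, tau_fire = Inf, t = 0) {
  b <- as.numeric(b)
  if (length(b) != 6L || anyNA(b)) stop("'b' must be 6 cover fractions")
  if (any(b < -1e-9)) stop("covers must be non-negative")
  b <- pmax(b, 0)
  if (sum(b) > 1 + 1e-9)
    stop("total cover exceeds 1 (free space would be negative)")
  if (is.null(S)) S <- c(0, b[3:5] / 0.2)
  S <- as.numeric(S)
  if (length(S) != 4L || any(S < 0)) stop("'S' must be 4 non-negative levels")
  structure(list(b = b, S = S, tau_fire = tau_fire, t = t),
            class = "ecosystem_state")
}

#' @export
print.ecosystem_state <- function(x, ...) {
  cat("Ecosystem state at t =", x$t, "yr (",
      if (is.finite(x$tau_fire)) paste(x$tau_fire, "yr since fire")
      else "never burned", ")\n")
  print(setNames(round(x$b, 4), PLANT_TYPES))
  cat("seed banks:\n")
  print(setNames(signif(x$S, 4), c("S_P", "S_R", "S_U", "S_C")))
  invisible(x)
}
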