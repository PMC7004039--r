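#' Seed-bank rules
#'
#' Parameters governing the seed banks that drive post-fire seeder
#' establishment. Pines carry an aerial (canopy) bank: it is released to the
#' ground by a fire only if the stand is old enough to have reached seed
#' production maturity, and the released seeds stay viable for about two
#' years. The shrubs maintain soil banks fed continuously by their cover
#' (they reproduce from their first years, so no delay is modelled) and
#' subject to gradual first-order decay between fires.
#'
#' @param pine_maturity_age Stand age (yr since last fire) at which pines
#'   produce seeds (default 10, the lower end of the observed 10-12 yr).
#' @param pine_seed_viability Viability of released pine seeds (yr post-fire,
#'   default 2).
#' @param shrub_production_rate Seed-bank input per unit shrub cover per year
#'   (seed-units/yr) for the three shrub seeders `(R, U, C)`; a scalar is
#'   recycled. Only the ratios `gamma_i * S_i` between seeders matter for
#'   the establishment term, so the default is a uniform 1; species-specific
#'   values (e.g. a much larger one for the prolific seeder *Cistus*) shift
#'   which shrub dominates post-fire without changing the total
#'   establishment rate.
#' @param shrub_decay_rate First-order bank decay (1/yr, default 0.2).
#' @param bank_floor Bank levels below this are treated as exhausted inside
#'   the establishment-rate normalization (numerical guard; default 1e-10).
#' @return An object of class `seed_bank_rules`.
#' @export
seed_bank_rules <- function(pine_maturity_age = 10,
                            pine_seed_viability = 2,
                            shrub_production_rate = 1,
                            shrub_decay_rate = 0.2,
                            bank_floor = 1e-10) {
  shrub_production_rate <- rep_len(as.numeric(shrub_production_rate), 3L)
  r <- list(pine_maturity_age = pine_maturity_age,
            pine_seed_viability = pine_seed_viability,
            shrub_production_rate = shrub_production_rate,
            shrub_decay_rate = shrub_decay_rate,
            bank_floor = bank_floor)
  if (any(unlist(r) < 0)) stop("all seed-bank parameters must be >= 0")
  class(r) <- "seed_bank_rules"
  r
}

#' Fire hazard rate
#'
#' The instantaneous fire hazard given the current covers,
#' `lambda = flam_mult * sum(l_i b_i) + epsilon` (1/yr). The mean fire return
#' time is `1/lambda`: about 10^4 yr on bare ground (via `epsilon`) and e.g.
#' 10 yr under full grass cover (`l_B = 1/10`).
#'
#' @param b Cover vector (length 6) or [ecosystem_state()].
#' @param params A [plant_params()] set (its `flam_mult` scales the
#'   vegetation term).
#' @return Hazard rate (1/yr).
#' @export
fire_hazard <- function(b, params = plant_params()) {
  if (inherits(b, "ecosystem_state")) b <- b$b
  b <- as.numeric(b)
  if (length(b) != 6L) stop("cover vector must have length 6")
  params$flam_mult * sum(params$l * b) + params$epsilon
}

#' Sample the waiting time to the next fire
#'
#' Implements the non-homogeneous exponential waiting time by time-rescaling:
#' a unit-exponential deviate `E` is drawn and the fire occurs when the
#' hazard integrated along the running solution since the last fire reaches
#' `E`. The realized interval is clamped to the enforced minimum fire return
#' time of 2 yr (the event is deferred, not re-drawn). With a constant hazard
#' this reduces to an exponential interval with mean `1/lambda`.
#'
#' @param hazard A constant hazard (1/yr) or a function of time since the
#'   last fire returning the hazard.
#' @param t_last Time of the last fire (yr); the returned event time is
#'   absolute.
#' @param min_interval Minimum fire return time (yr, default 2).
#' @param dt Quadrature step for a time-varying hazard (yr).
#' @param t_max Give up after this much waiting time (returns `Inf`).
#' @return The absolute time of the next fire (yr). Reproducible under
#'   `set.seed()`.
#' @export
sample_next_fire <- function(hazard, t_last = 0, min_interval = 2,
                             dt = 1 / 365, t_max = 1e6) {
  E <- rexp(1)
  if (is.numeric(hazard)) {
    w <- E / hazard
  } else {
    acc <- 0
    w <- NA_real_
    lam0 <- hazard(0)
    tt <- 0
    while (tt < t_max) {
      lam1 <- hazard(tt + dt)
      acc <- acc + dt * 0.5 * (lam0 + lam1)
      tt <- tt + dt
      lam0 <- lam1
      if (acc >= E) { w <- tt; break }
    }
    if (is.na(w)) return(Inf)
  }
  t_last + max(w, min_interval)
}

#' Apply an instantaneous fire to a state
#'
#' Seeders (P, R, U, C) lose all cover (`r_i = 0`: severe crown fire);
#' resprouters retain the fraction `r_i` of their pre-fire cover,
#' immediately. The pine canopy bank is released (set to the pre-fire pine
#' cover) only if the stand had reached seed-production maturity; if two
#' fires occur closer together than the maturity age, no pine seeds are
#' available and pines cannot re-establish. Shrub soil banks are unchanged by
#' the event itself. The fire clock is reset.
#'
#' @param state An [ecosystem_state()].
#' @param params A [plant_params()] set.
#' @param rules A [seed_bank_rules()] object.
#' @return The post-fire `ecosystem_state`.
#' @export
apply_fire <- function(state, params = plant_params(),
                       rules = seed_bank_rules()) {
  stopifnot(inherits(state, "ecosystem_state"))
  pre <- state$b
  S <- state$S
  S[1] <- if (state$tau_fire >= rules$pine_maturity_age) pre[2] else 0
  ecosystem_state(b = params$r * pre, S = S, tau_fire = 0, t = state$t)
}

#' Advance the seed banks over a fire-free interval
#'
#' Shrub banks follow `dS/dt = production * cover - decay * S` (solved
#' exactly for constant cover over the step); the pine bank stays constant
#' while the released seeds are viable and is exhausted afterwards.
#'
#' @param state An [ecosystem_state()].
#' @param rules A [seed_bank_rules()] object.
#' @param dt Interval length (yr), > 0.
#' @return The updated seed-bank vector `(S_P, S_R, S_U, S_C)`.
#' @export
seedbank_step <- function(state, rules = seed_bank_rules(), dt) {
  stopifnot(inherits(state, "ecosystem_state"), dt > 0)
  S <- state$S
  k <- rules$shrub_decay_rate
  b_sh <- state$b[3:5]
  if (k > 0) {
    Seq <- rules$shrub_production_rate * b_sh / k
    S[2:4] <- Seq + (S[2:4] - Seq) * exp(-k * dt)
  } else {
    S[2:4] <- S[2:4] + rules$shrub_production_rate * b_sh * dt
  }
  S[1] <- if (state$tau_fire + dt > rules$pine_seed_viability) 0 else S[1]
  S
}

#' Post-fire establishment rates
#'
#' Allocates the total conversion rate `C_conv` among the seeder types in
#' proportion to their viable seed supply weighted by establishment ability:
#' `alpha_i = C_conv * gamma_i S_i / sum_k gamma_k S_k` for i = 2..5, with
#' `alpha = 0` for the resprouters and everywhere when no viable bank exists.
#' The rates therefore always sum to either 0 or exactly `C_conv`
#' (partition-of-unity of the normalization).
#'
#' @param S Seed-bank vector `(S_P, S_R, S_U, S_C)`, all >= 0.
#' @param params A [plant_params()] set.
#' @param rules A [seed_bank_rules()] object (supplies the bank floor).
#' @return Establishment-rate vector of length 6 (1/yr).
#' @export
postfire_alpha <- function(S, params = plant_params(),
                           rules = seed_bank_rules()) {
  S <- as.numeric(S)
  if (length(S) != 4L || any(S < 0)) stop("'S' must be 4 non-negative levels")
  S[S <= rules$bank_floor] <- 0
  num <- params$gamma[SEEDER_IDX] * S
  den <- sum(num)
  alpha <- rep(0, 6)
  if (den > 0) alpha[SEEDER_IDX] <- params$C_conv * num / den
  alpha
}
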