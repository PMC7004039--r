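#' Right-hand side of the competition model
#'
#' Time derivatives of the six cover fractions under hierarchical competition
#' for space:
#' `db_i/dt = c_i b_i (1 - sum_{j<=i} b_j) - m_i b_i - sum_{j<i} c_j b_j b_i
#'  + alpha_i (1 - sum_j b_j)`.
#' Type `i` can only colonize space not occupied by itself or by superior
#' competitors (`j <= i`), is displaced by superior colonizers (third term),
#' and seeders may additionally establish into free space after fires at rate
#' `alpha_i`. Pure function: no state is mutated.
#'
#' @param state An [ecosystem_state()] or a numeric cover vector of length 6.
#' @param params A [plant_params()] set.
#' @param alpha Establishment rates (1/yr), length 6; must be 0 for the
#'   resprouters (types 1 and 6).
#' @return Numeric vector of `db_i/dt` (1/yr).
#' @examples
#' competition_rhs(c(0.5, 0, 0, 0, 0, 0), plant_params())  # 0.0105 for oak
#' @export
competition_rhs <- function(state, params = plant_params(),
                            alpha = rep(0, 6)) {
  b <- if (inherits(state, "ecosystem_state")) state$b else as.numeric(state)
  if (length(b) != 6L) stop("cover vector must have length 6")
  if (any(b < -1e-9)) stop("covers must be non-negative")
  alpha <- as.numeric(alpha)
  if (length(alpha) != 6L) stop("'alpha' must have length 6")
  if (any(alpha[c(1, 6)] != 0))
    stop("resprouters (types 1 and 6) have no post-fire establishment term")
  b <- pmax(b, 0)
  cumb <- cumsum(b)
  csum <- c(0, cumsum(params$c * b)[-6])  # sum_{j<i} c_j b_j
  free <- 1 - sum(b)
  params$c * b * (1 - cumb) - params$m * b - csum * b + alpha * free
}

#' Closed-form no-fire equilibrium
#'
#' Sequential equilibrium of the hierarchical competition model without fires
#' (`alpha = 0`). In competitive order, each type settles at
#' `b_i* = max(0, 1 - m_i/c_i - sum_{j<i, persisting} b_j* (1 + c_j/c_i))`;
#' types driven to zero are excluded from subsequent sums. The top competitor
#' attains the classical single-species value `1 - m_1/c_1` independently of
#' all lower types. Serves as the analytic oracle for long no-fire
#' integrations.
#'
#' @param params A [plant_params()] set with all `c_i > 0`.
#' @return Named numeric vector of equilibrium covers.
#' @examples
#' equilibrium_no_fire(plant_params())  # only oak persists, ~0.947
#' @export
equilibrium_no_fire <- function(params = plant_params()) {
  if (any(params$c <= 0)) stop("all colonization rates must be positive")
  b <- numeric(6)
  for (i in 1:6) {
    s <- 0
    if (i > 1) {
      j <- which(b[seq_len(i - 1)] > 0)
      if (length(j))
        s <- sum(b[j] * (1 + params$c[j] / params$c[i]))
    }
    b[i] <- max(0, 1 - params$m[i] / params$c[i] - s)
  }
  setNames(b, PLANT_TYPES)
}
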