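#' Regulatory input activity of each gene
#'
#' Gene 1 is driven directly by its inducer, `R1 = I1`. Gene 2 is driven by
#' its inducer filtered through the inhibitory Hill function of the GFP
#' protein level, `R2 = I2 * Kg^n / (p1^n + Kg^n)`, so `R2` decreases
#' monotonically from `I2` (at `p1 = 0`) towards 0, with half-inhibition at
#' `p1 = Kg`.
#'
#' @param params A [circuit_params()] object.
#' @param p1 GFP protein concentration(s), non-negative. Vectorized.
#' @param gene Which gene's activity to return, `1` or `2`.
#' @return Numeric vector of activities, `>= 0`.
#' @examples
#' p <- circuit_params()
#' regulatory_input(p, 0, gene = 2)        # = I2
#' regulatory_input(p, p$Kg, gene = 2)     # = I2 / 2
#' @export
regulatory_input <- function(params, p1, gene) {
  stopifnot(is.circuit_params(params))
  if (!gene %in% c(1, 2)) stop("'gene' must be 1 or 2")
  if (any(!is.finite(p1))) stop("non-finite p1")
  if (any(p1 < 0)) stop("p1 must be non-negative")
  if (gene == 1) return(rep_len(params$I1, length(p1)))
  params$I2 * params$Kg^params$n / (p1^params$n + params$Kg^params$n)
}

# Production fluxes (concentration space, per unit time) for all three
# resource regimes. Single source of truth shared by the deterministic RHS,
# the stochastic propensities and the FDT flux ratios.
#
# state: named or positional c(m1, p1, m2, p2). Returns list with the two
# mRNA production rates and the two protein production rates, plus the
# partition denominators (useful for diagnostics).
production_rates <- function(state, params, mode,
                             clamp = NULL) {
  m1 <- state[[1]]; p1 <- state[[2]]; m2 <- state[[3]]
  R1 <- params$I1
  R2 <- params$I2 * params$Kg^params$n / (p1^params$n + params$Kg^params$n)
  if (mode == "unlimited") {
    Zm1 <- Zm2 <- Zp1 <- Zp2 <- 1
  } else if (mode == "shared") {
    Zm1 <- Zm2 <- 1 + R1 / params$Jm1 + R2 / params$Jm2
    # clamp = c(m1c, m2c): the opposing mRNA inside each gene's translation
    # partition is frozen at its mean; all other occurrences stay live.
    m2_in_1 <- if (is.null(clamp)) m2 else clamp[[2]]
    m1_in_2 <- if (is.null(clamp)) m1 else clamp[[1]]
    Zp1 <- 1 + m1 / params$Jp1 + m2_in_1 / params$Jp2
    Zp2 <- 1 + m1_in_2 / params$Jp1 + m2 / params$Jp2
  } else if (mode == "orthogonal") {
    Zm1 <- 1 + R1 / params$Jm1
    Zm2 <- 1 + R2 / params$Jm2
    Zp1 <- 1 + m1 / params$Jp1
    Zp2 <- 1 + m2 / params$Jp2
  } else {
    stop("unknown mode")
  }
  list(mrna = c((params$km01 + params$km1 * R1) / Zm1,
                (params$km02 + params$km2 * R2) / Zm2),
       protein = c(params$kp1 * m1 / Zp1,
                   params$kp2 * m2 / Zp2),
       R = c(R1, R2), Zm = c(Zm1, Zm2), Zp = c(Zp1, Zp2))
}

#' Deterministic rate laws of the cascade
#'
#' Time derivatives of the concentration state `(m1, p1, m2, p2)`:
#' `dm_i/dt = production_i - dm_i * m_i`, `dp_i/dt = kp_i m_i / Zp_i -
#' dp_i * p_i`, where the production terms carry the partition-function
#' denominators of the chosen resource regime (none for `"unlimited"`,
#' a sum over both genes for `"shared"`, own-gene terms only for
#' `"orthogonal"`). As all capacities `J -> Inf`, the shared model reduces
#' pointwise to the unlimited one.
#'
#' @param state Concentration 4-vector `(m1, p1, m2, p2)`, non-negative.
#' @param params A [circuit_params()] object.
#' @param mode One of [resource_modes()].
#' @return Named numeric 4-vector of time derivatives.
#' @export
ode_rhs <- function(state, params, mode) {
  stopifnot(is.circuit_params(params))
  mode <- match_mode(mode)
  if (length(state) != 4L) stop("state must have length 4")
  if (any(!is.finite(state))) stop("non-finite state")
  if (any(state < -1e-12)) stop("state must be non-negative")
  pr <- production_rates(state, params, mode)
  c(dm1 = pr$mrna[1] - params$dm1 * state[[1]],
    dp1 = pr$protein[1] - params$dp1 * state[[2]],
    dm2 = pr$mrna[2] - params$dm2 * state[[3]],
    dp2 = pr$protein[2] - params$dp2 * state[[4]])
}

#' Closed-form steady state (unlimited and orthogonal regimes)
#'
#' For the regimes without cross-gene coupling through the resource pools the
#' steady state is explicit: the gene-1 equations are self-contained
#' (`R1 = I1` is constant), giving `m1` and `p1` directly; `R2(p1)` then
#' yields `m2` and `p2` by substitution. The shared regime has no closed
#' form (steady states can be multiple); use [find_steady_states()].
#'
#' @inheritParams ode_rhs
#' @param mode `"unlimited"` or `"orthogonal"`.
#' @return Named concentration 4-vector at which [ode_rhs()] vanishes.
#' @examples
#' steady_state_closed_form(circuit_params(), "unlimited")  # m1 = 8.4, p1 = 126
#' @export
steady_state_closed_form <- function(params, mode) {
  stopifnot(is.circuit_params(params))
  mode <- match_mode(mode)
  if (mode == "shared")
    stop("no closed form for the shared regime; use find_steady_states()")
  R1 <- params$I1
  if (mode == "unlimited") {
    m1 <- (params$km01 + params$km1 * R1) / params$dm1
    p1 <- params$kp1 * m1 / params$dp1
    R2 <- regulatory_input(params, p1, 2)
    m2 <- (params$km02 + params$km2 * R2) / params$dm2
    p2 <- params$kp2 * m2 / params$dp2
  } else {
    m1 <- (params$km01 + params$km1 * R1) / (params$dm1 * (1 + R1 / params$Jm1))
    p1 <- params$kp1 * m1 / (params$dp1 * (1 + m1 / params$Jp1))
    R2 <- regulatory_input(params, p1, 2)
    m2 <- (params$km02 + params$km2 * R2) / (params$dm2 * (1 + R2 / params$Jm2))
    p2 <- params$kp2 * m2 / (params$dp2 * (1 + m2 / params$Jp2))
  }
  conc_state(m1, p1, m2, p2)
}

#' Integrate the deterministic model forward in time
#'
#' Classic fixed-step fourth-order Runge-Kutta on the 4-species system; the
#' step (default 0.01 lifetimes) is ample for these non-stiff kinetics.
#' States are floored at zero after each step to guard round-off.
#'
#' @inheritParams ode_rhs
#' @param init Initial concentration 4-vector.
#' @param t_end Final time.
#' @param dt Integration step.
#' @param record_every Record every k-th step (default records ~200 rows).
#' @return A data.frame with columns `t, m1, p1, m2, p2`; the attribute
#'   `"final"` holds the exact final state.
#' @export
integrate_ode <- function(params, mode, init, t_end, dt = 0.01,
                          record_every = NULL) {
  mode <- match_mode(mode)
  x <- as.numeric(init)
  nstep <- ceiling(t_end / dt)
  if (is.null(record_every)) record_every <- max(1L, floor(nstep / 200))
  keep <- seq(0L, nstep, by = record_every)
  out <- matrix(NA_real_, nrow = length(keep), ncol = 5L)
  k <- 1L
  f <- function(x) {
    pr <- production_rates(x, params, mode)
    c(pr$mrna[1] - params$dm1 * x[1], pr$protein[1] - params$dp1 * x[2],
      pr$mrna[2] - params$dm2 * x[3], pr$protein[2] - params$dp2 * x[4])
  }
  for (i in 0:nstep) {
    if (k <= length(keep) && i == keep[k]) {
      out[k, ] <- c(i * dt, x); k <- k + 1L
    }
    if (i == nstep) break
    k1 <- f(x); k2 <- f(pmax(x + dt / 2 * k1, 0))
    k3 <- f(pmax(x + dt / 2 * k2, 0)); k4 <- f(pmax(x + dt * k3, 0))
    x <- pmax(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  res <- as.data.frame(out)
  names(res) <- c("t", "m1", "p1", "m2", "p2")
  attr(res, "final") <- stats::setNames(x, c("m1", "p1", "m2", "p2"))
  res
}
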