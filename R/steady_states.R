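# Steady-state enumeration.
#
# At a fixed point the two mRNA means are explicit functions of p1 alone:
# R1 = I1 is constant and R2 = R2(p1), so
#   m_i = (km0_i + km_i R_i) / (dm_i * Zm_i(p1)),
# and the translation balance for gene 1 closes the loop through a scalar
# residual g(p1) = p1 - kp1 m1(p1) / (dp1 * Zp1(m1(p1), m2(p1))).
# Every fixed point of the 4D system is a root of g, so a dense bracket scan
# plus uniroot refinement enumerates them completely — no multi-start needed.

mrna_means_given_p1 <- function(p1, params, mode) {
  R1 <- params$I1
  R2 <- params$I2 * params$Kg^params$n / (p1^params$n + params$Kg^params$n)
  if (mode == "unlimited") {
    Zm1 <- Zm2 <- 1
  } else if (mode == "shared") {
    Zm1 <- Zm2 <- 1 + R1 / params$Jm1 + R2 / params$Jm2
  } else {
    Zm1 <- 1 + R1 / params$Jm1
    Zm2 <- 1 + R2 / params$Jm2
  }
  list(m1 = (params$km01 + params$km1 * R1) / (params$dm1 * Zm1),
       m2 = (params$km02 + params$km2 * R2) / (params$dm2 * Zm2))
}

p1_residual <- function(p1, params, mode) {
  mm <- mrna_means_given_p1(p1, params, mode)
  Zp1 <- switch(mode,
                unlimited = 1,
                shared = 1 + mm$m1 / params$Jp1 + mm$m2 / params$Jp2,
                orthogonal = 1 + mm$m1 / params$Jp1)
  p1 - params$kp1 * mm$m1 / (params$dp1 * Zp1)
}

state_from_p1 <- function(p1, params, mode) {
  mm <- mrna_means_given_p1(p1, params, mode)
  Zp2 <- switch(mode,
                unlimited = 1,
                shared = 1 + mm$m1 / params$Jp1 + mm$m2 / params$Jp2,
                orthogonal = 1 + mm$m2 / params$Jp2)
  conc_state(mm$m1, p1, mm$m2,
             params$kp2 * mm$m2 / (params$dp2 * Zp2))
}

#' Finite-difference Jacobian of the rate laws
#'
#' Central differences with relative step `1e-6` (absolute floor `1e-8`).
#'
#' @inheritParams ode_rhs
#' @return 4x4 numeric matrix `J[i, j] = d(rhs_i)/d(state_j)`.
#' @export
ode_jacobian <- function(state, params, mode, rel_step = 1e-6) {
  mode <- match_mode(mode)
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    h <- max(abs(state[[j]]) * rel_step, 1e-8)
    up <- dn <- as.numeric(state)
    up[j] <- up[j] + h
    dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (ode_rhs(up, params, mode) - ode_rhs(dn, params, mode)) /
      (up[j] - dn[j])
  }
  J
}

#' Find all deterministic steady states with stability
#'
#' Enumerates every fixed point of [ode_rhs()] via an exact one-dimensional
#' reduction in the GFP protein level (see Details in the package vignette),
#' deduplicates roots closer than `1e-5` relative, and classifies stability
#' from the eigenvalues of the finite-difference Jacobian.
#'
#' @inheritParams ode_rhs
#' @param n_grid Number of scan points for bracketing roots of the scalar
#'   residual (default 4000).
#' @return A list of steady-state points, each a list with elements `state`
#'   (named concentration 4-vector), `eigenvalues` (4 complex values) and
#'   `stable` (logical: all real parts `< 0`). Sorted by increasing `p1`.
#'   Empty list (with a warning) if no root converges.
#' @examples
#' length(find_steady_states(circuit_params(), "shared"))       # 3
#' length(find_steady_states(circuit_params(I1 = 0.2), "shared")) # 1
#' @export
find_steady_states <- function(params, mode, n_grid = 4000) {
  stopifnot(is.circuit_params(params))
  mode <- match_mode(mode)
  # upper bound on p1: translation of the (partition-free) maximal m1
  m1_max <- (params$km01 + params$km1 * params$I1) / params$dm1
  p1_max <- params$kp1 * m1_max / params$dp1
  grid <- seq(0, p1_max * 1.05 + 1e-9, length.out = n_grid)
  gv <- p1_residual(grid, params, mode)
  sgn <- sign(gv)
  roots <- numeric(0)
  idx <- which(sgn[-1] * sgn[-n_grid] < 0)
  for (i in idx) {
    r <- tryCatch(
      stats::uniroot(p1_residual, c(grid[i], grid[i + 1]),
                     params = params, mode = mode, tol = 1e-12)$root,
      error = function(e) NA_real_)
    if (is.finite(r)) roots <- c(roots, r)
  }
  # exact zeros on the grid (e.g. p1 = 0 with no production)
  roots <- c(roots, grid[gv == 0])
  if (!length(roots)) {
    warning("no steady state converged; pathological parameters?")
    return(list())
  }
  roots <- sort(roots)
  # deduplicate (relative distance < 1e-5)
  keep <- c(TRUE, diff(roots) > 1e-5 * pmax(roots[-length(roots)], 1))
  roots <- roots[keep]
  lapply(roots, function(r) {
    st <- state_from_p1(r, params, mode)
    ev <- eigen(ode_jacobian(st, params, mode), only.values = TRUE)$values
    list(state = st, eigenvalues = ev, stable = all(Re(ev) < 0))
  })
}

n_stable <- function(ss) sum(vapply(ss, `[[`, logical(1), "stable"))

#' Nullclines of the resource-coupled cascade in the (p1, m2) plane
#'
#' The full system's `(p1, p2)` plane is degenerate (`p2` feeds back on
#' nothing), so the analysis is done in the only two-variable projection in
#' which both the direct inhibition and the resource-mediated return path
#' appear: GFP protein `p1` versus RFP mRNA `m2`. Curve A is the GFP
#' translation balance `dp1/dt = 0` with `m1` at its quasi-steady value
#' `m1*(p1)`, solved for `m2`; curve B is the RFP transcription balance
#' `dm2/dt = 0`, i.e. `m2 = m2*(p1)`. Their intersections are exactly the
#' fixed points of the full 4D system.
#'
#' @inheritParams ode_rhs
#' @param mode Resource regime; the analysis targets `"shared"`.
#' @param p1_grid Grid of GFP protein values (default 400 points spanning
#'   the physical range).
#' @return A list with data.frames `curve_a` and `curve_b` (columns `p1`,
#'   `m2`, `p2`) and `intersections`, the steady-state list from
#'   [find_steady_states()].
#' @export
nullclines <- function(params, mode = "shared", p1_grid = NULL) {
  stopifnot(is.circuit_params(params))
  mode <- match_mode(mode)
  m1_max <- (params$km01 + params$km1 * params$I1) / params$dm1
  if (is.null(p1_grid))
    p1_grid <- seq(1e-3, params$kp1 * m1_max / params$dp1, length.out = 400)
  mm <- mrna_means_given_p1(p1_grid, params, mode)
  # curve B: dm2/dt = 0
  m2_b <- mm$m2
  # curve A: dp1/dt = 0 solved for m2 given p1 (shared); for regimes without
  # cross-coupling the balance fixes p1 alone and the curve is vertical there.
  if (mode == "shared") {
    m2_a <- params$Jp2 *
      (params$kp1 * mm$m1 / (params$dp1 * p1_grid) - 1 - mm$m1 / params$Jp1)
    m2_a[m2_a < 0] <- NA_real_
  } else {
    m2_a <- rep(NA_real_, length(p1_grid))
  }
  to_p2 <- function(m1, m2) {
    Zp2 <- switch(mode,
                  unlimited = 1,
                  shared = 1 + m1 / params$Jp1 + m2 / params$Jp2,
                  orthogonal = 1 + m2 / params$Jp2)
    params$kp2 * m2 / (params$dp2 * Zp2)
  }
  list(curve_a = data.frame(p1 = p1_grid, m2 = m2_a,
                            p2 = to_p2(mm$m1, m2_a)),
       curve_b = data.frame(p1 = p1_grid, m2 = m2_b,
                            p2 = to_p2(mm$m1, m2_b)),
       intersections = find_steady_states(params, mode))
}
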