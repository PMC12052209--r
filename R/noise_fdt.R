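# Analytical noise via the normalized fluctuation-dissipation theorem.
#
# For stationary normalized covariances eta_ij = sigma_ij/(mu_i mu_j) the
# FDT reads A eta + eta A' + D = 0 with drift A_ij = -H_ij/tau_i and
# diffusion D_ii = 2/(tau_i <N_i>), where H_ij is the static susceptibility
# d ln(J_i^- / J_i^+) / d ln(x_j) evaluated at the stationary means and
# tau_i the species lifetime. The cascade ordering is
# x = (M1, P1, M2, P2), tau = (1/dm1, 1/dp1, 1/dm2, 1/dp2).

CASCADE_PATTERN <- cbind(i = c(1L, 2L, 2L, 3L, 3L, 4L, 4L),
                         j = c(1L, 1L, 2L, 2L, 3L, 3L, 4L))

count_fluxes <- function(counts, params, mode, clamp = NULL) {
  pr <- production_rates(counts / params$Omega, params, mode, clamp = clamp)
  list(gain = params$Omega * c(pr$mrna[1], pr$protein[1],
                               pr$mrna[2], pr$protein[2]),
       loss = c(params$dm1, params$dp1, params$dm2, params$dp2) *
         as.numeric(counts))
}

#' Static susceptibility matrix and lifetimes
#'
#' Computes `H[i, j] = d ln(J_i^-/J_i^+)/d ln(x_j)` by central differences
#' in log space (relative step `1e-6`) at the stationary means, restricted
#' to the cascade coupling pattern (diagonals plus the chain M1 -> P1 ->
#' M2 -> P2). Diagonal entries equal 1 in every regime: each species' loss
#' is first-order in itself and its own gain does not depend on it.
#'
#' @inheritParams ode_rhs
#' @param means Stationary concentration 4-vector; default is the closed
#'   form for `"unlimited"`/`"orthogonal"` and the single stable state for
#'   `"shared"` (error if bistable — pass the branch mean explicitly).
#' @return List with `H` (4x4), `tau` (lifetimes), `means_counts`
#'   (Omega-scaled stationary counts).
#' @export
susceptibilities <- function(params, mode, means = NULL) {
  stopifnot(is.circuit_params(params))
  mode <- match_mode(mode)
  means <- resolve_means(params, mode, means)
  N <- conc_to_counts(means, params)
  if (any(N <= 0)) stop("zero mean count: log-derivative undefined")
  H <- diag(4)  # diagonals are exactly 1 in every regime: the loss flux is
                # first-order in its own species and the gain never is
  h <- 1e-6
  offdiag <- CASCADE_PATTERN[CASCADE_PATTERN[, "i"] != CASCADE_PATTERN[, "j"], ,
                             drop = FALSE]
  for (k in seq_len(nrow(offdiag))) {
    i <- offdiag[k, "i"]; j <- offdiag[k, "j"]
    up <- dn <- as.numeric(N)
    up[j] <- up[j] * exp(h); dn[j] <- dn[j] * exp(-h)
    fu <- count_fluxes(up, params, mode)
    fd <- count_fluxes(dn, params, mode)
    H[i, j] <- (log(fu$loss[i] / fu$gain[i]) -
                log(fd$loss[i] / fd$gain[i])) / (2 * h)
  }
  list(H = H,
       tau = c(1 / params$dm1, 1 / params$dp1, 1 / params$dm2, 1 / params$dp2),
       means_counts = N, means = means, mode = mode)
}

resolve_means <- function(params, mode, means) {
  if (!is.null(means)) return(means)
  if (mode %in% c("unlimited", "orthogonal"))
    return(steady_state_closed_form(params, mode))
  ss <- Filter(function(s) s$stable, find_steady_states(params, mode))
  if (length(ss) != 1L)
    stop("shared regime is not monostable here; pass 'means' explicitly")
  ss[[1]]$state
}

#' Total noise by Lyapunov solve of the normalized FDT
#'
#' Solves `A eta + eta A' + D = 0` (via the Kronecker-vectorized 16x16
#' linear system) for the normalized stationary covariance; the diagonal is
#' the total noise `eta^2` of each species. Exact for the `"unlimited"` and
#' `"orthogonal"` regimes; for `"shared"` the result is a linear-noise
#' approximation restricted to the cascade couplings and is flagged with a
#' warning (the shared-regime results of record are simulation-based).
#'
#' @inheritParams susceptibilities
#' @return 4x4 symmetric matrix with dimnames `(M1, P1, M2, P2)`; attribute
#'   `"means_counts"` holds the Omega-scaled means.
#' @export
lyapunov_noise <- function(params, mode, means = NULL) {
  mode <- match_mode(mode)
  if (mode == "shared")
    warning("shared regime: linear-noise approximation over cascade ",
            "couplings only; simulation is the reference there")
  su <- susceptibilities(params, mode, means)
  A <- -su$H / su$tau          # row i scaled by 1/tau_i
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= 0)) stop("drift matrix not Hurwitz: unstable point")
  D <- diag(2 / (su$tau * su$means_counts))
  n <- 4L
  K <- kronecker(diag(n), A) + kronecker(A, diag(n))
  eta <- matrix(solve(K, -as.vector(D)), n, n)
  eta <- (eta + t(eta)) / 2
  dimnames(eta) <- list(c("M1", "P1", "M2", "P2"), c("M1", "P1", "M2", "P2"))
  attr(eta, "means_counts") <- su$means_counts
  attr(eta, "susceptibilities") <- su
  eta
}

#' Closed-form cascade decomposition of the total noise
#'
#' Evaluates the source-attributed components of each species' stationary
#' noise for the regimes with an exact analytical solution. Writing
#' `a_i = 1/tau_i` and `T_i = a_i / (a_(i-1) + a_i)` for the time-averaging
#' factors, the components are
#'
#' * `eta2(m1<-m1) = 1/M1`
#' * `eta2(p1<-p1) = 1/P1`;
#'   `eta2(p1<-m1) = eta2(m1<-m1) H21^2 a2/(a1+a2)`
#' * `eta2(m2<-m2) = 1/M2`;
#'   `eta2(m2<-p1) = eta2(p1<-p1) H32^2 a3/(a2+a3)`;
#'   `eta2(m2<-p1<-m1) = eta2(p1<-m1) (1 + a2/(a1+a3)) H32^2 a3/(a2+a3)`
#' * `eta2(p2<-p2) = 1/P2`;
#'   `eta2(p2<-m2) = eta2(m2<-m2) H43^2 a4/(a3+a4)`;
#'   `eta2(p2<-m2<-p1) = eta2(m2<-p1) (1 + a3/(a2+a4)) H43^2 a4/(a3+a4)`;
#'   `eta2(p2<-m2<-p1<-m1) = eta2(m2<-p1<-m1) *
#'      (1 + a3/(a2+a4) * (1 + a2/(a1+a2+a3) * (a2+a3)/(a1+a4))) *
#'      H43^2 a4/(a3+a4)`
#'
#' The components of each species sum exactly to the corresponding diagonal
#' of [lyapunov_noise()] (this closure is enforced in the test suite to
#' 1e-8 and certifies the nested time-averaging factors).
#'
#' @inheritParams susceptibilities
#' @return An object of class `rc_noise`: list with `components` (named
#'   numeric vectors per species, names using the `"alpha<-beta"` arrow
#'   convention), `totals` (per species) and the susceptibility structure.
#' @export
decompose_noise <- function(params, mode, means = NULL) {
  mode <- match_mode(mode)
  su <- susceptibilities(params, mode, means)
  N <- su$means_counts
  a <- 1 / su$tau
  H21 <- su$H[2, 1]; H32 <- su$H[3, 2]; H43 <- su$H[4, 3]
  m1_m1 <- 1 / N[["M1"]]
  p1_p1 <- 1 / N[["P1"]]
  p1_m1 <- m1_m1 * H21^2 * a[2] / (a[1] + a[2])
  m2_m2 <- 1 / N[["M2"]]
  m2_p1 <- p1_p1 * H32^2 * a[3] / (a[2] + a[3])
  m2_p1_m1 <- p1_m1 * (1 + a[2] / (a[1] + a[3])) * H32^2 * a[3] / (a[2] + a[3])
  p2_p2 <- 1 / N[["P2"]]
  p2_m2 <- m2_m2 * H43^2 * a[4] / (a[3] + a[4])
  p2_m2_p1 <- m2_p1 * (1 + a[3] / (a[2] + a[4])) * H43^2 * a[4] / (a[3] + a[4])
  p2_m2_p1_m1 <- m2_p1_m1 *
    (1 + a[3] / (a[2] + a[4]) *
       (1 + a[2] / (a[1] + a[2] + a[3]) * (a[2] + a[3]) / (a[1] + a[4]))) *
    H43^2 * a[4] / (a[3] + a[4])
  comp <- list(
    m1 = c("m1<-m1" = m1_m1),
    p1 = c("p1<-p1" = p1_p1, "p1<-m1" = p1_m1),
    m2 = c("m2<-m2" = m2_m2, "m2<-p1" = m2_p1, "m2<-p1<-m1" = m2_p1_m1),
    p2 = c("p2<-p2" = p2_p2, "p2<-m2" = p2_m2, "p2<-m2<-p1" = p2_m2_p1,
           "p2<-m2<-p1<-m1" = p2_m2_p1_m1))
  structure(list(components = comp,
                 totals = vapply(comp, sum, 0),
                 susceptibilities = su, mode = mode),
            class = "rc_noise")
}

#' @export
print.rc_noise <- function(x, ...) {
  cat("<rc_noise>", x$mode, "resources; total eta^2:\n")
  print(signif(x$totals, 4))
  invisible(x)
}

#' Analytical noise components across an inducer-dose grid
#'
#' @inheritParams susceptibilities
#' @param doses Grid of `I1` values.
#' @return Tidy data.frame with columns `I1`, `species`, `component`,
#'   `eta2` (components plus a `"total"` row per species).
#' @export
fdt_noise_curves <- function(params, mode, doses) {
  rows <- list()
  for (d in doses) {
    dec <- decompose_noise(update_params(params, I1 = d), mode)
    for (sp in names(dec$components)) {
      comp <- dec$components[[sp]]
      rows[[length(rows) + 1]] <- data.frame(
        I1 = d, species = sp,
        component = c(names(comp), "total"),
        eta2 = c(unname(comp), sum(comp)))
    }
  }
  do.call(rbind, rows)
}
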