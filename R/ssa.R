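#' Reaction channels of the stochastic cascade
#'
#' The stochastic model has exactly 8 channels: birth and death for each of
#' (M1, P1, M2, P2). Propensities are the deterministic concentration-space
#' fluxes evaluated at `(M/Omega, P/Omega)` and multiplied by `Omega`;
#' deaths are mass-action (`dm_i * M_i`, `dp_i * P_i`) and vanish at zero
#' counts. With `clamp = c(m1c, m2c)` (shared mode only), the opposing
#' mRNA concentration inside gene i's translation partition is replaced by
#' its clamped mean while all other occurrences stay live — this preserves
#' the level of resource competition but removes resource-competitive noise.
#'
#' @inheritParams ode_rhs
#' @param clamp Optional length-2 numeric, clamped mean mRNA concentrations
#'   `c(m1, m2)`; only allowed with `mode = "shared"`.
#' @return A list of 8 channels, each with `label`, `change` (integer
#'   4-vector over (M1, P1, M2, P2)) and `propensity(counts)`.
#' @export
build_propensities <- function(params, mode, clamp = NULL) {
  stopifnot(is.circuit_params(params))
  mode <- match_mode(mode)
  if (!is.null(clamp)) {
    if (mode != "shared") stop("clamping requires mode = 'shared'")
    if (length(clamp) != 2L || any(!is.finite(clamp)) || any(clamp < 0))
      stop("clamp must be two non-negative mRNA concentrations c(m1, m2)")
  }
  labels <- c("m1_birth", "m1_death", "p1_birth", "p1_death",
              "m2_birth", "m2_death", "p2_birth", "p2_death")
  changes <- list(c(1L, 0L, 0L, 0L), c(-1L, 0L, 0L, 0L),
                  c(0L, 1L, 0L, 0L), c(0L, -1L, 0L, 0L),
                  c(0L, 0L, 1L, 0L), c(0L, 0L, -1L, 0L),
                  c(0L, 0L, 0L, 1L), c(0L, 0L, 0L, -1L))
  deaths <- c(NA, 1, NA, 2, NA, 3, NA, 4)
  drates <- c(NA, params$dm1, NA, params$dp1, NA, params$dm2, NA, params$dp2)
  mk <- function(k) {
    force(k)
    function(counts) {
      if (any(counts < 0)) stop("negative counts")
      if (!is.na(deaths[k])) return(drates[k] * counts[[deaths[k]]])
      pr <- production_rates(counts / params$Omega, params, mode,
                             clamp = clamp)
      params$Omega * switch(labels[k],
                            m1_birth = pr$mrna[1], p1_birth = pr$protein[1],
                            m2_birth = pr$mrna[2], p2_birth = pr$protein[2])
    }
  }
  lapply(seq_along(labels), function(k)
    list(label = labels[k], change = changes[[k]], propensity = mk(k)))
}

mode_code <- function(mode) match(mode, resource_modes()) - 1L

default_init <- function(params, mode, branch = NULL) {
  ss <- find_steady_states(params, mode)
  stab <- Filter(function(s) s$stable, ss)
  if (length(stab) == 1L) {
    st <- stab[[1]]$state
  } else if (length(stab) >= 2L) {
    if (is.null(branch))
      stop("bistable parameters: name the starting branch ",
           "('gfp_high' or 'gfp_low') or give 'init' explicitly")
    p1s <- vapply(stab, function(s) s$state[["p1"]], 0)
    st <- switch(branch,
                 gfp_high = stab[[which.max(p1s)]]$state,
                 gfp_low = stab[[which.min(p1s)]]$state,
                 stop("branch must be 'gfp_high' or 'gfp_low'"))
  } else stop("no stable steady state found for initial condition")
  round(conc_to_counts(st, params))
}

#' Exact Gillespie simulation of the cascade
#'
#' Direct-method stochastic simulation: exponential waiting times with rate
#' equal to the total propensity, channel chosen proportionally. Sampling is
#' on a regular grid (default `dt = 0.1` lifetimes) to bound memory;
#' `record_events = TRUE` stores every event instead. The same
#' `(seed, params, mode, init, t_end)` reproduces the trajectory bit-exactly
#' (R's RNG is used throughout).
#'
#' @inheritParams build_propensities
#' @param t_end Simulation length (time units; mRNA lifetimes at defaults).
#' @param seed Integer seed (`set.seed` is called; pass `NULL` to continue
#'   the current RNG stream).
#' @param init Initial count 4-vector; default is the deterministic steady
#'   state times `Omega`, rounded (for bistable parameters name `branch`).
#' @param branch `"gfp_high"` or `"gfp_low"`, used when the default initial
#'   condition is requested at bistable parameters.
#' @param dt Sampling grid step.
#' @param record_events Store the full event sequence instead of grid samples.
#' @param burn_in Fraction of `t_end` excluded from stationary statistics
#'   downstream (recorded in the object; default 0.2).
#' @return An object of class `rc_trajectory`: list with `times`, `counts`
#'   (matrix, columns M1, P1, M2, P2), `params`, `mode`, `seed`, `clamp`,
#'   `t_end`, `dt`, `burn_in`, `n_events`.
#' @examples
#' \donttest{
#' tr <- gillespie_run(circuit_params(), "unlimited", t_end = 50, seed = 1)
#' colMeans(tr$counts)
#' }
#' @export
gillespie_run <- function(params, mode, t_end, seed = NULL, init = NULL,
                          branch = NULL, dt = 0.1, clamp = NULL,
                          record_events = FALSE, burn_in = 0.2) {
  stopifnot(is.circuit_params(params))
  mode <- match_mode(mode)
  if (t_end <= 0) stop("t_end must be positive")
  if (!is.null(clamp) && mode != "shared")
    stop("clamping requires mode = 'shared'")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- default_init(params, mode, branch)
  if (any(init < 0) || any(init != round(init)))
    stop("init must be non-negative integer counts")
  clamp_vec <- if (is.null(clamp)) c(NA_real_, NA_real_) else as.numeric(clamp)
  res <- .ssa_run(as.numeric(unclass(params)[PARAM_NAMES]), mode_code(mode),
                  as.numeric(init), t_end, dt, clamp_vec,
                  record_events = record_events)
  structure(list(times = res$times, counts = res$counts,
                 params = params, mode = mode, seed = seed,
                 clamp = if (is.null(clamp)) NULL else clamp_vec,
                 init = init, t_end = t_end, dt = dt, burn_in = burn_in,
                 n_events = res$n_events),
            class = "rc_trajectory")
}

#' @export
print.rc_trajectory <- function(x, ...) {
  cat("<rc_trajectory>", x$mode, "resources, t_end =", x$t_end,
      if (!is.null(x$clamp)) "(clamped-mean)", "\n")
  cat("  ", nrow(x$counts), "samples,", format(x$n_events, big.mark = ","),
      "events; final counts:",
      paste(x$counts[nrow(x$counts), ], collapse = ", "), "\n")
  invisible(x)
}

#' Clamped-mean simulation: resource competition without competitive noise
#'
#' Runs the shared-resource simulator with each gene's *opposing* mRNA level
#' inside its translation partition frozen at a mean value, removing the
#' noise transmitted through ribosome competition while keeping its average
#' effect. The clamping means come either from the deterministic steady
#' state of the shared model (`reference = "deterministic"`; at bistable
#' parameters the caller must name the `branch`) or from the time-average of
#' an unclamped burn-in run (`reference = "empirical"`).
#'
#' @inheritParams gillespie_run
#' @param reference `"deterministic"` or `"empirical"`.
#' @param burn_run_t Length of the unclamped reference run for
#'   `reference = "empirical"` (default 1000).
#' @param ... Passed on to [gillespie_run()].
#' @return An `rc_trajectory` (with its `clamp` field set).
#' @export
clamped_mean_run <- function(params, t_end, seed = NULL,
                             reference = c("deterministic", "empirical"),
                             branch = NULL, burn_run_t = 1000, ...) {
  stopifnot(is.circuit_params(params))
  reference <- match.arg(reference)
  if (!is.null(seed)) set.seed(seed)
  if (reference == "deterministic") {
    ss <- find_steady_states(params, "shared")
    stab <- Filter(function(s) s$stable, ss)
    if (length(stab) >= 2L && is.null(branch))
      stop("bistable parameters: name the clamping branch ",
           "('gfp_high' or 'gfp_low')")
    st <- if (length(stab) == 1L) stab[[1]]$state else {
      p1s <- vapply(stab, function(s) s$state[["p1"]], 0)
      switch(branch,
             gfp_high = stab[[which.max(p1s)]]$state,
             gfp_low = stab[[which.min(p1s)]]$state,
             stop("branch must be 'gfp_high' or 'gfp_low'"))
    }
    clamp <- c(st[["m1"]], st[["m2"]])
    init <- round(conc_to_counts(st, params))
  } else {
    ref <- gillespie_run(params, "shared", t_end = burn_run_t, seed = NULL,
                         branch = branch, ...)
    keep <- ref$times >= ref$burn_in * ref$t_end
    mM <- colMeans(ref$counts[keep, , drop = FALSE])
    clamp <- c(mM[["M1"]], mM[["M2"]]) / params$Omega
    init <- round(mM)
  }
  gillespie_run(params, "shared", t_end = t_end, seed = NULL, init = init,
                clamp = clamp, ...)
}

#' Deterministic per-task seed schedule
#'
#' Derives `n` child seeds from a master seed by drawing from R's RNG after
#' `set.seed(master)`; all seeds are `< 2^31` and the schedule depends only
#' on `(master, n)`.
#'
#' @param master Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
seed_schedule <- function(master, n) {
  set.seed(master)
  sample.int(.Machine$integer.max, n)
}

#' Dose sweep of stochastic simulations
#'
#' Runs `reps` independent simulations at each inducer dose `I1`, with a
#' deterministic seed schedule derived from `master_seed`. To bound memory
#' on long sweeps, per-run stationary summaries can be kept instead of full
#' trajectories (`summarise = "stationary"`). At bistable doses the initial
#' branch alternates between replicates (odd reps start GFP-low, even reps
#' GFP-high) so the ensemble explores both basins.
#'
#' @inheritParams gillespie_run
#' @param doses Numeric vector of `I1` values.
#' @param reps Replicates per dose.
#' @param master_seed Integer master seed for the schedule.
#' @param summarise `"none"` keeps trajectories; `"stationary"` keeps only
#'   [stationary_summary()] tables.
#' @param clamp_reference If non-`NULL`, every run is a [clamped_mean_run()]
#'   with this reference policy.
#' @return An object of class `rc_sweep`: list with `doses`, `runs` (list
#'   over doses of lists over reps), `summarise`, `master_seed`, provenance.
#' @export
dose_sweep <- function(params, mode, doses, reps = 10, t_end = 5000,
                       master_seed = 1, dt = 0.1,
                       summarise = c("none", "stationary"),
                       clamp_reference = NULL, burn_in = 0.2) {
  stopifnot(is.circuit_params(params))
  mode <- match_mode(mode)
  summarise <- match.arg(summarise)
  seeds <- matrix(seed_schedule(master_seed, length(doses) * reps),
                  nrow = length(doses))
  runs <- vector("list", length(doses))
  for (d in seq_along(doses)) {
    pd <- update_params(params, I1 = doses[d])
    nstab <- tryCatch(n_stable(find_steady_states(pd, mode)),
                      error = function(e) 1L)
    runs[[d]] <- vector("list", reps)
    for (r in seq_len(reps)) {
      branch <- if (nstab >= 2) c("gfp_low", "gfp_high")[(r %% 2) + 1] else NULL
      tr <- if (is.null(clamp_reference)) {
        gillespie_run(pd, mode, t_end = t_end, seed = seeds[d, r],
                      branch = branch, dt = dt, burn_in = burn_in)
      } else {
        clamped_mean_run(pd, t_end = t_end, seed = seeds[d, r],
                         reference = clamp_reference, branch = branch,
                         dt = dt, burn_in = burn_in)
      }
      runs[[d]][[r]] <- if (summarise == "stationary")
        stationary_summary(tr) else tr
    }
  }
  structure(list(doses = doses, runs = runs, reps = reps, mode = mode,
                 params = params, t_end = t_end, dt = dt,
                 master_seed = master_seed, summarise = summarise,
                 clamped = !is.null(clamp_reference), burn_in = burn_in),
            class = "rc_sweep")
}

#' Write a trajectory as CSV with a JSON provenance sidecar
#'
#' @param traj An `rc_trajectory`.
#' @param csv_path Output CSV (columns `t, M1, P1, M2, P2`).
#' @param json_path Optional sidecar path (default: `csv_path` with
#'   `.json` extension) holding params, mode, seed, clamp and grid info.
#' @return Invisibly, `csv_path`.
#' @export
export_trajectory <- function(traj, csv_path,
                              json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(traj, "rc_trajectory"))
  df <- data.frame(t = traj$times, traj$counts)
  utils::write.csv(df, csv_path, row.names = FALSE)
  side <- list(params = unclass(traj$params), mode = traj$mode,
               seed = traj$seed, clamp = traj$clamp, t_end = traj$t_end,
               dt = traj$dt, burn_in = traj$burn_in,
               n_events = traj$n_events)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(csv_path)
}
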