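# Bifurcation analysis by grid scan + bisection. The system is 4D and cheap
# (steady states come from an exact scalar reduction), so robustness wins
# over pseudo-arclength elegance.

set_swept <- function(params, name, value) {
  args <- stats::setNames(list(value), name)
  do.call(update_params, c(list(params), args))
}

count_states_at <- function(value, params, mode, name, n_grid = 4000) {
  ss <- find_steady_states(set_swept(params, name, value), mode,
                           n_grid = n_grid)
  c(total = length(ss), stable = n_stable(ss))
}

#' One-parameter bifurcation diagram with saddle-node localization
#'
#' Sweeps a single parameter over a grid, records every steady state with
#' stability at each grid value, and refines each change in the number of
#' stable states (a saddle-node, where a stable/unstable pair is created or
#' destroyed) by bisection to `|delta param| < tol`.
#'
#' The pseudo-parameter `"inv_Jp2"` sweeps the RFP resource competitivity
#' `1/Jp2`.
#'
#' @inheritParams ode_rhs
#' @param parameter Name of the swept parameter (a [circuit_params()] field
#'   or `"inv_Jp2"`).
#' @param range Length-2 numeric, `lo < hi`.
#' @param resolution Number of grid points (default 400).
#' @param sn_tol Bisection tolerance on the swept parameter (default 1e-3).
#' @return An object of class `rc_bifurcation`: list with `parameter`,
#'   `grid`, `branches` (per grid value, the [find_steady_states()] list),
#'   `points` (tidy data.frame: value, branch id, state, stable) and
#'   `sn_points` (data.frame: `value` of the parameter at each saddle-node
#'   and the approximate merging state columns `m1, p1, m2, p2`).
#' @examples
#' \donttest{
#' bd <- bifurcation_1d(circuit_params(), "shared", "I1", c(0, 2))
#' bd$sn_points$value  # ~0.875 and ~1.129
#' }
#' @export
bifurcation_1d <- function(params, mode, parameter, range,
                           resolution = 400, sn_tol = 1e-3) {
  stopifnot(is.circuit_params(params))
  mode <- match_mode(mode)
  if (length(range) != 2L || range[1] >= range[2])
    stop("'range' must be c(lo, hi) with lo < hi")
  grid <- seq(range[1], range[2], length.out = resolution)
  branches <- vector("list", resolution)
  nstab <- integer(resolution)
  for (i in seq_len(resolution)) {
    p_i <- tryCatch(set_swept(params, parameter, grid[i]),
                    error = function(e) NULL)
    if (is.null(p_i))
      stop("range leaves the positivity domain of '", parameter, "'")
    branches[[i]] <- suppressWarnings(find_steady_states(p_i, mode))
    nstab[i] <- n_stable(branches[[i]])
  }
  sn <- list()
  for (i in which(diff(nstab) != 0)) {
    lo <- grid[i]; hi <- grid[i + 1]
    n_lo <- nstab[i]
    while (hi - lo > sn_tol) {
      mid <- (lo + hi) / 2
      n_mid <- count_states_at(mid, params, mode, parameter)["stable"]
      if (n_mid == n_lo) lo <- mid else hi <- mid
    }
    val <- (lo + hi) / 2
    # approximate merging state: the closest stable/unstable pair just inside
    # the side with more steady states
    side <- if (length(branches[[i]]) >= length(branches[[i + 1]])) i else i + 1
    st <- merging_pair_state(branches[[side]])
    sn[[length(sn) + 1]] <- c(value = val, st)
  }
  sn_points <- if (length(sn)) as.data.frame(do.call(rbind, sn))
               else data.frame(value = numeric(0), m1 = numeric(0),
                               p1 = numeric(0), m2 = numeric(0),
                               p2 = numeric(0))
  structure(list(parameter = parameter, grid = grid, branches = branches,
                 points = branch_table(grid, branches, parameter),
                 sn_points = sn_points, mode = mode, params = params),
            class = "rc_bifurcation")
}

merging_pair_state <- function(ss) {
  if (length(ss) < 2) {
    if (!length(ss)) return(c(m1 = NA, p1 = NA, m2 = NA, p2 = NA))
    return(ss[[1]]$state)
  }
  p1s <- vapply(ss, function(s) s$state[["p1"]], 0)
  stab <- vapply(ss, `[[`, logical(1), "stable")
  best <- c(NA_integer_, NA_integer_); bestd <- Inf
  for (a in seq_along(ss)) for (b in seq_along(ss)) {
    if (stab[a] && !stab[b] && abs(p1s[a] - p1s[b]) < bestd) {
      bestd <- abs(p1s[a] - p1s[b]); best <- c(a, b)
    }
  }
  if (is.na(best[1])) return(ss[[1]]$state)
  (ss[[best[1]]]$state + ss[[best[2]]]$state) / 2
}

# tidy table with nearest-neighbour branch matching on p1 between
# consecutive grid points
branch_table <- function(grid, branches, parameter) {
  rows <- list()
  prev_p1 <- numeric(0); prev_id <- integer(0); next_id <- 1L
  for (i in seq_along(grid)) {
    ss <- branches[[i]]
    if (!length(ss)) { prev_p1 <- numeric(0); prev_id <- integer(0); next }
    p1s <- vapply(ss, function(s) s$state[["p1"]], 0)
    ids <- integer(length(ss))
    used <- logical(length(prev_id))
    for (k in order(p1s)) {
      if (length(prev_p1)) {
        d <- abs(prev_p1 - p1s[k]); d[used] <- Inf
        j <- which.min(d)
        if (is.finite(d[j]) && d[j] < 0.5 * max(diff(range(c(prev_p1, p1s))), 1)) {
          ids[k] <- prev_id[j]; used[j] <- TRUE; next
        }
      }
      ids[k] <- next_id; next_id <- next_id + 1L
    }
    for (k in seq_along(ss)) {
      st <- ss[[k]]$state
      rows[[length(rows) + 1]] <- data.frame(
        value = grid[i], branch = ids[k], m1 = st[["m1"]], p1 = st[["p1"]],
        m2 = st[["m2"]], p2 = st[["p2"]], stable = ss[[k]]$stable)
    }
    prev_p1 <- p1s; prev_id <- ids
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- parameter
  out
}

#' @export
print.rc_bifurcation <- function(x, ...) {
  cat("<rc_bifurcation> sweep of", x$parameter, "over [",
      min(x$grid), ",", max(x$grid), "],", length(x$grid), "points,",
      x$mode, "resources\n")
  if (nrow(x$sn_points)) {
    cat("  saddle-node points at", x$parameter, "=",
        paste(signif(x$sn_points$value, 5), collapse = ", "), "\n")
  } else cat("  no saddle-node points (monostable throughout)\n")
  invisible(x)
}

#' Two-parameter bifurcation diagram (saddle-node curves and cusp)
#'
#' For each value of the second parameter, runs [bifurcation_1d()] over the
#' first and records the 0 or 2 saddle-node locations; the region between
#' the two curves is bistable. The cusp — the `p_y` value below which the
#' saddle nodes vanish — is refined by bisection.
#'
#' @inheritParams bifurcation_1d
#' @param p_x,p_y Lists `list(name =, range =)` for the two swept parameters
#'   (e.g. `p_y = list(name = "inv_Jp2", range = c(0, 1))`).
#' @param resolution_y Grid size for `p_y` (default 21).
#' @param resolution_x Grid size of each inner 1D sweep (default 200).
#' @param cusp_tol Bisection tolerance on `p_y` for the cusp.
#' @return List with `sn_curves` (data.frame: y, sn_lower, sn_upper; `NA`
#'   rows where monostable) and `cusp` (the refined `p_y` value, or `NA` if
#'   the whole range is on one side).
#' @export
bifurcation_2d <- function(params, mode, p_x, p_y,
                           resolution_y = 21, resolution_x = 200,
                           cusp_tol = 1e-3) {
  stopifnot(is.circuit_params(params))
  mode <- match_mode(mode)
  ygrid <- seq(p_y$range[1], p_y$range[2], length.out = resolution_y)
  sn_at_y <- function(y) {
    py <- set_swept(params, p_y$name, y)
    bd <- bifurcation_1d(py, mode, p_x$name, p_x$range,
                         resolution = resolution_x)
    bd$sn_points$value
  }
  lower <- upper <- rep(NA_real_, resolution_y)
  for (i in seq_along(ygrid)) {
    sn <- sn_at_y(ygrid[i])
    if (length(sn) >= 2) { lower[i] <- min(sn); upper[i] <- max(sn) }
  }
  bist <- !is.na(lower)
  cusp <- NA_real_
  if (any(bist) && any(!bist)) {
    # bisect between the largest monostable y below the bistable block and
    # the smallest bistable y
    i_in <- min(which(bist))
    if (i_in > 1) {
      lo <- ygrid[i_in - 1]; hi <- ygrid[i_in]
      while (hi - lo > cusp_tol) {
        mid <- (lo + hi) / 2
        if (length(sn_at_y(mid)) >= 2) hi <- mid else lo <- mid
      }
      cusp <- (lo + hi) / 2
    }
  }
  list(sn_curves = data.frame(y = ygrid, sn_lower = lower, sn_upper = upper),
       cusp = cusp, p_x = p_x, p_y = p_y, mode = mode)
}

#' Sensitivity of the saddle-node points to parameter perturbations
#'
#' Perturbs each model parameter (excluding `Omega` and the swept inducer
#' `I1`) by `+delta` and `-delta` (relative), reruns the one-parameter
#' bifurcation in `I1`, and reports the percent change of both saddle-node
#' locations relative to baseline. Loss of bistability under a perturbation
#' is recorded as such (`bistable = FALSE`, `NA` shifts).
#'
#' @inheritParams bifurcation_1d
#' @param delta Relative perturbation (default 0.20).
#' @param sweep_range Range of the `I1` sweep (default `c(0, 2)`).
#' @param resolution Inner sweep resolution (default 200).
#' @param parameters Which parameters to perturb (default: all except
#'   `Omega` and `I1`).
#' @return Data.frame with columns `parameter`, `direction` (`"baseline"`,
#'   `"up"`, `"down"`), `sn1`, `sn2` (I1 values), `d_sn1_pct`, `d_sn2_pct`,
#'   `bistable`.
#' @export
sensitivity_sn <- function(params, mode = "shared", delta = 0.20,
                           sweep_range = c(0, 2), resolution = 200,
                           parameters = NULL) {
  stopifnot(is.circuit_params(params))
  mode <- match_mode(mode)
  sn_of <- function(p) {
    bd <- bifurcation_1d(p, mode, "I1", sweep_range, resolution = resolution)
    sn <- sort(bd$sn_points$value)
    if (length(sn) >= 2) c(sn[1], sn[length(sn)]) else c(NA_real_, NA_real_)
  }
  base <- sn_of(params)
  if (any(is.na(base))) stop("baseline is not bistable over the sweep range")
  pars <- if (is.null(parameters)) setdiff(PARAM_NAMES, c("Omega", "I1"))
          else {
            bad <- setdiff(parameters, setdiff(PARAM_NAMES, c("Omega", "I1")))
            if (length(bad)) stop("cannot perturb: ", paste(bad, collapse = ", "))
            parameters
          }
  rows <- list(data.frame(parameter = "(none)", direction = "baseline",
                          sn1 = base[1], sn2 = base[2],
                          d_sn1_pct = 0, d_sn2_pct = 0, bistable = TRUE))
  for (nm in pars) {
    for (dir in c("up", "down")) {
      fac <- if (dir == "up") 1 + delta else 1 - delta
      sn <- if (delta == 0) base else
        sn_of(set_swept(params, nm, params[[nm]] * fac))
      rows[[length(rows) + 1]] <- data.frame(
        parameter = nm, direction = dir, sn1 = sn[1], sn2 = sn[2],
        d_sn1_pct = 100 * (sn[1] - base[1]) / base[1],
        d_sn2_pct = 100 * (sn[2] - base[2]) / base[2],
        bistable = !any(is.na(sn)))
    }
  }
  do.call(rbind, rows)
}

#' Export a bifurcation diagram as tidy CSV plus a JSON saddle-node sidecar
#'
#' @param bd An `rc_bifurcation` object.
#' @param csv_path,json_path Output file paths (either may be `NULL`).
#' @return Invisibly, the tidy points table.
#' @export
export_bifurcation <- function(bd, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(bd, "rc_bifurcation"))
  if (!is.null(csv_path))
    utils::write.csv(bd$points, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(parameter = bd$parameter, mode = bd$mode,
                              sn_points = bd$sn_points),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(bd$points)
}
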