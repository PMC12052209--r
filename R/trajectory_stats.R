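#' Stationary moments and CV^2 noise of a trajectory
#'
#' Discards the burn-in segment and computes per-species mean, variance and
#' noise `eta^2 = sigma^2 / mu^2` (squared coefficient of variation) over
#' the regular-grid samples (grid sampling at fixed `dt` makes sample- and
#' time-weighted moments equivalent; event-resolution input is
#' time-weighted). An effective-sample-size estimate from the lag-1
#' autocorrelation is included.
#'
#' @param traj An `rc_trajectory` from [gillespie_run()].
#' @param burn_in Fraction of `t_end` to discard (default: the trajectory's
#'   own `burn_in` field).
#' @return Data.frame with one row per species: `species`, `mean`, `var`,
#'   `eta2` (`NA` when the mean is zero), `n`, `n_eff`.
#' @export
stationary_summary <- function(traj, burn_in = NULL) {
  stopifnot(inherits(traj, "rc_trajectory"))
  if (is.null(burn_in)) burn_in <- traj$burn_in
  t0 <- burn_in * traj$t_end
  keep <- traj$times >= t0
  if (sum(keep) < 2L) stop("trajectory shorter than burn-in")
  x <- traj$counts[keep, , drop = FALSE]
  tt <- traj$times[keep]
  event_res <- length(unique(round(diff(tt), 10))) > 2L
  rows <- lapply(colnames(x), function(sp) {
    v <- as.numeric(x[, sp])
    if (event_res) {
      # time-weighted: state v[k] holds on [tt[k], tt[k+1])
      w <- diff(c(tt, traj$t_end)); w <- w / sum(w)
      mu <- sum(w * v)
      va <- sum(w * (v - mu)^2)
      n_eff <- length(v)
    } else {
      mu <- mean(v)
      va <- stats::var(v)
      rho <- if (va > 0)
        stats::cor(v[-length(v)], v[-1]) else 0
      n_eff <- length(v) * max((1 - rho) / (1 + rho), 1 / length(v))
    }
    data.frame(species = sp, mean = mu, var = va,
               eta2 = if (mu > 0) va / mu^2 else NA_real_,
               n = length(v), n_eff = n_eff)
  })
  out <- do.call(rbind, rows)
  attr(out, "burn_in") <- burn_in
  out
}

#' Local modes and modality of a stationary count distribution
#'
#' Histogram of the post-burn-in counts, smoothed by a centered moving
#' average; local maxima passing both a height floor (relative to the
#' global maximum) and a prominence threshold (relative to their own
#' height) are reported as modes. One prominent mode classifies the
#' distribution as unimodal; two or more as bimodal, keeping the two
#' tallest, with the anti-mode at the minimum of the smoothed histogram
#' between them.
#'
#' By default the histogram is built on a square-root count scale
#' (variance-stabilizing for birth-death counts), which renders the two
#' metastable peaks at comparable widths; on the raw scale a broad
#' high-expression state can be flattened below any prominence threshold by
#' the much narrower low state. Mode and anti-mode locations are reported
#' back on the count scale. Bin width defaults to Freedman-Diaconis on the
#' working scale (floor of 1 count on the raw scale).
#'
#' @inheritParams stationary_summary
#' @param species One of `"M1", "P1", "M2", "P2"`.
#' @param bin_width Histogram bin width on the working scale; default
#'   Freedman-Diaconis.
#' @param smooth_window Moving-average window (bins).
#' @param prominence Height floor as a fraction of the global maximum
#'   (default 0.05): candidate modes shorter than this are ignored.
#' @param rel_prominence Prominence threshold as a fraction of the
#'   candidate peak's own height (default 0.1), making the criterion
#'   scale-free: a broad low mode next to a tall narrow one is kept, while
#'   histogram-noise twins on a single state are rejected.
#' @param transform `"sqrt"` (default) or `"identity"` working scale.
#' @return List with `modes` (count values at the local maxima, ascending),
#'   `modality` (`"unimodal"` or `"bimodal"`), `anti_mode` (`NA` unless
#'   bimodal), `heights`, and the smoothed histogram (`breaks`, `density`,
#'   on the working scale).
#' @export
detect_modes <- function(traj, species, burn_in = NULL, bin_width = NULL,
                         smooth_window = 3, prominence = 0.05,
                         rel_prominence = 0.1,
                         transform = c("sqrt", "identity")) {
  stopifnot(inherits(traj, "rc_trajectory"))
  transform <- match.arg(transform)
  if (is.null(burn_in)) burn_in <- traj$burn_in
  keep <- traj$times >= burn_in * traj$t_end
  v <- as.numeric(traj$counts[keep, species])
  if (!length(v)) stop("empty stationary segment")
  w <- if (transform == "sqrt") sqrt(v) else v
  if (is.null(bin_width)) {
    fd <- 2 * stats::IQR(w) / length(w)^(1 / 3)
    bin_width <- if (transform == "identity") max(1, round(fd))
                 else max(fd, 0.25)
  }
  if (transform == "sqrt") {
    # spread each integer count's mass over its unit interval before
    # binning on the sqrt scale; otherwise bins alternately swallow 2 or 3
    # lattice points and the histogram inherits a systematic sawtooth
    h <- sqrt_binned_mass(v, bin_width)
  } else {
    breaks <- seq(min(w) - 0.5, max(w) + bin_width + 0.5, by = bin_width)
    h <- graphics::hist(w, breaks = breaks, plot = FALSE)
  }
  d <- smooth_ma(h$counts, smooth_window)
  pk <- find_peaks(d)
  hts_all <- d[pk$index]
  prom_ok <- hts_all >= prominence * max(d) &
    pk$prominence >= rel_prominence * hts_all
  idx <- pk$index[prom_ok]
  hts <- d[idx]
  if (length(idx) > 2L) {
    top <- order(hts, decreasing = TRUE)[1:2]
    idx <- sort(idx[top]); hts <- d[idx]
  }
  back <- function(x) if (transform == "sqrt") x^2 else x
  modes <- back(h$mids[idx])
  modality <- if (length(idx) >= 2L) "bimodal" else "unimodal"
  anti <- NA_real_
  if (modality == "bimodal") {
    span <- seq(idx[1], idx[2])
    anti <- back(h$mids[span[which.min(d[span])]])
  }
  list(modes = modes, modality = modality, anti_mode = anti,
       heights = hts, breaks = h$breaks, density = d, species = species,
       transform = transform)
}

# mass of integer counts spread uniformly over [k-1/2, k+1/2] and binned on
# the sqrt scale; returns the same fields hist() provides (counts = mass)
sqrt_binned_mass <- function(v, bin_width) {
  tab <- tabulate(v + 1L, nbins = max(v) + 1L)
  kmax <- length(tab) - 1L
  lo <- sqrt(pmax((0:kmax) - 0.5, 0))
  hi <- sqrt((0:kmax) + 0.5)
  breaks <- seq(0, max(hi) + bin_width, by = bin_width)
  d <- numeric(length(breaks) - 1L)
  for (k in which(tab > 0)) {
    a <- lo[k]; b <- hi[k]
    i1 <- findInterval(a, breaks); i2 <- min(findInterval(b, breaks),
                                             length(d))
    for (i in i1:i2)
      d[i] <- d[i] + tab[k] * (min(b, breaks[i + 1]) - max(a, breaks[i])) /
        (b - a)
  }
  list(breaks = breaks, counts = d,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2)
}

smooth_ma <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  n <- length(x)
  xp <- c(rep(x[1], w), x, rep(x[n], w))
  stats::filter(xp, k, sides = 2)[(w + 1):(w + n)]
}

# local maxima with a simple prominence: height minus the higher of the two
# bracketing minima on the walk to the nearest strictly higher point (or the
# edge). Plateaus (runs of tied values) are collapsed to their midpoint so
# histogram ties cannot spawn twin peaks.
find_peaks <- function(d) {
  d <- as.numeric(d)
  n <- length(d)
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  idx <- integer(0)
  for (k in seq_len(nr)) {
    left <- if (k == 1L) -Inf else r$values[k - 1L]
    right <- if (k == nr) -Inf else r$values[k + 1L]
    if (r$values[k] > left && r$values[k] > right)
      idx <- c(idx, as.integer((starts[k] + ends[k]) %/% 2))
  }
  prom <- vapply(idx, function(i) {
    left <- if (any(d[seq_len(i - 1)] > d[i])) {
      j <- max(which(d[seq_len(i - 1)] > d[i]))
      min(d[j:i])
    } else 0
    right <- if (i < n && any(d[(i + 1):n] > d[i])) {
      j <- i + min(which(d[(i + 1):n] > d[i]))
      min(d[i:j])
    } else 0
    d[i] - max(left, right)
  }, 0)
  list(index = idx, prominence = prom)
}

#' Switching events and dwell times of a bimodal trajectory
#'
#' Assigns a two-state (low/high) label by hysteresis thresholding around
#' the anti-mode: the thresholds sit at `anti_mode +/- band * (mode2 -
#' mode1)`, and a switch is only counted when the signal crosses the far
#' threshold, so within-mode fluctuations are not counted as switches.
#'
#' @inheritParams stationary_summary
#' @param modes A [detect_modes()] result with `modality == "bimodal"`.
#' @param band Hysteresis half-width as a fraction of the inter-mode
#'   distance (default 0.25).
#' @return List with `n_switches`, `dwell_times` (per completed visit),
#'   `state` (per-sample factor `"low"/"high"`), `fraction_time`
#'   (named, sums to 1).
#' @export
switching_stats <- function(traj, modes, band = 0.25, burn_in = NULL) {
  stopifnot(inherits(traj, "rc_trajectory"))
  if (modes$modality != "bimodal")
    stop("switching statistics require a bimodal classification")
  if (is.null(burn_in)) burn_in <- traj$burn_in
  keep <- traj$times >= burn_in * traj$t_end
  v <- as.numeric(traj$counts[keep, modes$species])
  tt <- traj$times[keep]
  gap <- diff(modes$modes)
  lo_thr <- modes$anti_mode - band * gap
  hi_thr <- modes$anti_mode + band * gap
  state <- character(length(v))
  cur <- if (abs(v[1] - modes$modes[1]) <= abs(v[1] - modes$modes[2]))
    "low" else "high"
  switches <- integer(0)
  for (i in seq_along(v)) {
    if (cur == "low" && v[i] >= hi_thr) { cur <- "high"; switches <- c(switches, i) }
    else if (cur == "high" && v[i] <= lo_thr) { cur <- "low"; switches <- c(switches, i) }
    state[i] <- cur
  }
  sw_t <- tt[switches]
  dwell <- diff(c(tt[1], sw_t, tt[length(tt)]))
  frac <- tapply(c(diff(tt), traj$dt), state, sum)
  frac <- frac / sum(frac)
  list(n_switches = length(switches), switch_times = sw_t,
       dwell_times = dwell, state = state,
       fraction_time = frac)
}

#' Dose-response mean and noise curves from a stochastic sweep
#'
#' Aggregates a [dose_sweep()] into per-dose, per-species mean and `eta^2`
#' (averaged across replicates), and locates each species' noise peak by
#' parabolic interpolation around the grid argmax.
#'
#' @param sweep An `rc_sweep` object.
#' @return List with `curves` (data.frame: `dose`, `species`, `mean`,
#'   `eta2`, `n_reps`) and `peaks` (data.frame: `species`, `dose_peak`,
#'   `eta2_peak`), plus the sweep provenance carried through.
#' @export
noise_dose_curves <- function(sweep) {
  stopifnot(inherits(sweep, "rc_sweep"))
  rows <- list()
  for (d in seq_along(sweep$doses)) {
    sums <- lapply(sweep$runs[[d]], function(r)
      if (inherits(r, "rc_trajectory")) stationary_summary(r) else r)
    for (sp in c("M1", "P1", "M2", "P2")) {
      mu <- vapply(sums, function(s) s$mean[s$species == sp], 0)
      e2 <- vapply(sums, function(s) s$eta2[s$species == sp], 0)
      rows[[length(rows) + 1]] <- data.frame(
        dose = sweep$doses[d], species = sp,
        mean = mean(mu), eta2 = mean(e2, na.rm = TRUE),
        n_reps = length(sums))
    }
  }
  curves <- do.call(rbind, rows)
  peaks <- do.call(rbind, lapply(c("M1", "P1", "M2", "P2"), function(sp) {
    cc <- curves[curves$species == sp, ]
    pk <- interior_peak(cc$dose, cc$eta2)
    data.frame(species = sp, dose_peak = pk[1], eta2_peak = pk[2])
  }))
  list(curves = curves, peaks = peaks, mode = sweep$mode,
       clamped = sweep$clamped, master_seed = sweep$master_seed)
}

# the noise hump of interest is an interior local maximum: basal-expression
# noise diverges at zero dose, so the global argmax may sit on the grid
# edge. Pick the tallest interior local maximum (plateaus collapsed); fall
# back to the global argmax when the curve is monotone.
interior_peak <- function(x, y) {
  pk <- find_peaks(y)
  interior <- pk$index[pk$index > 1 & pk$index < length(y)]
  if (!length(interior)) return(c(x[which.max(y)], max(y)))
  i <- interior[which.max(y[interior])]
  parabolic_peak(x, y, i)
}

# refine a peak of y(x) by fitting a parabola through grid point i and its
# two neighbours (falls back to the grid argmax at the edges)
parabolic_peak <- function(x, y, i = which.max(y)) {
  if (i == 1L || i == length(y)) return(c(x[i], y[i]))
  x3 <- x[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
  denom <- (y3[1] - 2 * y3[2] + y3[3])
  if (denom >= 0) return(c(x[i], y[i]))
  delta <- 0.5 * (y3[1] - y3[3]) / denom
  xp <- x3[2] + delta * (x3[2] - x3[1])
  yp <- y3[2] - 0.25 * (y3[1] - y3[3]) * delta
  c(xp, yp)
}

#' Stationary correlation between the two proteins
#'
#' Pearson correlation of post-burn-in `P1` and `P2` samples; negative in
#' the bistable window, where the genes alternate in winner-takes-all
#' fashion.
#'
#' @inheritParams stationary_summary
#' @return Scalar correlation.
#' @export
protein_correlation <- function(traj, burn_in = NULL) {
  stopifnot(inherits(traj, "rc_trajectory"))
  if (is.null(burn_in)) burn_in <- traj$burn_in
  keep <- traj$times >= burn_in * traj$t_end
  stats::cor(traj$counts[keep, "P1"], traj$counts[keep, "P2"])
}
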