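# Shared fixtures built in code.

default_params <- circuit_params()

# a trajectory object wrapped around externally supplied samples, for
# feeding constructed signals to the statistics functions
fake_trajectory <- function(counts, dt = 0.1, burn_in = 0) {
  counts <- as.matrix(counts)
  colnames(counts) <- c("M1", "P1", "M2", "P2")[seq_len(ncol(counts))]
  if (ncol(counts) < 4) {
    pad <- matrix(0L, nrow(counts), 4 - ncol(counts))
    counts <- cbind(counts, pad)
    colnames(counts) <- c("M1", "P1", "M2", "P2")
  }
  structure(list(times = seq(0, by = dt, length.out = nrow(counts)),
                 counts = counts, params = default_params, mode = "shared",
                 seed = NA, clamp = NULL, t_end = (nrow(counts) - 1) * dt,
                 dt = dt, burn_in = burn_in, n_events = NA),
            class = "rc_trajectory")
}

# two-state telegraph signal with known switch structure: dwell blocks of
# length `block` samples alternating between lo and hi, with small additive
# wiggle so the histogram has width
telegraph_signal <- function(n_blocks = 20, block = 500, lo = 20, hi = 120,
                             wiggle = 3, seed = 99) {
  set.seed(seed)
  lv <- rep(rep(c(lo, hi), length.out = n_blocks), each = block)
  pmax(0, round(lv + stats::rnorm(length(lv), 0, wiggle)))
}

# random non-negative concentration states
random_states <- function(n, seed = 1, scale = c(10, 150, 5, 60)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) stats::runif(4) * scale)
}

jittered_params <- function(seed, frac = 0.2) {
  set.seed(seed)
  vals <- lapply(unclass(default_params), function(v)
    v * stats::runif(1, 1 - frac, 1 + frac))
  vals$n <- max(1, vals$n)
  do.call(circuit_params, vals)
}
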