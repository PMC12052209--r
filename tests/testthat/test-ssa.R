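test_that("channel structure: 8 reactions, unit steps, mass-action deaths", {
  ch <- build_propensities(default_params, "shared")
  expect_length(ch, 8)
  for (c_k in ch) expect_equal(sum(abs(c_k$change)), 1)
  zero <- c(M1 = 0, P1 = 0, M2 = 0, P2 = 0)
  for (c_k in ch[c(2, 4, 6, 8)]) expect_equal(c_k$propensity(zero), 0)
  expect_error(ch[[1]]$propensity(c(-1, 0, 0, 0)), "negative")
  expect_error(build_propensities(default_params, "unlimited", clamp = c(1, 1)),
               "shared")
})

test_that("propensities are Omega-scaled concentration fluxes", {
  p <- default_params
  st <- c(M1 = 12, P1 = 180, M2 = 2, P2 = 45)
  ch <- build_propensities(p, "unlimited")
  # translation: a(p1_birth) = Omega * kp1 * (M1/Omega) = kp1 * M1
  expect_equal(ch[[3]]$propensity(st), p$kp1 * 12)
  # transcription of gene 2 sees the Hill input at concentration P1/Omega
  R2 <- p$I2 * p$Kg^p$n / ((180 / p$Omega)^p$n + p$Kg^p$n)
  expect_equal(ch[[5]]$propensity(st), p$Omega * (p$km02 + p$km2 * R2))
  # huge capacities: shared propensities match unlimited to 1e-5 relative
  p_inf <- circuit_params(Jm1 = 1e9, Jm2 = 1e9, Jp1 = 1e9, Jp2 = 1e9)
  ch_s <- build_propensities(p_inf, "shared")
  ch_u <- build_propensities(p_inf, "unlimited")
  for (k in 1:8)
    expect_equal(ch_s[[k]]$propensity(st), ch_u[[k]]$propensity(st),
                 tolerance = 1e-5)
})

test_that("R-level channels agree with the simulator's C++ kernel", {
  set.seed(20)
  for (mode in resource_modes()) {
    for (rep in 1:5) {
      st <- c(M1 = rpois(1, 12), P1 = rpois(1, 150),
              M2 = rpois(1, 3), P2 = rpois(1, 50))
      ch <- build_propensities(default_params, mode)
      a_r <- vapply(ch, function(c_k) c_k$propensity(st), 0)
      a_cpp <- rcnoise:::.ssa_propensities(
        as.numeric(unclass(default_params)), rcnoise:::mode_code(mode),
        as.numeric(st), c(NA_real_, NA_real_))
      expect_equal(unname(a_cpp), unname(a_r), tolerance = 1e-12)
    }
  }
  # clamped variant
  clamp <- c(5.2, 0.8)
  st <- c(M1 = 10, P1 = 100, M2 = 2, P2 = 40)
  ch <- build_propensities(default_params, "shared", clamp = clamp)
  a_r <- vapply(ch, function(c_k) c_k$propensity(st), 0)
  a_cpp <- rcnoise:::.ssa_propensities(
    as.numeric(unclass(default_params)), 1L, as.numeric(st), clamp)
  expect_equal(unname(a_cpp), unname(a_r), tolerance = 1e-12)
})

test_that("identical seed and configuration reproduce the trajectory", {
  a <- gillespie_run(default_params, "shared", t_end = 50, seed = 31,
                     branch = "gfp_low")
  b <- gillespie_run(default_params, "shared", t_end = 50, seed = 31,
                     branch = "gfp_low")
  expect_identical(a$counts, b$counts)
  expect_identical(a$times, b$times)
})

test_that("every event changes exactly one species by one molecule", {
  tr <- gillespie_run(default_params, "unlimited", t_end = 5, seed = 8,
                      record_events = TRUE)
  steps <- diff(tr$counts)
  expect_true(all(rowSums(abs(steps)) == 1))
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$counts >= 0))
})

test_that("linear birth-death species is Poisson at stationarity", {
  # unlimited-mode M1 is a linear birth-death process with birth
  # Omega*(km01 + km1*I1) = 12.6 and death rate 1 -> Poisson(12.6), Fano 1
  tr <- gillespie_run(default_params, "unlimited", t_end = 3000, seed = 5)
  s <- stationary_summary(tr)
  m1 <- s[s$species == "M1", ]
  se_mean <- sqrt(m1$var / m1$n_eff)
  expect_lt(abs(m1$mean - 12.6), 3 * se_mean)
  fano <- m1$var / m1$mean
  expect_lt(abs(fano - 1), 3 * sqrt(2 / m1$n_eff))
  # protein mean matches the closed form x Omega
  p1 <- s[s$species == "P1", ]
  expect_lt(abs(p1$mean - 189), 3 * sqrt(p1$var / p1$n_eff))
})

test_that("ensemble means track the deterministic solution", {
  p <- update_params(default_params, I1 = 0.4)  # monostable shared regime
  det <- integrate_ode(p, "shared", c(0, 0, 0, 0), t_end = 15, dt = 0.005,
                       record_every = 200)
  reps <- 40
  acc <- 0
  for (r in seq_len(reps))
    acc <- acc + gillespie_run(p, "shared", t_end = 15, seed = 700 + r,
                               init = c(0, 0, 0, 0), dt = 1)$counts
  ens <- acc / reps
  # compare P1 at t = 5, 10, 15 against concentration x Omega
  for (tq in c(5, 10, 15)) {
    det_p1 <- det$p1[which.min(abs(det$t - tq))] * p$Omega
    got <- ens[round(tq) + 1, "P1"]
    se <- sqrt(det_p1 / reps) + 0.05 * det_p1 / sqrt(reps)
    expect_lt(abs(got - det_p1), 4 * se + 2)
  }
})

test_that("clamping at the stationary mean leaves monostable statistics
           unchanged", {
  p <- update_params(default_params, I1 = 0.3)
  un <- gillespie_run(p, "shared", t_end = 2000, seed = 77)
  cl <- clamped_mean_run(p, t_end = 2000, seed = 77)
  su <- stationary_summary(un); sc <- stationary_summary(cl)
  for (sp in c("P1", "P2")) {
    a <- su[su$species == sp, ]; b <- sc[sc$species == sp, ]
    se <- sqrt(a$var / a$n_eff + b$var / b$n_eff)
    expect_lt(abs(a$mean - b$mean), 4 * se)
  }
  expect_error(clamped_mean_run(default_params, t_end = 10, seed = 1),
               "branch")
  expect_error(gillespie_run(default_params, "unlimited", t_end = 10,
                             seed = 1, clamp = c(1, 1)), "shared")
})

test_that("dose sweep is a seed-scheduled stack of single runs", {
  p <- default_params
  sw <- dose_sweep(p, "shared", doses = 0.3, reps = 1, t_end = 30,
                   master_seed = 9)
  single <- gillespie_run(update_params(p, I1 = 0.3), "shared", t_end = 30,
                          seed = seed_schedule(9, 1)[1])
  expect_identical(sw$runs[[1]][[1]]$counts, single$counts)
  # dose-response shape: GFP mean rises, RFP mean falls across the sweep
  sw2 <- dose_sweep(p, "unlimited", doses = c(0.2, 0.6, 1.0), reps = 2,
                    t_end = 400, master_seed = 4, summarise = "stationary")
  nc <- noise_dose_curves(sw2)
  gfp <- nc$curves[nc$curves$species == "P1", "mean"]
  rfp <- nc$curves[nc$curves$species == "P2", "mean"]
  expect_true(all(diff(gfp) > 0))
  expect_true(all(diff(rfp) < 0))
  # unlimited means match closed form x Omega within a few percent
  for (k in 1:3) {
    st <- steady_state_closed_form(update_params(p, I1 = c(0.2, 0.6, 1)[k]),
                                   "unlimited")
    expect_equal(gfp[k], st[["p1"]] * p$Omega, tolerance = 0.05)
  }
})

test_that("trajectories export with a provenance sidecar", {
  tr <- gillespie_run(default_params, "unlimited", t_end = 5, seed = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  export_trajectory(tr, csv)
  df <- utils::read.csv(csv)
  expect_named(df, c("t", "M1", "P1", "M2", "P2"))
  side <- jsonlite::read_json(sub("\\.csv$", ".json", csv),
                              simplifyVector = TRUE)
  expect_equal(side$seed, 2)
  expect_equal(side$params$Kg, 17)
})
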