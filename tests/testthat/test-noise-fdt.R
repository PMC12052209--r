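test_that("susceptibilities match their analytic log-derivatives", {
  su <- susceptibilities(default_params, "unlimited")
  expect_equal(diag(su$H), rep(1, 4), tolerance = 1e-8)
  expect_equal(su$H[2, 1], -1, tolerance = 1e-8)   # |H21| = 1
  expect_equal(su$H[4, 3], -1, tolerance = 1e-8)
  # oracle: analytic log-derivative of the gene-2 transcription flux ratio
  p <- default_params
  p1 <- 126
  phi <- p$n * p1^p$n / (p1^p$n + p$Kg^p$n)
  R2 <- p$I2 * p$Kg^p$n / (p1^p$n + p$Kg^p$n)
  H32_want <- phi * p$km2 * R2 / (p$km02 + p$km2 * R2)
  expect_equal(su$H[3, 2], H32_want, tolerance = 1e-6)
  # orthogonal: diagonals still exactly 1, translation gain saturates
  so <- susceptibilities(default_params, "orthogonal")
  expect_equal(diag(so$H), rep(1, 4), tolerance = 1e-8)
  m1 <- so$means[["m1"]]
  expect_equal(so$H[2, 1], -1 / (1 + m1 / p$Jp1), tolerance = 1e-6)
  expect_error(susceptibilities(default_params, "unlimited",
                                means = c(0, 126, 1.06, 31.8)), "zero mean")
})

test_that("Lyapunov solve reproduces the known closed forms", {
  p <- default_params
  eta <- lyapunov_noise(p, "unlimited")
  M1 <- 8.4 * 1.5
  expect_equal(eta["M1", "M1"], 1 / M1, tolerance = 1e-12)
  # two-term GFP protein noise: 1/P1 + (1/M1) H21^2 (1/tau2)/(1/tau1+1/tau2)
  P1 <- 126 * 1.5
  want <- 1 / P1 + (1 / M1) * 1 * (1 / (1 + 1))
  expect_equal(eta["P1", "P1"], want, tolerance = 1e-10)
  expect_true(isSymmetric(unclass(eta)))
  expect_true(all(eigen(eta, only.values = TRUE)$values > -1e-12))
})

test_that("independent birth-death: diagonal drift gives 1/N and no
           correlations", {
  # all off-diagonal susceptibilities zero
  su <- list(H = diag(4), tau = c(1, 0.5, 2, 0.25),
             means_counts = c(M1 = 10, P1 = 200, M2 = 3, P2 = 60))
  A <- -su$H / su$tau
  D <- diag(2 / (su$tau * su$means_counts))
  K <- kronecker(diag(4), A) + kronecker(A, diag(4))
  eta <- matrix(solve(K, -as.vector(D)), 4, 4)
  expect_equal(diag(eta), 1 / su$means_counts, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_lt(max(abs(eta - diag(diag(eta)))), 1e-12)
})

test_that("decomposition components are positive and close the total", {
  for (mode in c("unlimited", "orthogonal")) {
    for (I1 in seq(0.05, 2, length.out = 20)) {
      p <- update_params(default_params, I1 = I1)
      dec <- decompose_noise(p, mode)
      eta <- lyapunov_noise(p, mode)
      expect_true(all(unlist(dec$components) >= 0))
      expect_equal(dec$totals[["m1"]], eta["M1", "M1"], tolerance = 1e-8)
      expect_equal(dec$totals[["p1"]], eta["P1", "P1"], tolerance = 1e-8)
      expect_equal(dec$totals[["m2"]], eta["M2", "M2"], tolerance = 1e-8)
      expect_equal(dec$totals[["p2"]], eta["P2", "P2"], tolerance = 1e-8)
      expect_equal(dec$components$m1[["m1<-m1"]],
                   1 / attr(eta, "means_counts")[["M1"]])
    }
  }
})

test_that("closure holds for asymmetric lifetimes (certifies the nested
           time-averaging factors)", {
  set.seed(14)
  for (k in 1:10) {
    p <- circuit_params(dm1 = runif(1, 0.2, 3), dp1 = runif(1, 0.2, 3),
                        dm2 = runif(1, 0.2, 3), dp2 = runif(1, 0.2, 3),
                        I1 = runif(1, 0.2, 2))
    for (mode in c("unlimited", "orthogonal")) {
      dec <- decompose_noise(p, mode)
      eta <- lyapunov_noise(p, mode)
      expect_equal(dec$totals[["p2"]], eta["P2", "P2"], tolerance = 1e-8)
      expect_equal(dec$totals[["m2"]], eta["M2", "M2"], tolerance = 1e-8)
    }
  }
})

test_that("dose dependence: GFP noise falls, RFP noise peaks inside the
           sweep", {
  doses <- seq(0.05, 2, length.out = 40)
  tab <- fdt_noise_curves(default_params, "unlimited", doses)
  gfp <- tab$eta2[tab$species == "p1" & tab$component == "total"]
  rfp <- tab$eta2[tab$species == "p2" & tab$component == "total"]
  expect_true(all(diff(gfp) < 0))
  i <- which.max(rfp)
  expect_gt(i, 1); expect_lt(i, length(rfp))
  expect_gt(max(rfp) / rfp[1], 1.5)
})

test_that("orthogonal pools suppress the noise propagated from GFP mRNA
           into RFP", {
  doses <- seq(0.2, 1.6, length.out = 15)
  prop_u <- prop_o <- numeric(length(doses))
  for (k in seq_along(doses)) {
    p <- update_params(default_params, I1 = doses[k])
    prop_u[k] <- decompose_noise(p, "unlimited")$
      components$p2[["p2<-m2<-p1<-m1"]]
    prop_o[k] <- decompose_noise(p, "orthogonal")$
      components$p2[["p2<-m2<-p1<-m1"]]
  }
  # suppression holds wherever the component matters (the peak region);
  # deep in the suppressed tail both are negligible and may cross over
  big <- prop_u > 0.01 * max(prop_u)
  expect_true(all(prop_o[big] < prop_u[big]))
  expect_lt(max(prop_o), 0.25 * max(prop_u))
})

test_that("long protein lifetimes time-average the mRNA noise away", {
  # the time-averaging factor is tau1/(tau1 + tau2): a long-lived protein
  # (tau2 >> tau1, i.e. small dp1) filters mRNA fluctuations to nothing,
  # while a fast protein (tau2 -> 0) tracks them fully
  vals <- vapply(c(1, 0.1, 0.01, 0.001), function(dp1) {
    p <- circuit_params(dp1 = dp1)
    decompose_noise(p, "unlimited")$components$p1[["p1<-m1"]]
  }, 0)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[4] / vals[1], 0.01)
  fast <- decompose_noise(circuit_params(dp1 = 1000),
                          "unlimited")$components$p1[["p1<-m1"]]
  M1 <- 8.4 * 1.5
  expect_equal(fast, 1 / M1, tolerance = 1e-2)  # factor -> 1, full tracking
})

test_that("stationary SSA noise matches the FDT analytics (unlimited)", {
  # average 4 independent long runs so the MC standard error (~1%) sits
  # well inside the 5% agreement surface
  eta <- lyapunov_noise(default_params, "unlimited")
  acc <- matrix(0, 4, 4, dimnames = list(NULL, c("M1", "P1", "M2", "P2")))
  for (r in 1:4) {
    s <- stationary_summary(gillespie_run(default_params, "unlimited",
                                          t_end = 5000, seed = 200 + r))
    acc[r, ] <- s$eta2[match(colnames(acc), s$species)]
  }
  for (sp in colnames(acc)) {
    got <- mean(acc[, sp])
    expect_lt(abs(got - eta[sp, sp]) / eta[sp, sp], 0.05)
  }
})

test_that("shared-mode analytics are flagged as an approximation", {
  p <- update_params(default_params, I1 = 0.3)
  expect_warning(lyapunov_noise(p, "shared"), "approximation")
  expect_error(suppressWarnings(lyapunov_noise(default_params, "shared")),
               "monostable")
})
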