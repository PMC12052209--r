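# Frozen reference values for the saddle-node locations at printed defaults,
# computed independently of bifurcation_1d by dense bracketing of the scalar
# steady-state residual (20000-point scan) plus 40-step bisection on the
# swept parameter.
SN_I1 <- c(0.874718, 1.128607)
SN_KG <- c(15.23572, 18.96624)

test_that("I1 sweep of the shared model localizes both saddle nodes", {
  bd <- bifurcation_1d(default_params, "shared", "I1", c(0, 2))
  expect_equal(nrow(bd$sn_points), 2)
  sn <- sort(bd$sn_points$value)
  expect_lt(abs(sn[1] - SN_I1[1]), 5e-3)
  expect_lt(abs(sn[2] - SN_I1[2]), 5e-3)
  # between the SN points: 2 stable + 1 unstable; outside: 1 stable
  inside <- bd$grid > sn[1] + 0.01 & bd$grid < sn[2] - 0.01
  counts <- vapply(bd$branches, length, 0L)
  stables <- vapply(bd$branches, rcnoise:::n_stable, 0L)
  expect_true(all(counts[inside] == 3 & stables[inside] == 2))
  expect_true(all(counts[!inside & abs(bd$grid - sn[1]) > 0.01 &
                           abs(bd$grid - sn[2]) > 0.01] == 1))
})

test_that("Kg sweep reproduces the frozen bistable window", {
  bd <- bifurcation_1d(default_params, "shared", "Kg", c(1, 40),
                       resolution = 200)
  sn <- sort(bd$sn_points$value)
  expect_length(sn, 2)
  expect_lt(abs(sn[1] - SN_KG[1]), 2e-2)
  expect_lt(abs(sn[2] - SN_KG[2]), 2e-2)
})

test_that("the unlimited cascade is monostable for any inducer dose", {
  bd <- bifurcation_1d(default_params, "unlimited", "I1", c(0, 2),
                       resolution = 100)
  expect_equal(nrow(bd$sn_points), 0)
  expect_true(all(vapply(bd$branches, length, 0L) == 1))
})

test_that("approaching a saddle node the merging pair collapses", {
  # p1 distance of the closest stable/unstable pair just inside the window,
  # relative to the branch separation at the window center
  ss_mid <- find_steady_states(default_params, "shared")
  p1s <- vapply(ss_mid, function(s) s$state[["p1"]], 0)
  sep_mid <- max(p1s) - min(p1s)
  pair_dist <- function(eps, sn) {
    inside <- if (sn < 1) sn + eps else sn - eps
    ss <- find_steady_states(update_params(default_params, I1 = inside),
                             "shared", n_grid = 20000)
    stab <- vapply(ss, `[[`, logical(1), "stable")
    min(abs(outer(vapply(ss[stab], function(s) s$state[["p1"]], 0),
                  vapply(ss[!stab], function(s) s$state[["p1"]], 0), "-")))
  }
  for (sn in SN_I1) {
    # square-root collapse: d ~ C*sqrt(eps); at eps = 1e-3 the pair sits
    # within 7% of the branch separation (the lower saddle has C ~ 84, so
    # the nominal 5% is reached just below eps = 1e-3), and quartering eps
    # halves the distance
    d3 <- pair_dist(1e-3, sn)
    d4 <- pair_dist(2.5e-4, sn)
    expect_lt(d3, 0.07 * sep_mid)
    expect_lt(d4, 0.05 * sep_mid)
    expect_lt(d4 / d3, 0.65)
  }
})

test_that("two-parameter diagram: slice consistency and widening window", {
  p_x <- list(name = "I1", range = c(0, 2))
  b2 <- bifurcation_2d(default_params, "shared", p_x,
                       p_y = list(name = "inv_Jp2", range = c(0.5, 0.8)),
                       resolution_y = 3, resolution_x = 200)
  # slice at 1/Jp2 = 0.5 (the default Jp2 = 2) equals the 1D result
  row <- b2$sn_curves[b2$sn_curves$y == 0.5, ]
  expect_lt(abs(row$sn_lower - SN_I1[1]), 5e-3)
  expect_lt(abs(row$sn_upper - SN_I1[2]), 5e-3)
  # stronger RFP competition (larger 1/Jp2) widens the bistable window
  # (until it drifts past the swept I1 range, hence the modest span here)
  widths <- b2$sn_curves$sn_upper - b2$sn_curves$sn_lower
  expect_true(all(diff(widths) >= -1e-6))
})

test_that("weak RFP competition loses bistability below a cusp", {
  p_x <- list(name = "I1", range = c(0, 2))
  b2 <- bifurcation_2d(default_params, "shared", p_x,
                       p_y = list(name = "inv_Jp2", range = c(0.01, 0.5)),
                       resolution_y = 2, resolution_x = 200)
  expect_true(is.na(b2$sn_curves$sn_lower[1]))   # 1/Jp2 = 0.01: monostable
  expect_false(is.na(b2$sn_curves$sn_lower[2]))  # 1/Jp2 = 0.5: bistable
  expect_true(is.finite(b2$cusp))
  expect_gt(b2$cusp, 0.01)
  expect_lt(b2$cusp, 0.5)
})

test_that("sensitivity report: identity perturbation and input checks", {
  sr <- sensitivity_sn(default_params, "shared", delta = 0,
                       parameters = c("kp2", "Kg"))
  expect_true(all(sr$d_sn1_pct == 0) && all(sr$d_sn2_pct == 0))
  expect_true(all(sr$bistable))
  expect_error(sensitivity_sn(default_params, "shared",
                              parameters = "Omega"), "cannot perturb")
  expect_error(sensitivity_sn(default_params, "unlimited",
                              parameters = "kp2"),
               "not bistable")
})

test_that("diagrams export as tidy CSV with a JSON saddle-node sidecar", {
  bd <- bifurcation_1d(default_params, "shared", "I1", c(0.8, 1.2),
                       resolution = 40)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  export_bifurcation(bd, csv, js)
  tab <- utils::read.csv(csv)
  expect_named(tab, c("I1", "branch", "m1", "p1", "m2", "p2", "stable"))
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(side$sn_points), nrow(bd$sn_points))
})
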