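test_that("blood:plasma partitioning follows saturable red-cell binding", {
  d <- compound_disposition(bp_max = 35, c50 = 5)
  expect_equal(blood_to_plasma(0, d), 35)                 # low-conc limit
  expect_equal(blood_to_plasma(5, d), 1 + 34 / 2)         # half saturation
  expect_equal(blood_to_plasma(1e9, d), 1, tolerance = 1e-6)
  d1 <- compound_disposition(bp_max = 1)
  expect_equal(blood_to_plasma(c(0, 1, 100), d1), rep(1, 3))
  # decreasing and bounded
  cp <- seq(0, 100, by = 1)
  bp <- blood_to_plasma(cp, d)
  expect_true(all(diff(bp) < 0))
  expect_true(all(bp >= 1 & bp <= 35))
  expect_error(blood_to_plasma(-1, d), ">= 0")
})

test_that("an IV impulse matches the closed-form two-compartment solution", {
  skip_if_not_installed("Matrix")
  d <- compound_disposition(bp_max = 1)   # linear output for the oracle
  tg <- seq(0, 96, by = 0.5)
  pk <- simulate_pk(function(t) 0, d, t_grid = tg, iv_bolus = 2)
  clh <- hepatic_clearance(d)
  k10 <- clh / d$vc; k12 <- d$q_dist / d$vc; k21 <- d$q_dist / d$vp
  M <- matrix(c(-(k10 + k12), k21, k12, -k21), 2, 2, byrow = TRUE)
  oracle <- vapply(tg, function(t)
    (Matrix::expm(M * t) %*% c(2, 0))[1], 0) / d$vc * 1000
  rel <- abs(pk$conc_blood[-1] - oracle[-1]) / oracle[-1]
  expect_lt(max(rel), 1e-3)
})

test_that("disposition is linear: zero input and dose proportionality", {
  d <- compound_disposition(bp_max = 1)
  tg <- seq(0, 48, by = 0.5)
  z <- simulate_pk(function(t) 0, d, t_grid = tg)
  expect_true(all(z$conc_blood == 0))
  a <- simulate_pk(function(t) ifelse(t < 2, 1, 0), d, t_grid = tg)
  b <- simulate_pk(function(t) ifelse(t < 2, 2, 0), d, t_grid = tg)
  expect_equal(b$conc_blood[-1], 2 * a$conc_blood[-1], tolerance = 1e-6)
})

test_that("whole-blood output equals plasma times the partition ratio", {
  fx <- default_fixture()
  reg <- fx$regions
  reg$dlm_scalar <- recovery_region_scalars()
  run <- simulate_oral_pk(fx$form, reg, fx$disp, mode = "dlm",
                          t_grid = coarse_grid)
  expect_equal(run$pk$conc_blood,
               run$pk$conc_plasma * blood_to_plasma(run$pk$conc_plasma, fx$disp))
})

test_that("AUC decreases monotonically with intrinsic clearance", {
  fx <- default_fixture()
  reg <- fx$regions
  reg$dlm_scalar <- recovery_region_scalars()
  aucs <- vapply(c(5000, 20000, 80000), function(cl) {
    d <- fx$disp; d$clint_3a4 <- cl
    run <- simulate_oral_pk(fx$form, reg, d, mode = "dlm", t_grid = coarse_grid)
    compute_metrics(run$pk)$auc_0_144
  }, 0)
  expect_true(all(diff(aucs) < 0))
})

test_that("full-system mass balance holds in both input modes", {
  fx <- default_fixture()
  reg <- fx$regions
  reg$dlm_scalar <- recovery_region_scalars()
  a <- simulate_oral_pk(fx$form, reg, fx$disp, mode = "dlm",
                        t_grid = coarse_grid)
  expect_lt(max(abs(a$mass_balance)), 1e-6)
  b <- simulate_oral_pk(fx$form, reg, fx$disp, mode = "profile",
                        profile = profile_preset("advagraf"),
                        t_grid = coarse_grid)
  expect_lt(max(abs(b$mass_balance)), 1e-6)
})

test_that("population simulation is reproducible and degenerates correctly", {
  fx <- default_fixture()
  reg <- fx$regions
  reg$dlm_scalar <- recovery_region_scalars()
  tg <- seq(0, 144, by = 1)
  p1 <- simulate_population(fx$form, reg, fx$disp, n = 3, seed = 9, t_grid = tg)
  p2 <- simulate_population(fx$form, reg, fx$disp, n = 3, seed = 9, t_grid = tg)
  expect_identical(p1$subjects, p2$subjects)

  p0 <- simulate_population(fx$form, reg, fx$disp, n = 3, seed = 9, t_grid = tg,
                            cv = c(clint = 0, vc = 0, peff = 0))
  for (s in p0$subjects)
    expect_equal(s$conc_blood, p0$mean$conc_blood, tolerance = 1e-10)
  expect_error(simulate_population(fx$form, reg, fx$disp, n = 2,
                                   cv = c(bogus = 0.1)), "bogus")
})
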