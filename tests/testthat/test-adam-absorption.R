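test_that("GI state is conserved and responds to limiting cases", {
  fx <- default_fixture()
  reg <- fx$regions
  reg$dlm_scalar <- recovery_region_scalars()

  # zero permeability: nothing absorbed, everything eventually fecal
  d0 <- fx$disp
  d0$peff <- 1e-12
  run <- simulate_gi_dlm(fx$form, reg, d0, t_grid = seq(0, 400, by = 1))
  tr <- utils::tail(run$trajectory, 1)
  expect_lt(tr$absorbed, 1e-6)
  expect_gt(tr$fecal_solid + tr$fecal_dissolved, 0.999 * fx$form$dose)

  # instant dissolution, high permeability, no gut metabolism: portal ~ dose
  d1 <- fx$disp
  d1$peff <- 50
  d1$kgut_3a4 <- 0
  reg_fast <- reg
  reg_fast$dlm_scalar <- rep(1e5, 9)
  run1 <- simulate_gi_dlm(fx$form, reg_fast, d1, t_grid = seq(0, 72, by = 0.1))
  expect_gt(utils::tail(run1$trajectory$absorbed, 1), 0.99 * fx$form$dose)
})

test_that("GI mass balance holds at every output time", {
  fx <- default_fixture()
  reg <- fx$regions
  reg$dlm_scalar <- recovery_region_scalars()
  run <- simulate_gi_dlm(fx$form, reg, fx$disp, t_grid = seq(0, 48, by = 0.1))
  tr <- run$trajectory
  pools <- rowSums(tr[, grep("^(solid|dissolved|enterocyte)\\.", names(tr))])
  total <- pools + tr$absorbed + tr$gut_metabolised + tr$fecal_solid +
    tr$fecal_dissolved
  expect_lt(max(abs(total - fx$form$dose) / fx$form$dose), 1e-6)
})

test_that("release never decreases when a regional scalar is raised", {
  fx <- default_fixture()
  base <- recovery_region_scalars()
  released <- function(scalars) {
    reg <- fx$regions
    reg$dlm_scalar <- scalars
    run <- simulate_gi_dlm(fx$form, reg, fx$disp, t_grid = seq(0, 30, by = 0.1))
    tr <- utils::tail(run$trajectory, 1)
    fx$form$dose - sum(tr[, grep("^solid\\.", names(tr))]) - tr$fecal_solid
  }
  r0 <- released(base)
  for (region in c("Duodenum", "Ileum II", "Colon")) {
    up <- base
    up[region] <- up[region] * 5
    expect_gte(released(up), r0 - 1e-9)
  }
})

test_that("the release hazard reproduces the in vitro curve in vivo", {
  fx <- default_fixture()
  reg <- fx$regions
  reg$transit_rate[9] <- 1 / 1000   # keep solid in the GI over the window
  slow <- profile_preset("advagraf")
  run <- simulate_gi_profile(slow, reg, fx$disp, t_grid = seq(0, 6, by = 0.05))
  tr <- utils::tail(run$trajectory, 1)
  unreleased <- sum(tr[, grep("^solid\\.", names(tr))]) + tr$fecal_solid
  released_pct <- (1 - unreleased / 5) * 100
  expect_equal(released_pct, utils::tail(slow$cum_pct, 1), tolerance = 1e-3)
})

test_that("a null profile releases nothing and a complete one is capped", {
  fx <- default_fixture()
  null_prof <- dissolution_profile(c(0, 180, 360), c(0, 0, 0))
  run <- simulate_gi_profile(null_prof, fx$regions, fx$disp,
                             t_grid = seq(0, 200, by = 1))
  tr <- utils::tail(run$trajectory, 1)
  expect_lt(tr$absorbed, 1e-9)
  expect_gt(tr$fecal_solid, 0.999 * 5)

  # d = 1 from the start: hazard capped at lambda_max, release ~ immediate
  step <- dissolution_profile(c(0, 5, 360), c(100, 100, 100))
  hz <- release_hazard(step, lambda_max = 50)
  expect_equal(hz(c(0, 1, 3, 10)), rep(50, 4))
})

test_that("hazard is held at its final value beyond the profile end", {
  prof <- dissolution_profile(c(0, 60, 120), c(0, 20, 40))
  hz <- release_hazard(prof)
  expect_equal(hz(10), hz(1.9))   # beyond 2 h end
  expect_gt(hz(10), 0)
})

test_that("unresolved scalar sentinels are rejected with region names", {
  fx <- default_fixture()
  reg <- fx$regions
  reg$dlm_scalar <- c(rep(0.1, 8), NA)
  expect_error(simulate_gi_dlm(fx$form, reg, fx$disp), "Colon")
})
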