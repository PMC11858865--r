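recovery_setup <- function() {
  fx <- default_fixture()
  reg <- fx$regions
  reg$dlm_scalar <- recovery_region_scalars()
  reg$dlm_scalar[5:9] <- NA   # ileal and colonic scalars unresolved
  list(fx = fx, reg = reg)
}

test_that("a single-point grid equals a direct simulation", {
  s <- recovery_setup()
  tab <- scan_scalars(s$fx$form, s$reg, s$fx$disp, ileum_grid = 0.05,
                      colon_grid = 0.5, reference = c(ileum = 0.05, colon = 0.5),
                      n = 1, t_grid = coarse_grid)
  reg2 <- s$reg
  reg2$dlm_scalar[5:8] <- 0.05
  reg2$dlm_scalar[9] <- 0.5
  direct <- compute_metrics(simulate_oral_pk(s$fx$form, reg2, s$fx$disp,
                                             mode = "dlm",
                                             t_grid = coarse_grid)$pk)
  expect_equal(tab$auc_0_144[1], direct$auc_0_144, tolerance = 1e-10)
  expect_equal(tab$cmax[1], direct$cmax, tolerance = 1e-10)
  expect_equal(tab$tmax[1], direct$tmax)
})

test_that("the default layout mirrors the one-at-a-time grid", {
  s <- recovery_setup()
  tab <- scan_scalars(s$fx$form, s$reg, s$fx$disp, n = 1, t_grid = coarse_grid)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$ileum_scalar[1:3], c(0.005, 0.05, 0.5))
  expect_equal(tab$colon_scalar[1:3], rep(0.5, 3))
  expect_equal(tab$ileum_scalar[4:6], rep(0.05, 3))
  expect_equal(tab$colon_scalar[4:6], c(0.05, 0.5, 5))
})

test_that("scans are deterministic under a fixed seed", {
  s <- recovery_setup()
  obs <- list(sample_times = c(0, 1, 2, 4, 8, 24, 72, 144), residual_cv = 0.1)
  t1 <- scan_scalars(s$fx$form, s$reg, s$fx$disp, ileum_grid = c(0.05),
                     colon_grid = 0.5, n = 4, seed = 21, observe = obs,
                     t_grid = coarse_grid)
  t2 <- scan_scalars(s$fx$form, s$reg, s$fx$disp, ileum_grid = c(0.05),
                     colon_grid = 0.5, n = 4, seed = 21, observe = obs,
                     t_grid = coarse_grid)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("selection minimises the worst fold error, smaller scalars on ties", {
  tab <- structure(
    data.frame(ileum_scalar = c(0.005, 0.05, 0.5),
               colon_scalar = rep(0.5, 3),
               auc_0_144 = c(300, 400, 520),
               cmax = c(20, 30, 45),
               tmax = c(4, 3, 2)),
    class = c("sensitivity_table", "data.frame"))
  obs <- c(auc_0_144 = 405, cmax = 29, tmax = 3.1)
  sel <- select_scalars(tab, obs)
  expect_equal(sel$ileum, 0.05)
  expect_equal(sel$colon, 0.5)
  expect_true(all(c("fe_auc", "fe_cmax", "fe_tmax", "fe_max") %in%
                    names(sel$table)))

  # identical rows: the smallest pair wins
  tie <- tab
  tie$auc_0_144 <- 400; tie$cmax <- 30; tie$tmax <- 3
  sel2 <- select_scalars(tie, obs)
  expect_equal(sel2$ileum, 0.005)

  # a dominating row is always chosen
  dom <- tab
  dom$auc_0_144 <- c(405, 800, 900)
  dom$cmax <- c(29, 70, 80)
  dom$tmax <- c(3.1, 6, 7)
  expect_equal(select_scalars(dom, obs)$ileum, 0.005)
})

test_that("a summarize_study data.frame is accepted as the observed side", {
  tab <- structure(
    data.frame(ileum_scalar = 0.05, colon_scalar = 0.5,
               auc_0_144 = 400, cmax = 30, tmax = 3),
    class = c("sensitivity_table", "data.frame"))
  obs_df <- data.frame(metric = c("auc_0_144", "cmax", "tmax"),
                       mean = c(410, 31, 3), sd = c(1, 1, 1))
  sel <- select_scalars(tab, obs_df)
  expect_equal(sel$max_fold_error, 31 / 30, tolerance = 1e-12)
  expect_error(select_scalars(tab, c(auc_0_144 = 1)), "cmax")
})
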