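#' Compound disposition parameters (minimal PBPK)
#'
#' Two-compartment disposition with well-stirred hepatic extraction of the
#' portal inflow (first pass) and systemic hepatic clearance, plus
#' concentration-dependent whole-blood to plasma partitioning from saturable
#' red-cell binding.  The shipped defaults describe an illustrative
#' tacrolimus-like compound (very low plasma unbound fraction, extensive
#' red-cell partitioning, high-extraction CYP3A clearance, large peripheral
#' distribution); every value is configurable and none of the package's
#' self-consistency checks depends on them.
#'
#' @param vc Central (plasma-referenced) volume (L).
#' @param vp Peripheral volume (L).
#' @param q_dist Inter-compartment distribution clearance (L/h).
#' @param clint_3a4,clint_3a5 Unbound intrinsic metabolic clearances (L/h);
#'   the CYP3A5 pathway defaults to 0 (non-expressor).
#' @param fu_plasma Unbound fraction in plasma, in (0, 1].
#' @param q_h Hepatic blood flow (L/h).
#' @param peff Effective jejunal permeability (1e-4 cm/s units).
#' @param bp_max Blood:plasma ratio at vanishing concentration (>= 1 - Hct).
#' @param c50 Plasma concentration (ng/mL) at which red-cell binding is half
#'   saturated.
#' @param k_villi First-order enterocyte-to-portal transfer rate (1/h).
#' @param kgut_3a4,kgut_3a5 First-order enterocyte metabolic rate constants
#'   (1/h at unit regional CYP3A abundance).
#' @return Object of class `compound_disposition`.
#' @export
compound_disposition <- function(vc = 140, vp = 1500, q_dist = 50,
                                 clint_3a4 = 20000, clint_3a5 = 0,
                                 fu_plasma = 0.01, q_h = 90,
                                 peff = 1.2, bp_max = 35, c50 = 5,
                                 k_villi = 4, kgut_3a4 = 4, kgut_3a5 = 0) {
  stopifnot(vc > 0, vp > 0, q_dist > 0, q_h > 0,
            clint_3a4 >= 0, clint_3a5 >= 0,
            fu_plasma > 0, fu_plasma <= 1,
            peff > 0, c50 > 0, k_villi > 0, kgut_3a4 >= 0, kgut_3a5 >= 0)
  hct <- 0.45
  if (bp_max < 1 - hct) stop("bp_max must be >= 1 - hematocrit (0.55)")
  structure(list(vc = vc, vp = vp, q_dist = q_dist,
                 clint_3a4 = clint_3a4, clint_3a5 = clint_3a5,
                 fu_plasma = fu_plasma, q_h = q_h, peff = peff,
                 bp_max = bp_max, c50 = c50, k_villi = k_villi,
                 kgut_3a4 = kgut_3a4, kgut_3a5 = kgut_3a5),
            class = "compound_disposition")
}

#' Whole-blood to plasma partition ratio
#'
#' Saturable single-site red-cell binding:
#' `B:P(Cp) = 1 + (bp_max - 1) / (1 + Cp / c50)` -- decreasing in plasma
#' concentration, continuous, bounded in `[1, bp_max]`.
#'
#' @param cp Plasma concentration (ng/mL), >= 0 (vectorised).
#' @param disp A [compound_disposition()] or any list with `bp_max`, `c50`.
#' @return Dimensionless blood:plasma ratio.
#' @export
blood_to_plasma <- function(cp, disp) {
  if (any(!is.finite(cp)) || any(cp < 0)) stop("plasma concentration must be >= 0")
  1 + (disp$bp_max - 1) / (1 + cp / disp$c50)
}

hepatic_extraction <- function(disp) {
  clu <- disp$fu_plasma * (disp$clint_3a4 + disp$clint_3a5)
  clu / (disp$q_h + clu)
}

#' Hepatic plasma clearance under the well-stirred model (L/h)
#' @param disp A [compound_disposition()].
#' @export
hepatic_clearance <- function(disp) disp$q_h * hepatic_extraction(disp)

pk_rhs_factory <- function(disp, input_fun) {
  eh <- hepatic_extraction(disp)
  clh <- disp$q_h * eh
  k10 <- clh / disp$vc
  k12 <- disp$q_dist / disp$vc
  k21 <- disp$q_dist / disp$vp
  function(t, y, parms) {
    inp <- input_fun(t)
    dAc <- (1 - eh) * inp - k10 * y[1] - k12 * y[1] + k21 * y[2]
    dAp <- k12 * y[1] - k21 * y[2]
    list(c(dAc, dAp, eh * inp, k10 * y[1]))
  }
}

amount_to_blood_conc <- function(ac_mg, disp) {
  cp <- ac_mg / disp$vc * 1000   # mg/L -> ng/mL
  cp * blood_to_plasma(cp, disp)
}

#' Simulate systemic disposition from a portal input rate
#'
#' Integrates central/peripheral plasma amounts with well-stirred hepatic
#' extraction of the portal inflow (first pass) and systemic hepatic
#' clearance, then maps plasma to whole-blood concentration through
#' [blood_to_plasma()], since whole-blood concentrations are what the
#' clinical assay reports for this compound.
#'
#' @param portal_input Function of time (h) returning portal inflow (mg/h),
#'   nonnegative; e.g. the `portal_rate` element of [simulate_gi_dlm()].
#' @param disp A [compound_disposition()].
#' @param t_grid Output times (h).
#' @param iv_bolus Optional amount (mg) placed in the central compartment at
#'   time 0 (used for impulse-response checks).
#' @param rtol,atol Solver tolerances.
#' @return Object of class `pk_profile`: data.frame with `time_h`,
#'   `conc_blood` (ng/mL), `conc_plasma` (ng/mL) and attribute `subject_id`.
#' @export
simulate_pk <- function(portal_input, disp, t_grid = seq(0, 144, by = 0.25),
                        iv_bolus = 0, rtol = 1e-10, atol = 1e-12) {
  rhs <- pk_rhs_factory(disp, portal_input)
  sol <- deSolve::lsoda(c(iv_bolus, 0, 0, 0), t_grid, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  cp <- sol[, 2] / disp$vc * 1000
  pk_profile(t_grid, cp * blood_to_plasma(cp, disp), conc_plasma = cp)
}

#' Whole-blood concentration-time profile
#'
#' @param time_h Times (h), increasing.
#' @param conc_blood Whole-blood concentrations (ng/mL), >= 0.
#' @param conc_plasma Optional matching plasma concentrations (ng/mL).
#' @param subject_id Subject identifier or `"mean"`.
#' @return Object of class `pk_profile` (a data.frame).
#' @export
pk_profile <- function(time_h, conc_blood, conc_plasma = NULL,
                       subject_id = "mean") {
  df <- data.frame(time_h = time_h, conc_blood = conc_blood)
  if (!is.null(conc_plasma)) df$conc_plasma <- conc_plasma
  structure(df, class = c("pk_profile", "data.frame"), subject_id = subject_id)
}

#' Simulate an oral dose end to end (GI + disposition, one ODE system)
#'
#' Couples the nine-compartment GI model to the two-compartment disposition
#' model in a single stiff ODE system so that mass balance holds to solver
#' tolerance across the whole dose: at every time,
#' GI pools + body amounts + gut-metabolised + fecal + first-pass and
#' systemic hepatic elimination add up to the dose.
#'
#' @param form A [formulation] (used in `dlm` mode; supplies the dose in
#'   both modes when `profile` lacks one).
#' @param regions [gi_regions()] table; in `dlm` mode all scalars resolved.
#' @param disp A [compound_disposition()].
#' @param mode `"dlm"` for mechanistic regional dissolution or `"profile"`
#'   for direct in vitro profile input.
#' @param profile A [dissolution_profile] (required in `profile` mode).
#' @param t_grid Output times (h).
#' @param lambda_max Hazard cap for profile mode (1/h).
#' @param rtol,atol Solver tolerances.
#' @return List with `pk` (a `pk_profile`), `trajectory` (GI + systemic
#'   pools and cumulative elimination routes) and `mass_balance` (relative
#'   error of total accounted mass vs dose at each output time).
#' @export
simulate_oral_pk <- function(form, regions, disp, mode = c("dlm", "profile"),
                             profile = NULL, t_grid = seq(0, 144, by = 0.25),
                             lambda_max = 50, rtol = 1e-8, atol = 1e-10) {
  mode <- match.arg(mode)
  if (mode == "profile") {
    if (is.null(profile)) stop("profile mode requires a dissolution profile")
    hz <- release_hazard(profile, lambda_max = lambda_max)
    gi_rhs <- gi_rhs_factory(form, regions, disp, mode = "profile",
                             hazard_fun = hz)
  } else {
    gi_rhs <- gi_rhs_factory(form, regions, disp, mode = "dlm")
  }
  eh <- hepatic_extraction(disp)
  clh <- disp$q_h * eh
  k10 <- clh / disp$vc
  k12 <- disp$q_dist / disp$vc
  k21 <- disp$q_dist / disp$vp
  rhs <- function(t, y, parms) {
    gi <- gi_rhs(t, y[1:31], parms)
    portal <- gi$portal
    ac <- y[32]; ap <- y[33]
    dAc <- (1 - eh) * portal - k10 * ac - k12 * ac + k21 * ap
    dAp <- k12 * ac - k21 * ap
    list(c(gi[[1]], dAc, dAp, eh * portal, k10 * ac))
  }
  y0 <- c(form$dose, rep(0, 34))
  sol <- deSolve::lsoda(y0, t_grid, rhs, parms = NULL, rtol = rtol, atol = atol)
  gi_traj <- gi_traj_frame(sol[, 1:32])
  gi_traj$portal_rate <- NULL
  sys <- as.data.frame(sol[, 33:36])
  names(sys) <- c("central", "peripheral", "first_pass_eliminated",
                  "systemic_eliminated")
  traj <- cbind(gi_traj, sys)
  accounted <- rowSums(traj[, c(paste0("solid.", gi_region_names()),
                                paste0("dissolved.", gi_region_names()),
                                paste0("enterocyte.", gi_region_names()),
                                "gut_metabolised", "fecal_solid",
                                "fecal_dissolved", "central",
                                "peripheral", "first_pass_eliminated",
                                "systemic_eliminated")])
  mb <- (accounted - form$dose) / form$dose
  cp <- sys$central / disp$vc * 1000
  pk <- pk_profile(traj$time_h, cp * blood_to_plasma(cp, disp), conc_plasma = cp)
  list(pk = pk, trajectory = traj, mass_balance = mb)
}

#' Simulate a virtual population of subjects
#'
#' Per-subject parameters are drawn log-normally around the reference
#' [compound_disposition()] with the supplied coefficients of variation
#' (median-preserving: multiplier `exp(sigma * Z)` with
#' `sigma = sqrt(log(1 + CV^2))`), reproducibly for a given seed.  Each
#' subject is simulated with [simulate_oral_pk()] and the whole-blood curves
#' are summarised pointwise.
#'
#' @inheritParams simulate_oral_pk
#' @param n Number of subjects (>= 1).
#' @param cv Named numeric vector of CVs (proportions) over any of
#'   `clint`, `vc`, `vp`, `q_dist`, `peff`; defaults
#'   `c(clint = 0.3, vc = 0.25, peff = 0.3)`.
#' @param seed Integer seed.
#' @return List with `subjects` (list of `pk_profile`), `mean`, `p5`, `p95`
#'   (pk_profiles of the pointwise mean and percentiles) and `params`
#'   (data.frame of per-subject multipliers).
#' @export
simulate_population <- function(form, regions, disp, n = 12,
                                cv = c(clint = 0.3, vc = 0.25, peff = 0.3),
                                seed = 1, mode = c("dlm", "profile"),
                                profile = NULL,
                                t_grid = seq(0, 144, by = 0.25),
                                rtol = 1e-8, atol = 1e-10) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, all(cv >= 0))
  allowed <- c("clint", "vc", "vp", "q_dist", "peff")
  bad <- setdiff(names(cv), allowed)
  if (length(bad)) stop("unknown CV parameter(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  sig <- sqrt(log(1 + cv^2))
  mult <- matrix(1, nrow = n, ncol = length(allowed),
                 dimnames = list(NULL, allowed))
  for (p in names(cv))
    mult[, p] <- exp(sig[[p]] * stats::rnorm(n))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    d <- disp
    d$clint_3a4 <- disp$clint_3a4 * mult[i, "clint"]
    d$clint_3a5 <- disp$clint_3a5 * mult[i, "clint"]
    d$vc <- disp$vc * mult[i, "vc"]
    d$vp <- disp$vp * mult[i, "vp"]
    d$q_dist <- disp$q_dist * mult[i, "q_dist"]
    d$peff <- disp$peff * mult[i, "peff"]
    run <- simulate_oral_pk(form, regions, d, mode = mode, profile = profile,
                            t_grid = t_grid, rtol = rtol, atol = atol)
    p <- run$pk
    attr(p, "subject_id") <- sprintf("S%02d", i)
    subjects[[i]] <- p
  }
  conc <- vapply(subjects, function(p) p$conc_blood, numeric(length(t_grid)))
  conc <- matrix(conc, nrow = length(t_grid))
  list(subjects = subjects,
       mean = pk_profile(t_grid, rowMeans(conc)),
       p5 = pk_profile(t_grid, apply(conc, 1, stats::quantile, 0.05),
                       subject_id = "p5"),
       p95 = pk_profile(t_grid, apply(conc, 1, stats::quantile, 0.95),
                        subject_id = "p95"),
       params = as.data.frame(mult))
}
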