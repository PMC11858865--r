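#' Default nine-compartment GI physiology
#'
#' Fasted-state defaults: gastric mean residence 0.25 h; total small-bowel
#' residence 3.32 h apportioned across the seven small-intestinal segments
#' in proportion to the in vitro residence of the corresponding dissolution
#' media (40 min proximal, 80 min midgut split over the two jejunal
#' segments, 60 min distal split over the four ileal segments); colonic mean
#' residence 12 h.  Fluid volumes and radii are standard fasted values.
#' CYP3A abundance is relative to the duodenum and declines distally;
#' colonic permeability is scaled by `colon_perm_scale` relative to the
#' small intestine.  Regional solubility is inherited from the matching
#' biorelevant medium through the protocol's region map.
#'
#' @param protocol A `dissolution_protocol` supplying media solubilities and
#'   the medium-to-region map.
#' @param dlm_scalars Optional named numeric vector of per-region
#'   dissolution scalars (9 regions); NA marks unresolved regions.
#' @param colon_perm_scale Colon permeability relative to small intestine.
#' @return `data.frame` with one row per region: name, transit_rate (1/h),
#'   fluid_volume (mL), radius (cm), solubility (mg/mL), dlm_scalar,
#'   cyp3a_abundance, perm_scale.
#' @export
gi_regions <- function(protocol = build_default_protocol(),
                       dlm_scalars = NULL, colon_perm_scale = 0.1) {
  nm <- gi_region_names()
  si_total <- 3.32
  mrt <- c(0.25,
           si_total * 40 / 180,
           si_total * 40 / 180, si_total * 40 / 180,
           rep(si_total * 15 / 180, 4),
           12)
  reg <- data.frame(
    name = nm,
    transit_rate = 1 / mrt,
    fluid_volume = c(50, 40, 40, 30, 20, 15, 10, 10, 25),
    radius = c(NA, rep(1.75, 7), 2.5),
    solubility = NA_real_,
    dlm_scalar = NA_real_,
    cyp3a_abundance = c(0, 1, 1, 0.9, 0.6, 0.5, 0.4, 0.3, 0.1),
    perm_scale = c(0, rep(1, 7), colon_perm_scale),
    stringsAsFactors = FALSE)
  for (m in names(protocol$region_map)) {
    rows <- match(protocol$region_map[[m]], nm)
    reg$solubility[rows] <- protocol$media[[m]]$solubility
  }
  if (!is.null(dlm_scalars)) reg$dlm_scalar[] <- dlm_scalars[nm]
  reg
}

# per-region first-order dissolution coefficient (1/h per unit driving
# concentration): diffusion-layer rate of the full-dose particle population
# at unit (Cs - Cb), scaled to the regional solid mass at fixed radii.
dlm_mass_coeff <- function(form) {
  st <- dissolution_state(form$bins, dissolved = 0, bulk_conc = 0)
  dlm_rate(st, solubility = 1, scalar = 1, form) / form$dose * 60  # mL/(mg*h) per mg solid
}

#' Build the GI right-hand side for the transit/absorption/metabolism model
#'
#' State layout (all mg): solid S1..S9, dissolved W1..W9, enterocyte E1..E9,
#' then cumulative absorbed-to-portal, gut-metabolised, and fecal loss
#' (split into its solid and dissolved components).  Solid and
#' dissolved pools transit sequentially at each region's transit rate;
#' dissolution follows either the region-scalar diffusion-layer model or an
#' externally supplied release hazard applied to all solid; absorption flux
#' is `2 Peff / radius` times the dissolved amount (no gastric absorption);
#' absorbed drug traverses an enterocyte pool with first-order CYP3A4/5
#' metabolism scaled by regional abundance before reaching the portal vein;
#' solid and dissolved drug leaving the Colon is counted as fecal loss
#' (tracked separately by phase).
#'
#' @keywords internal
#' @noRd
gi_rhs_factory <- function(form, regions, compound, mode = c("dlm", "profile"),
                           hazard_fun = NULL) {
  mode <- match.arg(mode)
  kt <- regions$transit_rate
  V <- regions$fluid_volume
  Cs <- regions$solubility
  sc <- regions$dlm_scalar
  if (mode == "dlm" && anyNA(sc))
    stop("unresolved dissolution scalar for region(s): ",
         paste(regions$name[is.na(sc)], collapse = ", "),
         " (resolve by sensitivity analysis first)")
  peff_cm_h <- compound$peff * 1e-4 * 3600
  ka <- ifelse(is.na(regions$radius), 0,
               2 * peff_cm_h / regions$radius * regions$perm_scale)
  kvilli <- compound$k_villi
  kmet <- (compound$kgut_3a4 + compound$kgut_3a5) * regions$cyp3a_abundance
  kz <- dlm_mass_coeff(form)
  function(t, y, parms) {
    S <- pmax(y[1:9], 0); W <- pmax(y[10:18], 0); E <- pmax(y[19:27], 0)
    if (mode == "dlm") {
      driving <- pmax(Cs - W / V, 0)
      diss <- sc * kz * S * driving
    } else {
      lam <- hazard_fun(t)
      diss <- lam * S
    }
    inS <- c(0, kt[1:8] * S[1:8])
    inW <- c(0, kt[1:8] * W[1:8])
    absf <- ka * W
    dS <- inS - kt * S - diss
    dW <- diss + inW - kt * W - absf
    dE <- absf - (kvilli + kmet) * E
    portal <- sum(kvilli * E)
    gutmet <- sum(kmet * E)
    list(c(dS, dW, dE, portal, gutmet, kt[9] * S[9], kt[9] * W[9]),
         portal = portal)
  }
}

gi_traj_frame <- function(sol) {
  nm <- gi_region_names()
  df <- as.data.frame(sol)
  base <- c("time_h", paste0("solid.", nm), paste0("dissolved.", nm),
            paste0("enterocyte.", nm), "absorbed", "gut_metabolised",
            "fecal_solid", "fecal_dissolved")
  if (ncol(df) == length(base) + 1) base <- c(base, "portal_rate")
  names(df) <- base
  df
}

#' Simulate GI transit and absorption with mechanistic regional dissolution
#'
#' @param form A [formulation] (dose, particle population, density,
#'   diffusivity).
#' @param regions GI physiology table from [gi_regions()] with all nine
#'   `dlm_scalar` values resolved.
#' @param compound A [compound_disposition()] (supplies permeability and gut
#'   metabolism constants).
#' @param t_grid Output times (h).
#' @param rtol,atol Solver tolerances.
#' @return List with `trajectory` (data.frame of all GI pools, cumulative
#'   absorbed/gut-metabolised/fecal amounts and the instantaneous portal
#'   rate) and `portal_rate` (function of time, mg/h).
#' @export
simulate_gi_dlm <- function(form, regions, compound,
                            t_grid = seq(0, 24, by = 0.05),
                            rtol = 1e-8, atol = 1e-10) {
  rhs <- gi_rhs_factory(form, regions, compound, mode = "dlm")
  y0 <- c(form$dose, rep(0, 30))
  sol <- deSolve::lsoda(y0, t_grid, rhs, parms = NULL, rtol = rtol, atol = atol)
  traj <- gi_traj_frame(sol)
  pr <- stats::approxfun(traj$time_h, traj$portal_rate, rule = 2)
  list(trajectory = traj, portal_rate = pr)
}

#' Release hazard implied by an in vitro cumulative profile
#'
#' Converts a cumulative-fraction curve `d(t)` into the first-order release
#' hazard `lambda(t) = d'(t) / (1 - d(t))` (1/h), piecewise constant on the
#' profile's intervals, capped at `lambda_max`, and held at its final value
#' beyond the profile end.  Applying this hazard to all remaining solid
#' makes total in vivo release track the in vitro curve exactly while solid
#' remains in transit (no fecal solid loss).
#'
#' @param profile A [dissolution_profile] (times in minutes).
#' @param lambda_max Hazard cap (1/h), default 50.
#' @return Function of time in hours returning the hazard (1/h).
#' @export
release_hazard <- function(profile, lambda_max = 50) {
  t_h <- profile$times / 60
  d <- pmin(pmax(profile$cum_pct / 100, 0), 1)
  if (length(t_h) < 2) stop("profile needs at least 2 points")
  # hazard on each interval from the survival ratio; exact for the
  # piecewise-exponential representation of the observed curve
  surv <- 1 - d
  dt <- diff(t_h)
  ratio <- surv[-1] / pmax(surv[-length(surv)], 1e-300)
  lam <- -log(pmax(ratio, 1e-300)) / dt
  lam <- pmin(pmax(lam, 0), lambda_max)
  if (d[1] >= 1) lam[] <- lambda_max
  lam0 <- if (d[1] > 0 && t_h[1] > 0) {
    min(-log(max(1 - d[1], 1e-300)) / t_h[1], lambda_max)
  } else if (d[1] > 0) lambda_max else 0
  breaks <- t_h
  function(t) {
    i <- findInterval(t, breaks)
    out <- numeric(length(t))
    out[i == 0] <- lam0
    inside <- i >= 1 & i < length(breaks)
    out[inside] <- lam[i[inside]]
    out[i >= length(breaks)] <- lam[length(lam)]
    out
  }
}

#' Simulate GI transit and absorption driven by an in vitro profile
#'
#' The in vitro cumulative dissolution curve is converted to a release
#' hazard ([release_hazard()]) applied to all transiting solid, so in vivo
#' release tracks the in vitro curve wherever no competing sink intervenes;
#' transit, absorption and gut metabolism are identical to
#' [simulate_gi_dlm()].
#'
#' @inheritParams simulate_gi_dlm
#' @param profile A [dissolution_profile] measured over the 6 h protocol;
#'   beyond its end the hazard is held at its final value.
#' @param dose Dose administered (mg), default 5.
#' @param lambda_max Hazard cap (1/h) used when the profile is complete.
#' @return As [simulate_gi_dlm()].
#' @export
simulate_gi_profile <- function(profile, regions, compound, dose = 5,
                                t_grid = seq(0, 24, by = 0.05),
                                lambda_max = 50, rtol = 1e-8, atol = 1e-10) {
  hz <- release_hazard(profile, lambda_max = lambda_max)
  form <- formulation(dose = dose)
  rhs <- gi_rhs_factory(form, regions, compound, mode = "profile",
                        hazard_fun = hz)
  y0 <- c(form$dose, rep(0, 30))
  sol <- deSolve::lsoda(y0, t_grid, rhs, parms = NULL, rtol = rtol, atol = atol)
  traj <- gi_traj_frame(sol)
  pr <- stats::approxfun(traj$time_h, traj$portal_rate, rule = 2)
  list(trajectory = traj, portal_rate = pr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
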