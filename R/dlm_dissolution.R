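#' Formulation model for diffusion-layer dissolution
#'
#' Holds the dose, particle density, aqueous diffusivity, particle-size
#' distribution (as bins of radius and particle count), per-medium apparent
#' solubility and per-region dissolution scalars.  Bin counts are derived so
#' that the bins exactly conserve the dose:
#' `sum(count * 4/3 * pi * r^3 * density) = dose`.
#'
#' @param dose Dose (mg), > 0.
#' @param density True density of the dissolving particles (g/mL).
#' @param diffusivity Aqueous diffusion coefficient (cm^2/s).
#' @param radius_um Particle radii (micrometres) of the size bins.
#' @param weights Mass fraction of the dose in each bin (recycled/normalised).
#' @param solubility_by_medium Named numeric vector, medium name -> mg/mL.
#'   Defaults to the illustrative values of [default_media()].
#' @param dlm_scalars Named numeric vector of dimensionless dissolution
#'   scalars keyed by GI region and/or medium name; all >= 0.
#' @param hmax Diffusion-layer thickness cap (micrometres), default 30.
#' @return Object of class `formulation`.
#' @export
formulation <- function(dose = 5, density = 1.3, diffusivity = 5e-6,
                        radius_um = 10, weights = 1,
                        solubility_by_medium = NULL,
                        dlm_scalars = numeric(0), hmax = 30) {
  stopifnot(dose > 0, density > 0, diffusivity > 0, all(radius_um > 0),
            hmax > 0)
  if (length(dlm_scalars) && any(dlm_scalars < 0))
    stop("dlm_scalars must be >= 0")
  if (is.null(solubility_by_medium))
    solubility_by_medium <- vapply(default_media(), `[[`, 0, "solubility")
  w <- rep_len(weights, length(radius_um))
  w <- w / sum(w)
  r_cm <- radius_um * 1e-4
  mass_per_particle <- (4 / 3) * pi * r_cm^3 * density * 1000  # mg
  bins <- data.frame(radius = radius_um,
                     count = dose * w / mass_per_particle)
  structure(list(dose = dose, density = density, diffusivity = diffusivity,
                 bins = bins, solubility_by_medium = solubility_by_medium,
                 dlm_scalars = dlm_scalars, hmax = hmax),
            class = "formulation")
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf("<formulation> dose %.3g mg, %d size bin(s), density %.2f g/mL, D %.2g cm2/s\n",
              x$dose, nrow(x$bins), x$density, x$diffusivity))
  invisible(x)
}

#' Snapshot of a dissolving particle population
#'
#' @param bins `data.frame` with columns `radius` (um) and `count`.
#' @param dissolved Mass in solution (mg).
#' @param bulk_conc Bulk concentration seen by the particles (mg/mL).
#' @return Object of class `dissolution_state`.
#' @export
dissolution_state <- function(bins, dissolved = 0, bulk_conc = 0) {
  stopifnot(all(bins$radius >= 0), all(bins$count >= 0),
            dissolved >= 0, bulk_conc >= 0)
  structure(list(bins = as.data.frame(bins), dissolved = dissolved,
                 bulk_conc = bulk_conc), class = "dissolution_state")
}

#' Solid mass held in a particle-bin table (mg)
#' @param bins Bin `data.frame` (radius um, count).
#' @param density Particle density (g/mL).
#' @export
bins_mass <- function(bins, density) {
  sum(bins$count * (4 / 3) * pi * (bins$radius * 1e-4)^3 * density * 1000)
}

#' Diffusion-layer dissolution rate
#'
#' Nernst-Brunner rate for a population of spherical particles with an
#' effective diffusion-layer thickness `h = min(r, hmax)`:
#' `rate = scalar * sum_i count_i * 4 pi r_i (r_i + h_i) * (D / h_i) * (Cs - Cb)`
#' in mg/min, clipped at 0 when the bulk is at or above saturation (no
#' precipitation is modelled).  The dimensionless scalar multiplies the whole
#' rate, so the rate is exactly linear in it.
#'
#' @param state A [dissolution_state].
#' @param solubility Drug solubility in the current medium (mg/mL).
#' @param scalar Dimensionless dissolution scalar, >= 0.
#' @param form A [formulation] (supplies density, diffusivity, hmax).
#' @return Dissolution rate (mg/min), >= 0.
#' @export
dlm_rate <- function(state, solubility, scalar, form) {
  if (!is.finite(scalar) || scalar < 0) stop("scalar must be >= 0")
  driving <- solubility - state$bulk_conc
  if (driving <= 0 || scalar == 0) return(0)
  r <- state$bins$radius * 1e-4            # cm
  h <- pmin(r, form$hmax * 1e-4)           # cm
  D <- form$diffusivity * 60               # cm^2/min
  live <- r > 0 & state$bins$count > 0
  if (!any(live)) return(0)
  r <- r[live]; h <- h[live]
  scalar * sum(state$bins$count[live] * 4 * pi * r * (r + h) * (D / h)) * driving
}

#' Shrink particles after a dissolution increment
#'
#' Apportions a dissolved-mass increment `dm` across bins in proportion to
#' each bin's instantaneous diffusion-layer rate factor (surface area over
#' layer thickness) at constant particle count, updating radii by
#' cube-root mass loss.  Bins falling below the radius cutoff are zeroed and
#' their residual mass moved to the dissolved pool, so total mass is
#' conserved exactly.
#'
#' @param state A [dissolution_state].
#' @param dm Dissolved mass increment (mg), `0 <= dm <=` remaining solid.
#' @param form A [formulation].
#' @param r_cutoff Radius (um) below which a bin is considered exhausted.
#' @return Updated [dissolution_state].
#' @export
shrink_particles <- function(state, dm, form, r_cutoff = 0.01) {
  if (!is.finite(dm) || dm < 0) stop("dm must be >= 0")
  solid <- bins_mass(state$bins, form$density)
  if (dm > solid * (1 + 1e-12)) stop("dm exceeds remaining solid mass")
  if (dm == 0) return(state)
  bins <- state$bins
  m <- bins$count * (4 / 3) * pi * (bins$radius * 1e-4)^3 * form$density * 1000
  r <- bins$radius * 1e-4
  h <- pmin(r, form$hmax * 1e-4)
  live <- r > 0 & bins$count > 0
  w <- numeric(nrow(bins))
  w[live] <- bins$count[live] * r[live] * (r[live] + h[live]) / h[live]
  if (sum(w) <= 0) w <- m
  dm_i <- dm * w / sum(w)
  # a bin cannot lose more than it holds; redistribute any excess
  for (k in 1:5) {
    over <- pmax(dm_i - m, 0)
    if (sum(over) <= 1e-15) break
    dm_i <- pmin(dm_i, m)
    room <- m - dm_i
    if (sum(room) > 0) dm_i <- dm_i + sum(over) * room / sum(room)
  }
  m_new <- pmax(m - dm_i, 0)
  bins$radius <- bins$radius * (m_new / pmax(m, 1e-300))^(1 / 3)
  dead <- bins$radius < r_cutoff
  extra <- 0
  if (any(dead)) {
    extra <- bins_mass(bins[dead, , drop = FALSE], form$density)
    bins$radius[dead] <- 0
    bins$count[dead] <- 0
  }
  dissolution_state(bins, dissolved = state$dissolved + dm + extra,
                    bulk_conc = state$bulk_conc)
}
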