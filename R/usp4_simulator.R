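#' Cumulative dissolution profile
#'
#' @param times Time points (min), strictly increasing.
#' @param cum_pct Cumulative percent of dose dissolved, nondecreasing,
#'   within `[0, 100]` up to 0.5 percentage points of numerical slack.
#' @param label Formulation identifier.
#' @return Object of class `dissolution_profile`.
#' @export
dissolution_profile <- function(times, cum_pct, label = "formulation") {
  p <- structure(list(times = as.numeric(times), cum_pct = as.numeric(cum_pct),
                      label = label), class = "dissolution_profile")
  viol <- validate_profile(p)
  if (length(viol)) stop("invalid dissolution profile: ",
                         paste(viol, collapse = "; "))
  p
}

validate_profile <- function(p) {
  v <- character(0)
  if (length(p$times) != length(p$cum_pct))
    return("times and cum_pct lengths differ")
  if (any(diff(p$times) <= 0)) {
    bad <- which(diff(p$times) <= 0) + 1
    v <- c(v, sprintf("times not strictly increasing at row(s) %s",
                      paste(bad, collapse = ", ")))
  }
  slack <- 0.5
  if (any(p$cum_pct < -slack | p$cum_pct > 100 + slack)) {
    bad <- which(p$cum_pct < -slack | p$cum_pct > 100 + slack)
    v <- c(v, sprintf("cum_pct outside [0, 100] at row(s) %s",
                      paste(bad, collapse = ", ")))
  }
  if (any(diff(p$cum_pct) < -1e-6)) {
    bad <- which(diff(p$cum_pct) < -1e-6) + 1
    v <- c(v, sprintf("cum_pct decreasing at row(s) %s",
                      paste(bad, collapse = ", ")))
  }
  v
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat(sprintf("<dissolution_profile> '%s': %d points over [%g, %g] min, final %.1f%%\n",
              x$label, length(x$times), min(x$times), max(x$times),
              x$cum_pct[length(x$cum_pct)]))
  invisible(x)
}

#' Linear interpolation of a profile as cumulative fraction of dose
#' @param profile A `dissolution_profile`.
#' @return Function of time (min) returning fraction in `[0, 1]`.
#' @export
profile_fraction_fun <- function(profile) {
  f <- stats::approxfun(profile$times, pmin(pmax(profile$cum_pct, 0), 100) / 100,
                        rule = 2)
  function(t) f(t)
}

#' Simulate an open-loop flow-through (USP IV) dissolution experiment
#'
#' The cell is treated as an ideally mixed vessel of fixed volume perfused at
#' the protocol flow rate: dissolved drug produced by the diffusion-layer
#' model accumulates in the cell and is washed out to the collected effluent
#' at rate `Q/V * M_cell`.  The cumulative percent dissolved counts cell plus
#' effluent.  At a medium switch the cell contents are replaced by the new
#' medium instantaneously while dissolved drug is carried over, preserving
#' mass balance.  Particle bins shrink as they dissolve (cube-root mass
#' loss); exhausted bins are retired.
#'
#' @param form A [formulation].
#' @param protocol A `dissolution_protocol`.
#' @param scalars_by_medium Named numeric vector: one dissolution scalar per
#'   protocol medium. Missing media raise a configuration error.
#' @param t_grid Output times (min) within the protocol span; default 5-min
#'   spacing over the whole protocol.
#' @param rtol,atol Solver tolerances (lsoda).
#' @param rate_fn Optional replacement for the diffusion-layer rate, called
#'   as `rate_fn(bins, bulk_conc, medium, scalar, form)` and returning
#'   mg/min; used for analytic oracles in tests.
#' @param full Return the full trajectory (solid, in-cell, collected) as the
#'   `trajectory` attribute.
#' @return A [dissolution_profile] on `t_grid` (label from the formulation
#'   scalars), with a `trajectory` data.frame attribute when `full = TRUE`.
#' @export
simulate_usp4 <- function(form, protocol, scalars_by_medium,
                          t_grid = NULL, rtol = 1e-8, atol = 1e-10,
                          rate_fn = NULL, full = FALSE) {
  seg <- protocol$segments
  missing_m <- setdiff(seg$medium, names(scalars_by_medium))
  if (length(missing_m))
    stop("no dissolution scalar for medium: ", paste(missing_m, collapse = ", "))
  end <- protocol_end(protocol)
  if (is.null(t_grid)) t_grid <- seq(0, end, by = 5)
  if (min(t_grid) < 0 || max(t_grid) > end + 1e-9)
    stop("t_grid outside protocol span")
  V <- protocol$cell_volume
  nb <- nrow(form$bins)
  counts <- form$bins$count
  dens <- form$density
  # state: per-bin solid mass (mg), dissolved in cell (mg), collected (mg)
  m0 <- counts * (4 / 3) * pi * (form$bins$radius * 1e-4)^3 * dens * 1000
  y <- c(m0, 0, 0)
  D <- form$diffusivity * 60
  hmax_cm <- form$hmax * 1e-4
  const_r <- (3 / (4 * pi * dens * 1000))^(1 / 3)   # mass (mg) -> radius (cm)

  rhs_factory <- function(med, scalar, Q) {
    Cs <- med$solubility
    kw <- Q / V
    force(scalar)
    function(t, y, parms) {
      m <- pmax(y[seq_len(nb)], 0)
      Mcell <- y[nb + 1]
      Cb <- max(Mcell, 0) / V
      driving <- Cs - Cb
      if (!is.null(rate_fn)) {
        bins <- data.frame(radius = const_r * (m / pmax(counts, 1e-300))^(1 / 3) * 1e4,
                           count = counts)
        rate_tot <- rate_fn(bins, Cb, med, scalar, form)
        rate_i <- if (nb == 1) rate_tot else rate_tot * m / max(sum(m), 1e-300)
        rate_i <- pmin(rate_i, ifelse(m > 0, Inf, 0))
      } else if (driving <= 0 || scalar == 0) {
        rate_i <- numeric(nb)
      } else {
        r <- const_r * (m / pmax(counts, 1e-300))^(1 / 3)
        h <- pmin(r, hmax_cm)
        live <- m > atol & counts > 0
        rate_i <- numeric(nb)
        if (any(live))
          rate_i[live] <- scalar * counts[live] * 4 * pi * r[live] *
            (r[live] + h[live]) * (D / h[live]) * driving
      }
      list(c(-rate_i, sum(rate_i) - kw * Mcell, kw * Mcell))
    }
  }

  maxbins <- 32
  if (nb > maxbins) stop("at most ", maxbins, " particle-size bins supported")
  out_t <- sort(unique(c(t_grid, seg$start, end)))
  traj <- matrix(NA_real_, nrow = length(out_t), ncol = nb + 2)
  traj[1, ] <- y
  done <- 1
  for (i in seq_len(nrow(seg))) {
    a <- seg$start[i]
    b <- if (i < nrow(seg)) seg$start[i + 1] else end
    tt <- out_t[out_t >= a & out_t <= b]
    if (length(tt) == 0 || tt[1] > a) tt <- c(a, tt)
    med <- protocol$media[[seg$medium[i]]]
    if (is.null(rate_fn)) {
      pv <- c(nb, scalars_by_medium[[seg$medium[i]]], med$solubility,
              seg$flow_rate[i] / V, D, hmax_cm, dens * 1000, V,
              counts, rep(0, maxbins - nb))
      sol <- deSolve::lsoda(y, tt, func = "usp4_derivs", parms = pv,
                            dllname = "usp4pbpk", initfunc = "usp4_init",
                            rtol = rtol, atol = atol)
    } else {
      f <- rhs_factory(med, scalars_by_medium[[seg$medium[i]]], seg$flow_rate[i])
      sol <- deSolve::lsoda(y, tt, f, parms = NULL, rtol = rtol, atol = atol)
    }
    y <- as.numeric(sol[nrow(sol), -1])
    keep <- tt %in% out_t & tt > out_t[done]
    idx <- match(tt[keep], out_t)
    traj[idx, ] <- sol[keep, -1, drop = FALSE]
    if (length(idx)) done <- max(idx)
  }
  solid <- if (nb == 1) pmax(traj[, 1], 0) else rowSums(pmax(traj[, seq_len(nb), drop = FALSE], 0))
  cell <- traj[, nb + 1]
  coll <- traj[, nb + 2]
  cum <- pmin(pmax((cell + coll) / form$dose * 100, 0), 100)
  cum <- cummax(cum)  # guard sub-tolerance wiggle
  sel <- match(t_grid, out_t)
  prof <- dissolution_profile(t_grid, cum[sel], label = "simulated")
  if (full)
    attr(prof, "trajectory") <- data.frame(time_min = out_t, solid = solid,
                                           in_cell = cell, collected = coll)
  prof
}

#' Read / write dissolution profiles as CSV
#'
#' CSV dialect: comma separated, dot decimal, header exactly
#' `time_min,pct_dissolved`.  Profiles are validated on read; violations
#' (non-monotone cumulative percent, unsorted times, out-of-range values)
#' are reported with the offending rows.
#'
#' @param path File path.
#' @param label Formulation identifier attached on read.
#' @return `read_profile`: a [dissolution_profile].
#' @export
read_profile <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("time_min", "pct_dissolved")))
    stop("expected header 'time_min,pct_dissolved' in ", path)
  p <- structure(list(times = as.numeric(df$time_min),
                      cum_pct = as.numeric(df$pct_dissolved), label = label),
                 class = "dissolution_profile")
  viol <- validate_profile(p)
  if (length(viol)) stop("invalid profile in ", path, ": ",
                         paste(viol, collapse = "; "))
  p
}

#' @param profile A [dissolution_profile] to write.
#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(data.frame(time_min = profile$times,
                              pct_dissolved = profile$cum_pct),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
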