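#' Non-compartmental metrics of a concentration-time profile
#'
#' AUC by the linear trapezoid rule on the recorded grid over 0-144 h,
#' Cmax as the highest concentration, Tmax as the time of the first
#' maximum.  Profiles shorter than 144 h are evaluated on their available
#' span and flagged with a warning attribute.
#'
#' @param profile A `pk_profile`, or any data.frame with `time_h` and
#'   `conc_blood` columns.
#' @param t_end Upper integration limit (h), default 144.
#' @return Object of class `pk_metrics`: list with `auc_0_144` (ng.h/mL),
#'   `cmax` (ng/mL), `tmax` (h) and logical `truncated`.
#' @export
compute_metrics <- function(profile, t_end = 144) {
  t <- profile$time_h
  c_ <- profile$conc_blood
  truncated <- max(t) < t_end
  if (truncated)
    warning(sprintf("profile ends at %.3g h; AUC computed on available span",
                    max(t)))
  keep <- t <= t_end + 1e-9
  t <- t[keep]; c_ <- c_[keep]
  auc <- trapz(t, c_)
  imax <- which.max(c_)   # first occurrence on ties
  structure(list(auc_0_144 = auc, cmax = c_[imax], tmax = t[imax],
                 truncated = truncated), class = "pk_metrics")
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf("<pk_metrics> AUC0-144 %.2f ng*h/mL  Cmax %.2f ng/mL  Tmax %.2f h%s\n",
              x$auc_0_144, x$cmax, x$tmax,
              if (x$truncated) " (truncated span)" else ""))
  invisible(x)
}

#' Study-level summary of per-subject metrics
#'
#' @param profiles List of `pk_profile` (or data.frames), one per subject.
#' @param t_end Upper integration limit (h).
#' @return `data.frame` with mean and SD of AUC0-144, Cmax and Tmax.
#' @export
summarize_study <- function(profiles, t_end = 144) {
  m <- lapply(profiles, compute_metrics, t_end = t_end)
  vals <- data.frame(auc_0_144 = vapply(m, `[[`, 0, "auc_0_144"),
                     cmax = vapply(m, `[[`, 0, "cmax"),
                     tmax = vapply(m, `[[`, 0, "tmax"))
  data.frame(metric = c("auc_0_144", "cmax", "tmax"),
             mean = vapply(vals, mean, 0),
             sd = vapply(vals, stats::sd, 0),
             row.names = NULL)
}

#' Fold error between observed and simulated means
#'
#' The ratio of the larger to the smaller of the two (study-mean) values,
#' reported to two decimals.  Symmetric, always >= 1, equal to 1 iff the
#' means coincide.
#'
#' @param mean_obs,mean_sim Positive mean values of the same PK metric.
#' @param digits Decimals in the reported value (default 2; `NA` for
#'   unrounded).
#' @return Dimensionless fold error >= 1.
#' @export
#' @examples
#' fold_error(355.87, 378.12)  # 1.06
#' fold_error(16.46, 13.10)    # 1.26
fold_error <- function(mean_obs, mean_sim, digits = 2) {
  if (any(!is.finite(c(mean_obs, mean_sim))) || mean_obs <= 0 || mean_sim <= 0)
    stop("fold error requires positive observed and simulated means")
  fe <- max(mean_obs, mean_sim) / min(mean_obs, mean_sim)
  if (is.na(digits)) fe else round(fe, digits)
}

#' Classify model performance by fold error
#'
#' A fold error at or below 1.25 indicates good performance, at or below
#' 2 acceptable performance, and above 2 failure.
#'
#' @param fe Fold error, >= 1.
#' @return `"good"`, `"acceptable"` or `"fail"` (vectorised).
#' @export
performance_class <- function(fe) {
  if (any(!is.finite(fe)) || any(fe < 1)) stop("fold error must be >= 1")
  ifelse(fe <= 1.25, "good", ifelse(fe <= 2, "acceptable", "fail"))
}

#' Observed-vs-simulated performance report
#'
#' Builds the study-comparison table: mean +/- SD of AUC0-144, Cmax and
#' Tmax for both arms, the fold error of the means and its performance
#' class.
#'
#' @param observed,simulated Lists of per-subject profiles (see
#'   [summarize_study()]), or precomputed summaries from it.
#' @return `data.frame` with one row per metric.
#' @export
metrics_report <- function(observed, simulated) {
  so <- if (is.data.frame(observed)) observed else summarize_study(observed)
  ss <- if (is.data.frame(simulated)) simulated else summarize_study(simulated)
  fe <- mapply(fold_error, so$mean, ss$mean)
  data.frame(metric = so$metric,
             mean_obs = so$mean, sd_obs = so$sd,
             mean_sim = ss$mean, sd_sim = ss$sd,
             fold_error = fe,
             class = performance_class(fe),
             row.names = NULL)
}
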