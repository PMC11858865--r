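#' Generate a synthetic cumulative dissolution profile
#'
#' Weibull release `F(t) = fmax * (1 - exp(-(t/td)^beta))` with optional
#' additive Gaussian noise; after noise the curve is restored to a valid
#' cumulative profile by isotonic regression and clamping to `[0, fmax']`.
#' `beta > 1` gives the sigmoidal shapes typical of pH-responsive
#' (Eudragit-S100) matrices, `beta <= 1` with `fmax < 100` the plateauing,
#' incomplete release of ethylcellulose matrices.
#'
#' @param fmax Release asymptote (%), in (0, 100].
#' @param td Time scale (min), > 0: time to 63.2% of `fmax` when
#'   `beta = 1`.
#' @param beta Shape exponent, > 0.
#' @param noise_sd Additive noise SD (% points), >= 0.
#' @param seed Integer seed (noise is reproducible).
#' @param t_grid Time points (min), default 5-min spacing over 6 h.
#' @param label Profile label.
#' @return A [dissolution_profile].
#' @export
#' @examples
#' gen_profile(fmax = 100, td = 60, beta = 1)$cum_pct[13]  # F(60) = 63.21
gen_profile <- function(fmax = 100, td = 60, beta = 1, noise_sd = 0,
                        seed = 1, t_grid = seq(0, 360, by = 5),
                        label = "synthetic") {
  stopifnot(fmax > 0, fmax <= 100, td > 0, beta > 0, noise_sd >= 0)
  f <- fmax * (1 - exp(-(t_grid / td)^beta))
  if (noise_sd > 0) {
    set.seed(seed)
    f <- f + stats::rnorm(length(f), sd = noise_sd)
    f[t_grid == 0] <- 0
    f <- stats::isoreg(t_grid, f)$yf
    f <- pmin(pmax(f, 0), 100)
  }
  dissolution_profile(t_grid, f, label = label)
}

#' Named dissolution-profile presets
#'
#' Presets emulating the qualitative behaviour of the eight amorphous
#' solid dispersion candidates plus the slow reference product:
#' `"advagraf"` is a slow, incomplete release reaching about 50% at 6 h;
#' `"test"` (alias of `"TAC1I8"`) is a fast sigmoidal release complete by
#' about 2.5 h.  Eudragit-S100 presets (`TAC1*`) are sigmoidal and
#' essentially complete; ethylcellulose presets (`TAC3*`) plateau below
#' 100%; intra-granular surfactant (`*I*`) releases faster and further
#' than extra-granular (`*E*`).  Parameter values are illustrative.
#'
#' @param preset Preset name.
#' @param noise_sd,seed,t_grid Passed to [gen_profile()].
#' @return A [dissolution_profile].
#' @export
profile_preset <- function(preset = c("advagraf", "test", "TAC1E5", "TAC1E8",
                                      "TAC1I8", "TAC1I7", "TAC3E5", "TAC3E6",
                                      "TAC3I5", "TAC3I6"),
                           noise_sd = 0, seed = 1,
                           t_grid = seq(0, 360, by = 5)) {
  preset <- match.arg(preset)
  par <- switch(preset,
    advagraf = c(60, 200, 1.0),
    test = ,
    TAC1I8 = c(100, 65, 2.0),
    TAC1I7 = c(100, 85, 1.9),
    TAC1E8 = c(97, 120, 1.8),
    TAC1E5 = c(95, 150, 1.7),
    TAC3I6 = c(70, 190, 1.0),
    TAC3I5 = c(65, 210, 1.0),
    TAC3E6 = c(55, 230, 0.9),
    TAC3E5 = c(45, 260, 0.9))
  gen_profile(fmax = par[1], td = par[2], beta = par[3], noise_sd = noise_sd,
              seed = seed, t_grid = t_grid, label = preset)
}

#' Generate a virtual single-dose PK study
#'
#' Simulates `n` subjects with between-subject log-normal parameter
#' variability ([simulate_population()]), samples each subject's whole-blood
#' curve at a clinical sampling schedule, applies multiplicative log-normal
#' residual error, and returns an observed-style long table together with
#' the ground-truth generating configuration -- the parameter-recovery
#' harness for the rest of the pipeline.
#'
#' @inheritParams simulate_population
#' @param residual_cv Residual (assay) CV as a proportion, >= 0.
#' @param sample_times Sampling schedule (h), default a rich 0-144 h
#'   schedule with dense early sampling.
#' @return List with `data` (data.frame `subject_id`, `time_h`,
#'   `conc_ng_ml`), `truth` (list of generating parameters) and `subjects`
#'   (noise-free per-subject profiles).
#' @export
gen_virtual_study <- function(form, regions, disp, n = 12,
                              cv = c(clint = 0.3, vc = 0.25, peff = 0.3),
                              residual_cv = 0.1, seed = 1,
                              mode = c("dlm", "profile"), profile = NULL,
                              sample_times = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5,
                                               4, 5, 6, 8, 12, 24, 48, 72, 96,
                                               120, 144)) {
  mode <- match.arg(mode)
  stopifnot(residual_cv >= 0)
  t_grid <- sort(unique(c(sample_times, seq(0, 144, by = 0.25))))
  pop <- simulate_population(form, regions, disp, n = n, cv = cv, seed = seed,
                             mode = mode, profile = profile, t_grid = t_grid)
  sig <- sqrt(log(1 + residual_cv^2))
  rows <- lapply(seq_len(n), function(i) {
    p <- pop$subjects[[i]]
    conc <- p$conc_blood[match(sample_times, p$time_h)]
    if (residual_cv > 0) conc <- conc * exp(sig * stats::rnorm(length(conc)))
    data.frame(subject_id = sprintf("S%02d", i), time_h = sample_times,
               conc_ng_ml = conc)
  })
  list(data = do.call(rbind, rows),
       truth = list(regions = regions, disp = disp, form = form, cv = cv,
                    residual_cv = residual_cv, seed = seed, n = n),
       subjects = pop$subjects)
}

#' Split an observed-style PK table into per-subject profiles
#' @param data `data.frame` with `subject_id`, `time_h`, `conc_ng_ml`.
#' @return Named list of `pk_profile` objects.
#' @export
split_subjects <- function(data) {
  lapply(split(data, data$subject_id), function(d)
    pk_profile(d$time_h, d$conc_ng_ml, subject_id = d$subject_id[1]))
}

#' Read / write observed-style PK study tables
#' @param path CSV path with header `subject_id,time_h,conc_ng_ml`.
#' @export
read_pk_study <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_h", "conc_ng_ml")
  if (!all(need %in% names(df)))
    stop("expected columns subject_id,time_h,conc_ng_ml in ", path)
  df
}

#' @param data Study table to write.
#' @rdname read_pk_study
#' @export
write_pk_study <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
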