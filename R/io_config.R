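#' Default run configuration
#'
#' A fully populated configuration list mirroring what
#' [load_config()] reads from YAML: compound disposition, formulation,
#' dissolution protocol (media, segments, cell volume) and trial design.
#' The bundled file `inst/extdata/default_config.yaml` contains exactly
#' this configuration.
#'
#' @param mode `"dlm"` or `"profile"`.
#' @return Nested configuration list.
#' @export
default_config <- function(mode = "dlm") {
  media <- default_media()
  cfg <- list(
    mode = mode,
    compound = unclass(compound_disposition()),
    formulation = list(dose = 5, density = 1.3, diffusivity = 5e-6,
                       radius_um = 10, weights = 1, hmax = 30,
                       dlm_scalars = list()),
    protocol = list(
      cell_volume = 20,
      segments = list(
        list(medium = "FaSSGF", start = 0, duration = 30, flow_rate = 8),
        list(medium = "FaSSIF-V2", start = 30, duration = 40, flow_rate = 4),
        list(medium = "FaSSIF-V2 midgut", start = 70, duration = 80, flow_rate = 4),
        list(medium = "SIF Ileum-V2", start = 150, duration = 60, flow_rate = 4),
        list(medium = "FaSSCoF", start = 210, duration = 150, flow_rate = 4)),
      media = lapply(media, function(m)
        list(pH = m$pH, buffer_total = m$buffer_total,
             buffer_pka1 = m$buffer_pka1, buffer_pka2 = m$buffer_pka2,
             bile_salt = m$bile_salt, solubility = m$solubility))),
    trial = list(n_subjects = 12, cv = list(clint = 0.3, vc = 0.25, peff = 0.3),
                 residual_cv = 0.1))
  cfg
}

config_schema <- function() {
  list(top = c("mode", "compound", "formulation", "protocol", "trial"),
       compound = names(formals(compound_disposition)),
       formulation = c("dose", "density", "diffusivity", "radius_um",
                       "weights", "hmax", "dlm_scalars"),
       protocol = c("cell_volume", "segments", "media"),
       segment = c("medium", "start", "duration", "flow_rate"),
       medium = c("pH", "buffer_total", "buffer_pka1", "buffer_pka2",
                  "bile_salt", "solubility"),
       trial = c("n_subjects", "cv", "residual_cv"))
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) at %s: %s", where, paste(bad, collapse = ", ")))
}

#' Load and validate a run configuration from YAML
#'
#' Unknown keys are rejected with their location; omitted keys fall back to
#' the package defaults.  In `dlm` mode every protocol medium must carry a
#' solubility, and any supplied `dlm_scalars` must be keyed by GI region or
#' medium name.
#'
#' @param path YAML file path.
#' @return Validated configuration list (as [default_config()]).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sch <- config_schema()
  check_keys(raw, sch$top, "top level")
  cfg <- utils::modifyList(default_config(), raw)
  if (!cfg$mode %in% c("dlm", "profile"))
    stop("mode must be 'dlm' or 'profile' at top level")
  check_keys(cfg$compound, sch$compound, "compound")
  check_keys(cfg$formulation, sch$formulation, "formulation")
  check_keys(cfg$protocol, sch$protocol, "protocol")
  check_keys(cfg$trial, sch$trial, "trial")
  for (i in seq_along(cfg$protocol$segments))
    check_keys(cfg$protocol$segments[[i]], sch$segment,
               sprintf("protocol.segments[%d]", i))
  for (m in names(cfg$protocol$media))
    check_keys(cfg$protocol$media[[m]], sch$medium,
               sprintf("protocol.media['%s']", m))
  seg_media <- vapply(cfg$protocol$segments, `[[`, "", "medium")
  # a user-supplied medium section must state the drug solubility itself --
  # it is a measured input, not something the defaults should invent
  user_media <- raw$protocol$media
  no_sol <- seg_media[vapply(seg_media, function(m)
    (is.null(cfg$protocol$media[[m]]$solubility)) ||
      (!is.null(user_media) && m %in% names(user_media) &&
         is.null(user_media[[m]]$solubility)), TRUE)]
  if (cfg$mode == "dlm" && length(no_sol))
    stop("protocol.media: missing solubility for medium ",
         paste(unique(no_sol), collapse = ", "))
  known <- c(gi_region_names(), seg_media)
  bad <- setdiff(names(cfg$formulation$dlm_scalars), known)
  if (length(bad))
    stop("formulation.dlm_scalars: unknown region/medium ",
         paste(bad, collapse = ", "))
  viol <- validate_protocol(config_protocol(cfg))
  if (length(viol)) stop("protocol: ", paste(viol, collapse = "; "))
  cfg
}

#' Save a configuration to YAML
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Materialise configuration sections as model objects
#'
#' @param cfg Configuration list from [load_config()]/[default_config()].
#' @return `config_protocol`: a `dissolution_protocol`; `config_formulation`:
#'   a [formulation]; `config_disposition`: a [compound_disposition()];
#'   `config_regions`: a [gi_regions()] table with any configured per-region
#'   scalars applied.
#' @export
config_protocol <- function(cfg) {
  p <- cfg$protocol
  media <- lapply(names(p$media), function(nm) {
    m <- p$media[[nm]]
    medium(nm, pH = m$pH, buffer_total = m$buffer_total %||% 0,
           buffer_pka1 = m$buffer_pka1 %||% NA_real_,
           buffer_pka2 = m$buffer_pka2 %||% NA_real_,
           bile_salt = m$bile_salt %||% 0, solubility = m$solubility)
  })
  names(media) <- names(p$media)
  seg <- do.call(rbind, lapply(p$segments, as.data.frame))
  dissolution_protocol(seg, media, cell_volume = p$cell_volume)
}

#' @rdname config_protocol
#' @export
config_formulation <- function(cfg) {
  f <- cfg$formulation
  sol <- vapply(cfg$protocol$media, `[[`, 0, "solubility")
  formulation(dose = f$dose, density = f$density, diffusivity = f$diffusivity,
              radius_um = unlist(f$radius_um), weights = unlist(f$weights),
              solubility_by_medium = sol,
              dlm_scalars = unlist(f$dlm_scalars) %||% numeric(0),
              hmax = f$hmax)
}

#' @rdname config_protocol
#' @export
config_disposition <- function(cfg) {
  do.call(compound_disposition, cfg$compound)
}

#' @rdname config_protocol
#' @export
config_regions <- function(cfg) {
  reg <- gi_regions(config_protocol(cfg))
  sc <- cfg$formulation$dlm_scalars
  if (length(sc)) {
    rm <- default_region_map()
    for (key in names(sc)) {
      regions <- if (key %in% gi_region_names()) key else rm[[key]]
      reg$dlm_scalar[reg$name %in% regions] <- sc[[key]]
    }
  }
  reg
}

#' Run the full extrapolation pipeline
#'
#' In `dlm` mode: fit per-medium dissolution scalars from the in vitro
#' profile with the chained three-media procedure, map them to GI regions,
#' resolve any non-estimable ileal/colonic scalars by grid sensitivity
#' against the observed study (when one is given), then simulate the
#' virtual population and report fold-error performance.  In `profile`
#' mode the fitting stage is skipped and the in vitro curve drives release
#' directly.  All stage outputs (fitted scalars, sensitivity table,
#' population summary, performance report, and a machine-readable log of
#' every parameter used) are written to `out_dir` and returned.
#'
#' @param cfg Configuration list ([load_config()]).
#' @param profile In vitro [dissolution_profile] or CSV path.
#' @param observed Observed study `data.frame` or CSV path (optional;
#'   required to resolve non-estimable scalars and to report fold errors).
#' @param out_dir Output directory (created); `NULL` to skip writing.
#' @param seed Integer seed governing every stochastic stage.
#' @return List with `scalars` (fit result or NULL), `region_scalars`,
#'   `sensitivity` (table or NULL), `population`, `report` (or NULL) and
#'   `log`.
#' @export
run_pipeline <- function(cfg, profile, observed = NULL, out_dir = NULL,
                         seed = 1) {
  protocol <- config_protocol(cfg)
  form <- config_formulation(cfg)
  disp <- config_disposition(cfg)
  regions <- config_regions(cfg)
  if (is.character(profile)) profile <- read_profile(profile)
  if (is.character(observed)) observed <- read_pk_study(observed)
  obs_summary <- if (!is.null(observed)) summarize_study(split_subjects(observed))
  fit <- NULL
  sens <- NULL
  if (cfg$mode == "dlm") {
    fit <- fit_scalars_chained(profile, protocol, form, seed = seed)
    region_scalars <- map_scalars_to_regions(fit, protocol)
    needs <- attr(region_scalars, "needs_sensitivity")
    regions$dlm_scalar <- as.numeric(region_scalars)
    if (length(needs)) {
      unresolved <- setdiff(needs, c("Ileum I", "Ileum II", "Ileum III",
                                     "Ileum IV", "Colon"))
      if (length(unresolved))
        stop("non-estimable scalar(s) outside the sensitivity grid: ",
             paste(unresolved, collapse = ", "))
      if (is.null(observed))
        stop("non-estimable ileal/colonic scalars require an observed study ",
             "for sensitivity analysis")
      # seed known scalars; grid scan fills the rest
      sens <- scan_scalars(form, regions, disp, seed = seed,
                           n = cfg$trial$n_subjects,
                           cv = unlist(cfg$trial$cv),
                           observe = list(
                             sample_times = sort(unique(observed$time_h)),
                             residual_cv = cfg$trial$residual_cv))
      sel <- select_scalars(sens, obs_summary)
      regions$dlm_scalar[regions$name %in%
                           c("Ileum I", "Ileum II", "Ileum III", "Ileum IV")] <- sel$ileum
      regions$dlm_scalar[regions$name == "Colon"] <- sel$colon
      attr(sens, "selected") <- c(ileum = sel$ileum, colon = sel$colon)
    }
    mode <- "dlm"
    prof_arg <- NULL
  } else {
    mode <- "profile"
    prof_arg <- profile
    region_scalars <- NULL
  }
  pop <- simulate_population(form, regions, disp, n = cfg$trial$n_subjects,
                             cv = unlist(cfg$trial$cv), seed = seed,
                             mode = mode, profile = prof_arg)
  report <- if (!is.null(observed))
    metrics_report(obs_summary, summarize_study(pop$subjects))
  log <- list(seed = seed, mode = cfg$mode, config = cfg,
              region_scalars = if (cfg$mode == "dlm")
                stats::setNames(as.list(regions$dlm_scalar), regions$name))
  out <- list(scalars = fit, region_scalars = regions$dlm_scalar,
              sensitivity = sens, population = pop, report = report, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(fit))
      jsonlite::write_json(
        list(scalars_by_medium = as.list(fit$scalars_by_medium),
             estimable = as.list(fit$estimable),
             sse_by_window = as.list(fit$sse_by_window)),
        file.path(out_dir, "scalars.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
    if (!is.null(sens))
      utils::write.csv(as.data.frame(sens), file.path(out_dir, "sensitivity.csv"),
                       row.names = FALSE)
    if (!is.null(report))
      utils::write.csv(report, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
    summ <- data.frame(time_h = pop$mean$time_h, mean = pop$mean$conc_blood,
                       p5 = pop$p5$conc_blood, p95 = pop$p95$conc_blood)
    utils::write.csv(summ, file.path(out_dir, "pk_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  }
  out
}
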