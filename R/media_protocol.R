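#' Biorelevant dissolution medium
#'
#' A medium is characterised by its pH, total buffer concentration with the
#' two dissociation constants of the (diprotic maleate) buffer species, the
#' sodium-taurocholate-equivalent surfactant concentration, and the apparent
#' solubility of the drug in the medium.  For amorphous solid dispersions the
#' solubility is the measured "apparent" (supersaturated) value; it is a
#' configuration input, not computed from pH, because tacrolimus is
#' non-ionisable over the physiological range.
#'
#' @param name Medium identifier, e.g. `"FaSSIF-V2 midgut"`.
#' @param pH Medium pH, must lie in `[1, 9]`.
#' @param buffer_total Total buffer concentration (mM); 0 for unbuffered.
#' @param buffer_pka1,buffer_pka2 Buffer pKa values (NA when unbuffered).
#' @param bile_salt Sodium-taurocholate-equivalent concentration (mM).
#' @param solubility Apparent drug solubility in the medium (mg/mL), > 0.
#' @return An object of class `medium`.
#' @export
medium <- function(name, pH, buffer_total = 0, buffer_pka1 = NA_real_,
                   buffer_pka2 = NA_real_, bile_salt = 0, solubility) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- structure(
    list(name = name, pH = as.numeric(pH),
         buffer_total = as.numeric(buffer_total),
         buffer_pka1 = as.numeric(buffer_pka1),
         buffer_pka2 = as.numeric(buffer_pka2),
         bile_salt = as.numeric(bile_salt),
         solubility = as.numeric(solubility)),
    class = "medium")
  viol <- validate_medium(m)
  if (length(viol)) stop("invalid medium '", name, "': ",
                         paste(viol, collapse = "; "))
  m
}

validate_medium <- function(m) {
  v <- character(0)
  if (!is.finite(m$pH) || m$pH < 1 || m$pH > 9)
    v <- c(v, sprintf("pH: %s outside [1, 9]", format(m$pH)))
  if (!is.finite(m$buffer_total) || m$buffer_total < 0)
    v <- c(v, "buffer_total: must be >= 0")
  if (!is.finite(m$bile_salt) || m$bile_salt < 0)
    v <- c(v, "bile_salt: must be >= 0")
  if (!is.finite(m$solubility) || m$solubility <= 0)
    v <- c(v, "solubility: must be > 0")
  v
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> %s  pH %.2f  buffer %.1f mM  bile %.2f mM  Cs %.4g mg/mL\n",
              x$name, x$pH, x$buffer_total, x$bile_salt, x$solubility))
  invisible(x)
}

#' Default biorelevant media set
#'
#' The five fasted-state media of the sequential flow-through protocol.
#' The three lower-intestinal media (FaSSIF-V2 midgut, SIF Ileum-V2, FaSSCoF)
#' use a maleate buffer (pKa 1.83 and 5.99) with totals 19.3, 52.8 and
#' 75.8 mM, pH 6.8, 7.5 and 7.8 and taurocholate 1.5, 0.8 and 0 mM.  FaSSGF
#' and FaSSIF-V2 carry the standard Level II/III biorelevant compositions
#' (pH 1.6 with 0.08 mM bile; pH 6.5 with 3 mM taurocholate on a 19.1 mM
#' maleate buffer).  Drug solubilities are illustrative amorphous apparent
#' values for a tacrolimus-like compound and are meant to be replaced by
#' measured values through the configuration file.
#'
#' @param solubility Named numeric vector of per-medium drug solubility
#'   (mg/mL) overriding the illustrative defaults; names must be medium names.
#' @return Named list of five [medium] objects in protocol order.
#' @export
default_media <- function(solubility = NULL) {
  sol <- c("FaSSGF" = 0.025, "FaSSIF-V2" = 0.05, "FaSSIF-V2 midgut" = 0.045,
           "SIF Ileum-V2" = 0.035, "FaSSCoF" = 0.02)
  if (!is.null(solubility)) {
    bad <- setdiff(names(solubility), names(sol))
    if (length(bad)) stop("unknown medium in solubility override: ",
                          paste(bad, collapse = ", "))
    sol[names(solubility)] <- solubility
  }
  media <- list(
    medium("FaSSGF", pH = 1.6, buffer_total = 0, bile_salt = 0.08,
           solubility = sol[["FaSSGF"]]),
    medium("FaSSIF-V2", pH = 6.5, buffer_total = 19.1, buffer_pka1 = 1.83,
           buffer_pka2 = 5.99, bile_salt = 3.0, solubility = sol[["FaSSIF-V2"]]),
    medium("FaSSIF-V2 midgut", pH = 6.8, buffer_total = 19.3,
           buffer_pka1 = 1.83, buffer_pka2 = 5.99, bile_salt = 1.5,
           solubility = sol[["FaSSIF-V2 midgut"]]),
    medium("SIF Ileum-V2", pH = 7.5, buffer_total = 52.8, buffer_pka1 = 1.83,
           buffer_pka2 = 5.99, bile_salt = 0.8, solubility = sol[["SIF Ileum-V2"]]),
    medium("FaSSCoF", pH = 7.8, buffer_total = 75.8, buffer_pka1 = 1.83,
           buffer_pka2 = 5.99, bile_salt = 0, solubility = sol[["FaSSCoF"]]))
  names(media) <- vapply(media, `[[`, "", "name")
  media
}

#' GI region names of the nine-compartment absorption model
#' @return Character vector of the 9 region names in anatomical order.
#' @export
gi_region_names <- function() {
  c("Stomach", "Duodenum", "Jejunum I", "Jejunum II",
    "Ileum I", "Ileum II", "Ileum III", "Ileum IV", "Colon")
}

#' Map each protocol medium to the GI regions it represents
#'
#' The gastric medium informs the Stomach scalar, FaSSIF-V2 the Duodenum,
#' the midgut medium both Jejunum segments, the distal-ileal medium all four
#' Ileum segments, and the colonic medium the Colon.
#'
#' @return Named list: medium name -> character vector of region names.
#' @export
default_region_map <- function() {
  list("FaSSGF" = "Stomach",
       "FaSSIF-V2" = "Duodenum",
       "FaSSIF-V2 midgut" = c("Jejunum I", "Jejunum II"),
       "SIF Ileum-V2" = c("Ileum I", "Ileum II", "Ileum III", "Ileum IV"),
       "FaSSCoF" = "Colon")
}

#' Sequential open-loop dissolution protocol
#'
#' @param segments `data.frame` with columns `medium` (name), `start` (min),
#'   `duration` (min) and `flow_rate` (mL/min), ordered and tiling time
#'   contiguously from 0.
#' @param media Named list of [medium] objects covering every segment medium.
#' @param cell_volume Working volume of the flow-through cell (mL).
#' @param region_map Named list mapping each medium to the GI regions whose
#'   dissolution scalar it informs; must cover all 9 regions.
#' @return Object of class `dissolution_protocol`.
#' @export
dissolution_protocol <- function(segments, media, cell_volume = 20,
                                 region_map = default_region_map()) {
  p <- structure(
    list(segments = as.data.frame(segments), media = media,
         cell_volume = as.numeric(cell_volume), region_map = region_map),
    class = "dissolution_protocol")
  p
}

#' Build the default five-media flow-through protocol
#'
#' Gastric medium for 30 min at 8 mL/min, then four intestinal/colonic media
#' at 4 mL/min for 40, 80, 60 and 150 min, ending at 360 min (6 h).
#'
#' @inheritParams default_media
#' @param cell_volume Flow-through cell volume (mL), default 20.
#' @return A validated `dissolution_protocol`.
#' @export
#' @examples
#' p <- build_default_protocol()
#' p$segments
#' protocol_end(p)  # 360 min
build_default_protocol <- function(solubility = NULL, cell_volume = 20) {
  media <- default_media(solubility)
  seg <- data.frame(
    medium = names(media),
    start = c(0, 30, 70, 150, 210),
    duration = c(30, 40, 80, 60, 150),
    flow_rate = c(8, 4, 4, 4, 4),
    stringsAsFactors = FALSE)
  p <- dissolution_protocol(seg, media, cell_volume = cell_volume)
  viol <- validate_protocol(p)
  if (length(viol)) stop("default protocol invalid: ",
                         paste(viol, collapse = "; "))
  p
}

#' Protocol end time (min)
#' @param protocol A `dissolution_protocol`.
#' @export
protocol_end <- function(protocol) {
  s <- protocol$segments
  s$start[nrow(s)] + s$duration[nrow(s)]
}

#' Medium active at a given time
#'
#' Segments are half-open intervals `[start, start + duration)`, so at a
#' switch time the incoming medium applies; at exactly the protocol end the
#' last medium is returned.
#'
#' @param protocol A `dissolution_protocol`.
#' @param t Time (min) with `0 <= t <= protocol_end(protocol)`.
#' @return The active [medium].
#' @export
medium_at <- function(protocol, t) {
  s <- protocol$segments
  end <- protocol_end(protocol)
  if (!is.finite(t) || t < s$start[1] || t > end)
    stop(sprintf("time %s outside protocol span [%s, %s]",
                 format(t), format(s$start[1]), format(end)))
  i <- findInterval(t, s$start)   # half-open [start, next start)
  if (t >= end) i <- nrow(s)
  protocol$media[[s$medium[i]]]
}

#' Validate a dissolution protocol
#'
#' Checks segment positivity and contiguity, the first-segment start, medium
#' coverage, per-medium invariants and that the region map covers all nine
#' GI compartments.  Violations are returned as data, not thrown.
#'
#' @param protocol A `dissolution_protocol`.
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_protocol <- function(protocol) {
  v <- character(0)
  s <- protocol$segments
  need <- c("medium", "start", "duration", "flow_rate")
  if (!all(need %in% names(s)))
    return(sprintf("segments: missing column(s) %s",
                   paste(setdiff(need, names(s)), collapse = ", ")))
  if (nrow(s) == 0) return("segments: empty")
  if (s$start[1] != 0) v <- c(v, "segment 1: start must be 0")
  for (i in seq_len(nrow(s))) {
    if (!is.finite(s$duration[i]) || s$duration[i] <= 0)
      v <- c(v, sprintf("segment %d: duration must be > 0", i))
    if (!is.finite(s$flow_rate[i]) || s$flow_rate[i] <= 0)
      v <- c(v, sprintf("segment %d: flow_rate must be > 0", i))
    if (i > 1) {
      gap <- s$start[i] - (s$start[i - 1] + s$duration[i - 1])
      if (gap > 1e-9) v <- c(v, sprintf("segment %d: gap before segment", i))
      if (gap < -1e-9) v <- c(v, sprintf("segment %d: overlap with segment %d", i, i - 1))
    }
    if (!s$medium[i] %in% names(protocol$media))
      v <- c(v, sprintf("segment %d: unknown medium '%s'", i, s$medium[i]))
  }
  if (!is.finite(protocol$cell_volume) || protocol$cell_volume <= 0)
    v <- c(v, "cell_volume: must be > 0")
  for (m in protocol$media) {
    mv <- validate_medium(m)
    if (length(mv)) v <- c(v, paste0("medium ", m$name, ": ", mv))
  }
  covered <- unlist(protocol$region_map, use.names = FALSE)
  missing <- setdiff(gi_region_names(), covered)
  if (length(missing))
    v <- c(v, sprintf("region_map: uncovered region(s) %s",
                      paste(missing, collapse = ", ")))
  v
}

#' @export
print.dissolution_protocol <- function(x, ...) {
  cat(sprintf("<dissolution_protocol> %d segments, cell %.1f mL, span [0, %g] min\n",
              nrow(x$segments), x$cell_volume, protocol_end(x)))
  print(x$segments)
  invisible(x)
}
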