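# shared fixtures: everything is built in code, nothing read from disk

default_fixture <- function() {
  protocol <- build_default_protocol()
  list(protocol = protocol,
       form = formulation(),
       disp = compound_disposition(),
       regions = gi_regions(protocol))
}

# slow, all-media-estimable scalar set (reference-product-like)
slow_scalars <- function(protocol = build_default_protocol()) {
  stats::setNames(c(0.05, 0.04, 0.03, 0.02, 0.015), protocol$segments$medium)
}

# modified-release DLM parameterisation used for in vivo recovery studies:
# enough solid reaches the distal bowel for ileal/colonic scalars to be
# informative in the PK data
recovery_region_scalars <- function() {
  stats::setNames(c(rep(0.02, 4), rep(0.05, 4), 0.5), gi_region_names())
}

coarse_grid <- seq(0, 144, by = 0.5)
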