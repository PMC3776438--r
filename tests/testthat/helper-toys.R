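# Closed-form FBA optimum of a toy species under uptake caps.
#
# With both sugars sharing the same fermentative/respiratory yields, the LP
# allocates the oxygen budget to respiration first (higher ATP), ferments
# the remaining substrate, and grows on what exceeds maintenance:
#   r   = min(u_g + u_z, u_o / o2_per_resp)
#   ATP = atp_resp * r + atp_ferm * (u_g + u_z - r) - maintenance
#   mu  = ATP / atp_per_biomass   (infeasible when ATP < 0)
# Valid for configs where glucose and xylose routes have identical yields
# and ethanol uptake is disabled.
toy_closed_form <- function(cfg, u_g = 0, u_z = 0, u_o = 0) {
  stopifnot(cfg$atp_per_glc_ferm == cfg$atp_per_xyl_ferm,
            cfg$atp_per_glc_resp == cfg$atp_per_xyl_resp,
            cfg$o2_per_glc_resp == cfg$o2_per_xyl_resp)
  if (!("xylose" %in% cfg$substrates)) u_z <- 0
  if (!("glucose" %in% cfg$substrates)) u_g <- 0
  u <- u_g + u_z
  r <- if (cfg$respiration) min(u, u_o / cfg$o2_per_glc_resp) else 0
  atp <- cfg$atp_per_glc_resp * r + cfg$atp_per_glc_ferm * (u - r) -
    cfg$maintenance
  if (atp < 0) return(list(status = "infeasible", mu = NA_real_))
  list(status = "optimal",
       mu = atp / cfg$atp_per_biomass,
       ethanol = cfg$eth_per_glc_ferm * (u - r),
       oxygen = -cfg$o2_per_glc_resp * r)
}

# random toy configuration drawing integer-friendly yields (seeded by
# caller); equal_sugar_yields makes both sugar routes identical so
# toy_closed_form applies
random_toy_config <- function(equal_sugar_yields = FALSE) {
  subs <- sample(list("glucose", c("glucose", "xylose")), 1)[[1]]
  ferm <- sample(1:3, 1)
  resp <- ferm + sample(8:24, 1)
  o2 <- sample(4:8, 1)
  xf <- if (equal_sugar_yields) ferm else sample(1:3, 1)
  xr <- if (equal_sugar_yields) resp else xf + sample(8:24, 1)
  xo <- if (equal_sugar_yields) o2 else sample(4:8, 1)
  toy_network_config(
    substrates = subs,
    atp_per_glc_ferm = ferm, atp_per_glc_resp = resp, o2_per_glc_resp = o2,
    eth_per_glc_ferm = if (equal_sugar_yields) 2 else sample(1:3, 1),
    atp_per_xyl_ferm = xf, atp_per_xyl_resp = xr, o2_per_xyl_resp = xo,
    eth_per_xyl_ferm = 2,
    maintenance = round(runif(1, 0, 2), 3))
}

random_caps <- function(cfg) {
  caps <- c(glucose = round(runif(1, 0, 12), 3),
            xylose = round(runif(1, 0, 8), 3),
            oxygen = round(runif(1, 0, 10), 3))
  if (!("xylose" %in% cfg$substrates)) caps <- caps[c("glucose", "oxygen")]
  caps
}

# standard two-member community and paper-magnitude batch conditions
toy_study_models <- function(...) make_toy_community(...)

toy_study_conditions <- function(X_c0 = 0.1, X_s0 = 0.9, G0 = 16, Z0 = 8,
                                 kLa = 10.1, t_end = 40, ...) {
  batch_conditions(
    initial = culture_state(X = c(cerevisiae = X_c0, stipitis = X_s0),
                            G = G0, Z = Z0, E = 0, O = 0.24),
    kLa = kLa, t_end = t_end, ...)
}
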