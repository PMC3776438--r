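#' Bundle a network with its uptake kinetics
#'
#' A species model is the unit the dynamic layer works with: a
#' [metabolic_network()], the [uptake_params()] that bound its exchange
#' fluxes, and an optional knockout set applied immediately (the stored
#' network already has the listed reactions blocked).
#'
#' @param network a [metabolic_network()].
#' @param uptake an [uptake_params()].
#' @param knockouts reaction ids to constrain to zero.
#' @param species label override (defaults to the network's).
#' @return an object of class `species_model`.
#' @export
species_model <- function(network, uptake, knockouts = character(),
                          species = network$species) {
  stopifnot(inherits(network, "metabolic_network"),
            inherits(uptake, "uptake_params"))
  network$species <- species
  structure(list(network = apply_knockouts(network, knockouts),
                 uptake = uptake, knockouts = knockouts,
                 species = species),
            class = "species_model")
}

#' Extracellular culture state
#'
#' @param X named numeric vector of biomass concentrations (gdw/L), one
#'   entry per species.
#' @param G,Z,E glucose, xylose, ethanol concentrations (g/L).
#' @param O dissolved oxygen (mM); defaults to the saturation value 0.24.
#' @param t time stamp (h).
#' @return object of class `culture_state`.
#' @export
culture_state <- function(X, G, Z = 0, E = 0, O = 0.24, t = 0) {
  if (is.null(names(X)) && length(X) > 0)
    stop("biomass vector X must be named by species")
  if (any(c(X, G, Z, E, O) < 0)) stop("concentrations must be nonnegative")
  structure(list(t = t, X = X, G = G, Z = Z, E = E, O = O),
            class = "culture_state")
}

#' Batch operating conditions
#'
#' @param initial a [culture_state()] at inoculation. The default initial
#'   dissolved oxygen is the saturation value (media saturated at
#'   inoculation); override `initial$O` for pre-sparged media.
#' @param kLa volumetric oxygen transfer coefficient (1/h); values above
#'   the validated microaerobic envelope (10.1 1/h) trigger a warning in
#'   [simulate_batch()] because ethanol reassimilation is not modeled.
#' @param O_star oxygen saturation concentration (mM); 0.24 mM is water at
#'   30 C and 1 atm.
#' @param t_end simulation horizon (h).
#' @param context `"co_culture"` or `"pure_culture"`; controls the
#'   proactive ATP-maintenance toggle (see [maintenance_toggle()]).
#' @param molar_masses g/mmol for glucose, xylose, ethanol, used to convert
#'   mmol-based exchange fluxes to the g/L balances.
#' @param glucose_depletion_threshold glucose level (g/L) below which the
#'   maintenance toggle engages.
#' @param output_dt reporting grid spacing (h).
#' @return object of class `batch_conditions`.
#' @export
batch_conditions <- function(initial, kLa, O_star = 0.24, t_end = 40,
                             context = c("co_culture", "pure_culture"),
                             molar_masses = c(glucose = 0.18016,
                                              xylose = 0.15013,
                                              ethanol = 0.04607),
                             glucose_depletion_threshold = 1e-6,
                             output_dt = 0.1) {
  stopifnot(inherits(initial, "culture_state"), kLa >= 0, O_star > 0,
            t_end > 0, output_dt > 0)
  context <- match.arg(context)
  structure(list(initial = initial, kLa = kLa, O_star = O_star,
                 t_end = t_end, context = context,
                 molar_masses = molar_masses,
                 glucose_depletion_threshold = glucose_depletion_threshold,
                 output_dt = output_dt),
            class = "batch_conditions")
}

#' Oxygen transfer coefficient from the gas sparge rate
#'
#' Linear calibration through the two measured sparge points
#' (25 cc/min -> 5.5 1/h, 50 cc/min -> 10.1 1/h).
#'
#' @param q gas sparge rate (cc/min), nonnegative.
#' @return kLa (1/h).
#' @examples
#' kla_from_sparge(c(25, 37.5, 50))
#' @export
kla_from_sparge <- function(q) {
  if (any(q < 0)) stop("sparge rate must be nonnegative")
  slope <- (10.1 - 5.5) / (50 - 25)
  5.5 + slope * (q - 25)
}

#' Maintenance-toggle bound overrides
#'
#' After glucose depletion a glucose-only organism (the respiratory
#' deficient *S. cerevisiae* member) cannot meet its non-growth-associated
#' ATP maintenance demand, which would make the whole community LP
#' infeasible and zero out the co-partner's fluxes. The toggle relaxes the
#' maintenance lower bound of the affected members to zero.
#'
#' @param models list of [species_model()]s.
#' @param members species labels to toggle; `NULL` selects the members
#'   without xylose uptake capability (glucose-only organisms).
#' @return named list of combined-reaction-id lower-bound overrides, in the
#'   form [solve_community_fba()]'s `bound_overrides` expects.
#' @export
maintenance_toggle <- function(models, members = NULL) {
  if (is.null(members))
    members <- names(models)[vapply(models, function(m)
      is.na(m$uptake$v_z_max), logical(1))]
  lower <- list()
  for (sp in members) {
    mid <- models[[sp]]$network$maintenance_id
    if (!is.null(mid)) lower[[paste(sp, mid, sep = ".")]] <- 0
  }
  list(lower = unlist(lower))
}

# Solve the community LP at one culture state, applying the maintenance
# toggle proactively (co-culture, glucose depleted) and reactively (on
# infeasibility). Returns a flux_solution; status "starved" marks the
# all-zero fallback.
.solve_at_state <- function(comm, models, state, cond, pfba = TRUE,
                            ignore_glucose_inhibition = FALSE,
                            toggle = NULL) {
  s <- c(G = max(state[["G"]], 0), Z = max(state[["Z"]], 0),
         E = max(state[["E"]], 0), O = max(state[["O"]], 0))
  caps <- lapply(models, function(m)
    uptake_caps(s, m$uptake, ignore_glucose_inhibition))
  if (is.null(toggle)) toggle <- maintenance_toggle(models)
  proactive <- cond$context == "co_culture" &&
    s[["G"]] < cond$glucose_depletion_threshold
  ov <- if (proactive) toggle else NULL
  sol <- solve_community_fba(comm, caps, pfba = pfba,
                             bound_overrides = ov)
  if (sol$status != "optimal" && !proactive) {
    sol <- solve_community_fba(comm, caps, pfba = pfba,
                               bound_overrides = toggle)
  }
  if (sol$status != "optimal") {
    # relax every member's maintenance before giving up
    all_tog <- maintenance_toggle(models, members = names(models))
    sol <- solve_community_fba(comm, caps, pfba = pfba,
                               bound_overrides = all_tog)
  }
  if (sol$status != "optimal") {
    zero <- setNames(rep(0, 4), c("glucose", "xylose", "ethanol", "oxygen"))
    sol <- structure(list(
      status = "starved",
      objective = 0,
      growth_rates = setNames(rep(0, length(models)), names(models)),
      exchange_fluxes = setNames(rep(list(zero), length(models)),
                                 names(models)),
      fluxes = NULL, residual = 0), class = "flux_solution")
  }
  sol
}

#' Time derivatives of the extracellular balances
#'
#' Evaluates the right-hand side of the batch model at one state: solves
#' the community LP under the kinetic uptake caps, then forms
#' `dX_i = mu_i X_i`, the sugar and ethanol balances (converted from
#' mmol-based fluxes by molar mass), and the dissolved-oxygen balance
#' `dO = sum(v_o_i X_i) + kLa (O* - O)` with uptake fluxes negative.
#'
#' @param state named numeric `c(X.<species>..., G, Z, E, O)`.
#' @param models list of [species_model()]s.
#' @param cond a [batch_conditions()].
#' @param comm optional prebuilt community (performance).
#' @param ... passed to the internal LP step (e.g. `pfba`,
#'   `ignore_glucose_inhibition`).
#' @return list: `derivatives` (same layout as `state`) and `solution`
#'   (the `flux_solution` used).
#' @export
dfba_rhs <- function(state, models, cond, comm = NULL, ...) {
  if (is.null(comm))
    comm <- combine_networks(lapply(models, `[[`, "network"))
  sp <- names(models)
  X <- pmax(state[paste0("X.", sp)], 0)
  sol <- .solve_at_state(comm, models, state, cond, ...)
  mm <- cond$molar_masses
  dX <- sol$growth_rates * X
  ex <- sol$exchange_fluxes
  sum_ex <- function(what)
    sum(vapply(sp, function(s2) ex[[s2]][[what]], numeric(1)) * X)
  dG <- mm[["glucose"]] * sum_ex("glucose")
  dZ <- mm[["xylose"]] * sum_ex("xylose")
  dE <- mm[["ethanol"]] * sum_ex("ethanol")
  dO <- sum_ex("oxygen") + cond$kLa * (cond$O_star - max(state[["O"]], 0))
  d <- c(setNames(dX, paste0("X.", sp)), G = dG, Z = dZ, E = dE, O = dO)
  # do not push nonnegative quantities below zero
  low <- state <= 0 & d < 0
  d[low] <- 0
  list(derivatives = d, solution = sol)
}

#' Simulate a batch fermentation by dynamic flux balance analysis
#'
#' Integrates the extracellular balances with the community flux balance
#' LP embedded in the right-hand side, using a stiff adaptive method
#' (`deSolve`; the oxygen balance makes the system stiff at microaerobic
#' quasi-steady state). Concentrations are clamped at zero, the
#' ATP-maintenance toggle engages after glucose depletion, and the result
#' is reported on a uniform output grid together with substrate-depletion
#' events and batch performance metrics.
#'
#' @param models list of [species_model()]s (named by species).
#' @param cond a [batch_conditions()].
#' @param pfba run the parsimonious secondary LP at each evaluation
#'   (default `TRUE`).
#' @param ignore_glucose_inhibition drop the diauxic glucose-inhibition
#'   factor from xylose uptake (transporter-engineering scenario).
#' @param method,rtol,atol integrator settings (stiff `"lsoda"` default).
#' @param flux_trace recompute and store the flux solution on the output
#'   grid (default `TRUE`).
#' @param xylose_cutoff batch-end xylose threshold (g/L) for the metrics.
#' @return a `simulation_result`: `trajectory` (data.frame with columns
#'   `time_h`, one `X_<species>_gdw_L` per member, `glucose_g_L`,
#'   `xylose_g_L`, `ethanol_g_L`, `DO_mM`), `events` (depletion times),
#'   `metrics` (see [batch_metrics()]), `flux_trace`, and the inputs.
#' @export
simulate_batch <- function(models, cond, pfba = TRUE,
                           ignore_glucose_inhibition = FALSE,
                           method = "lsoda", rtol = 1e-6, atol = 1e-8,
                           flux_trace = TRUE, xylose_cutoff = 0.5) {
  stopifnot(inherits(cond, "batch_conditions"))
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, character(1), "species")
  if (cond$kLa > 10.1 + 1e-9)
    warning("kLa above the validated microaerobic envelope (10.1 1/h); ",
            "ethanol reassimilation is not modeled", call. = FALSE)
  comm <- combine_networks(lapply(models, `[[`, "network"))
  toggle <- maintenance_toggle(models)
  sp <- names(models)
  init <- cond$initial
  X0 <- setNames(rep(0, length(sp)), sp)
  X0[names(init$X)] <- init$X
  y0 <- c(setNames(X0, paste0("X.", sp)),
          G = init$G, Z = init$Z, E = init$E, O = init$O)
  func <- function(t, y, parms) {
    d <- dfba_rhs(y, models, cond, comm = comm, pfba = pfba,
                  ignore_glucose_inhibition = ignore_glucose_inhibition,
                  toggle = toggle)$derivatives
    list(d)
  }
  times <- seq(0, cond$t_end, by = cond$output_dt)
  out <- deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("integrator failed near t = ", max(out[, "time"]),
         " h; last state: ",
         paste(sprintf("%s=%.4g", colnames(out)[-1],
                       out[nrow(out), -1]), collapse = ", "))
  traj <- as.data.frame(out)
  names(traj)[1] <- "time_h"
  for (cn in names(traj)[-1]) traj[[cn]] <- pmax(traj[[cn]], 0)
  names(traj) <- c("time_h", paste0("X_", sp, "_gdw_L"),
                   "glucose_g_L", "xylose_g_L", "ethanol_g_L", "DO_mM")

  cross_down <- function(tt, vv, thr) {
    below <- which(vv < thr)
    if (!length(below)) return(NA_real_)
    k <- below[1]
    if (k == 1) return(tt[1])
    # linear interpolation on the bracketing (descending) segment
    tt[k - 1] + (tt[k] - tt[k - 1]) * (vv[k - 1] - thr) /
      (vv[k - 1] - vv[k])
  }
  events <- list(
    glucose_depletion_h = cross_down(traj$time_h, traj$glucose_g_L,
                                     max(cond$glucose_depletion_threshold,
                                         1e-3)),
    xylose_depletion_h = cross_down(traj$time_h, traj$xylose_g_L,
                                    xylose_cutoff))

  ft <- NULL
  if (flux_trace) {
    ft <- lapply(seq_len(nrow(out)), function(i)
      .solve_at_state(comm, models, setNames(as.numeric(out[i, -1]),
                                             names(y0)),
                      cond, pfba = pfba,
                      ignore_glucose_inhibition = ignore_glucose_inhibition,
                      toggle = toggle))
  }
  res <- structure(list(trajectory = traj, events = events,
                        flux_trace = ft, models = models, cond = cond),
                   class = "simulation_result")
  res$metrics <- batch_metrics(res, xylose_cutoff = xylose_cutoff)
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<simulation_result: %d points over %.1f h>\n", nrow(tr),
              max(tr$time_h)))
  m <- x$metrics
  if (isTRUE(m$defined))
    cat(sprintf("  titer %.3f g/L at batch time %.2f h (productivity %.3f g/L/h)\n",
                m$titer_g_L, m$batch_time_h, m$productivity_g_L_h))
  else cat("  batch metrics undefined (xylose cutoff not crossed)\n")
  invisible(x)
}

#' Batch performance metrics from a simulated trajectory
#'
#' The batch ends when xylose first drops below the cutoff (linearly
#' interpolated between reporting points); the titer is the ethanol
#' concentration at that moment and the productivity is titer divided by
#' batch time. When the cutoff is never crossed, or is crossed at time
#' zero, the metrics are flagged undefined rather than raising an error,
#' so design-point optimizers can penalize such runs.
#'
#' @param result a `simulation_result` (or anything with a `trajectory`
#'   data.frame with columns `time_h`, `xylose_g_L`, `ethanol_g_L`).
#' @param xylose_cutoff batch-end threshold (g/L), 0.5 by default.
#' @return list with `batch_time_h`, `titer_g_L`, `productivity_g_L_h`,
#'   `defined`.
#' @export
batch_metrics <- function(result, xylose_cutoff = 0.5) {
  traj <- result$trajectory
  stopifnot(nrow(traj) >= 1)
  tt <- traj$time_h; zz <- traj$xylose_g_L
  below <- which(zz < xylose_cutoff)
  if (!length(below))
    return(list(batch_time_h = NA_real_, titer_g_L = NA_real_,
                productivity_g_L_h = NA_real_, defined = FALSE))
  k <- below[1]
  if (k == 1) {
    bt <- tt[1]
  } else {
    bt <- tt[k - 1] + (tt[k] - tt[k - 1]) * (zz[k - 1] - xylose_cutoff) /
      (zz[k - 1] - zz[k])
  }
  titer <- approx(tt, traj$ethanol_g_L, xout = bt, ties = "ordered")$y
  prod <- if (bt > 0) titer / bt else NA_real_
  list(batch_time_h = bt, titer_g_L = titer, productivity_g_L_h = prod,
       defined = is.finite(prod))
}
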