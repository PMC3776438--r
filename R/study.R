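#' Inoculum / aeration design grid
#'
#' Enumerates batch design points sharing the sugar loading and a fixed
#' total inoculum: the first-species inoculum fraction runs over
#' `seq(0, 1, by = step)` (endpoints trimmed by `fraction_range`) for each
#' kLa value.
#'
#' @param total total inoculum concentration (gdw/L).
#' @param step inoculum fraction step.
#' @param kLa aeration levels (1/h) to scan.
#' @param G0,Z0 initial glucose and xylose (g/L).
#' @param fraction_range inclusive limits for the first-species fraction.
#' @param fractions explicit fraction values (overrides `step`).
#' @return data.frame with columns `X_c0`, `X_s0`, `kLa`, `G0`, `Z0`.
#' @export
inoculum_design_grid <- function(total = 1.0, step = 0.05, kLa = 10.1,
                                 G0 = 16, Z0 = 8,
                                 fraction_range = c(0, 1),
                                 fractions = NULL) {
  f <- if (is.null(fractions)) seq(0, 1, by = step) else fractions
  f <- f[f >= fraction_range[1] - 1e-12 & f <= fraction_range[2] + 1e-12]
  if (!length(f)) stop("no inoculum fractions selected")
  grid <- expand.grid(frac = f, kLa = kLa)
  data.frame(X_c0 = round(grid$frac * total, 10),
             X_s0 = round((1 - grid$frac) * total, 10),
             kLa = grid$kLa, G0 = G0, Z0 = Z0)
}

# simulate one design point; models are named (first = "cerevisiae-like")
.simulate_design <- function(models, point, O_star = 0.24, t_end = 60,
                             context = "co_culture", xylose_cutoff = 0.5,
                             ...) {
  sp <- names(models)
  X0 <- setNames(c(point$X_c0, point$X_s0), sp[1:2])
  cond <- batch_conditions(
    initial = culture_state(X = X0, G = point$G0, Z = point$Z0, E = 0,
                            O = O_star),
    kLa = point$kLa, O_star = O_star, t_end = t_end, context = context)
  simulate_batch(models, cond, xylose_cutoff = xylose_cutoff,
                 flux_trace = FALSE, ...)
}

#' Grid optimization of batch ethanol productivity
#'
#' Simulates every design point, computes the batch metrics, and returns
#' the point with the largest ethanol productivity. Points whose
#' productivity is undefined (xylose cutoff never crossed within the
#' horizon) are excluded; ties break toward the smallest first-species
#' inoculum. Errors if every point is undefined.
#'
#' @param models list of two [species_model()]s (first species plays the
#'   `X_c0` role).
#' @param grid a design grid from [inoculum_design_grid()].
#' @param O_star oxygen saturation (mM).
#' @param t_end simulation horizon (h).
#' @param context culture context.
#' @param xylose_cutoff batch-end threshold (g/L).
#' @param ... passed to [simulate_batch()].
#' @return list with `best` (one-row data.frame) and `table` (the full
#'   response grid with `titer_g_L`, `batch_time_h`, `productivity_g_L_h`,
#'   `defined`).
#' @export
optimize_inoculum <- function(models, grid, O_star = 0.24, t_end = 60,
                              context = "co_culture", xylose_cutoff = 0.5,
                              ...) {
  stopifnot(nrow(grid) >= 1)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sim <- .simulate_design(models, grid[i, ], O_star = O_star,
                            t_end = t_end, context = context,
                            xylose_cutoff = xylose_cutoff, ...)
    m <- sim$metrics
    cbind(grid[i, ], titer_g_L = m$titer_g_L,
          batch_time_h = m$batch_time_h,
          productivity_g_L_h = m$productivity_g_L_h,
          defined = isTRUE(m$defined))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- tab[tab$defined, , drop = FALSE]
  if (!nrow(ok)) stop("productivity undefined at every design point")
  ord <- order(-ok$productivity_g_L_h, ok$X_c0)
  list(best = ok[ord[1], , drop = FALSE], table = tab)
}

#' Scaled sensitivity of productivity to one kinetic parameter
#'
#' Computes `S = (p/y) * (dy/dp)` by a forward difference: one simulation
#' at the nominal parameter value and one at `p * (1 + delta_rel)`, where
#' `y` is the batch ethanol productivity at the design point. A result
#' with undefined productivity at either point is flagged rather than
#' raising.
#'
#' @param models list of [species_model()]s.
#' @param base design point: list/row with `X_c0`, `X_s0`, `kLa`, `G0`,
#'   `Z0`.
#' @param param `"species.parameter"` name, e.g. `"stipitis.v_z_max"`.
#' @param delta_rel relative perturbation (e.g. `0.25` for +25%).
#' @param ... passed to the design simulations.
#' @return list of class `sensitivity_result`: `param`, `p_nominal`,
#'   `delta_p`, `y_nominal`, `y_perturbed`, `delta_y`, `S`, `defined`.
#' @export
scaled_sensitivity <- function(models, base, param, delta_rel, ...) {
  p0 <- .get_param(models, param)
  if (is.na(p0)) stop("parameter absent for this species: ", param)
  y0 <- .simulate_design(models, base, ...)$metrics$productivity_g_L_h
  dp <- p0 * delta_rel
  mods <- .set_param(models, param, p0 + dp)
  y1 <- .simulate_design(mods, base, ...)$metrics$productivity_g_L_h
  defined <- is.finite(y0) && is.finite(y1)
  S <- if (defined && dp != 0) (p0 / y0) * ((y1 - y0) / dp) else NA_real_
  structure(list(param = param, p_nominal = p0, delta_p = dp,
                 y_nominal = y0, y_perturbed = y1,
                 delta_y = if (defined) y1 - y0 else NA_real_,
                 S = S, defined = defined),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity %s: p=%.4g dp=%+.4g y=%.4g dy=%+.4g S=%.4g>\n",
              x$param, x$p_nominal, x$delta_p, x$y_nominal, x$delta_y, x$S))
  invisible(x)
}

#' Scan xylose-transporter parameters
#'
#' Wraps [scaled_sensitivity()] over a parameter set and perturbation
#' grid, producing a tidy table of productivities and scaled sensitivity
#' coefficients for the xylose transport system (maximum uptake rate,
#' saturation constant, glucose inhibition constant).
#'
#' @param models,base,... as in [scaled_sensitivity()].
#' @param params `"species.parameter"` names to scan.
#' @param deltas relative perturbations; `0` rows report the nominal
#'   productivity with `S = NA`.
#' @return data.frame with columns `param`, `delta_rel`, `p`,
#'   `productivity_g_L_h`, `S`.
#' @export
transporter_scan <- function(models, base,
                             params = c("stipitis.v_z_max", "stipitis.K_z",
                                        "stipitis.K_igz"),
                             deltas = c(-0.25, -0.1, 0.1, 0.25), ...) {
  y0 <- .simulate_design(models, base, ...)$metrics$productivity_g_L_h
  out <- list()
  for (pm in params) {
    p0 <- .get_param(models, pm)
    for (d in deltas) {
      if (d == 0) {
        out[[length(out) + 1]] <- data.frame(
          param = pm, delta_rel = 0, p = p0,
          productivity_g_L_h = y0, S = NA_real_)
        next
      }
      s <- scaled_sensitivity(models, base, pm, d, ...)
      out[[length(out) + 1]] <- data.frame(
        param = pm, delta_rel = d, p = s$p_nominal + s$delta_p,
        productivity_g_L_h = s$y_perturbed, S = s$S)
    }
  }
  do.call(rbind, out)
}

#' Productivity impact of removing diauxic glucose inhibition
#'
#' Re-simulates the design point with the glucose-inhibition factor of the
#' xylose uptake expression replaced by 1 (an idealized transporter free
#' of catabolite repression, equivalently the K_igz -> infinity limit) and
#' reports the relative productivity change.
#'
#' @param models,base,... as in [scaled_sensitivity()].
#' @return list: `y_nominal`, `y_no_inhibition`, `relative_change`
#'   (fractional; 0.85 means +85%).
#' @export
remove_glucose_inhibition_scenario <- function(models, base, ...) {
  y0 <- .simulate_design(models, base, ...)$metrics$productivity_g_L_h
  y1 <- .simulate_design(models, base, ignore_glucose_inhibition = TRUE,
                         ...)$metrics$productivity_g_L_h
  list(y_nominal = y0, y_no_inhibition = y1,
       relative_change = (y1 - y0) / y0)
}

#' Steady-state oxygen uptake deliverable at a given aeration level
#'
#' At quasi-steady dissolved oxygen, transfer `kLa (O* - O)` balances
#' consumption `v_o X` while the uptake kinetics cap `v_o` at
#' `v_o_max O / (K_o + O)`. The intersection (a quadratic in `O`) gives
#' the largest sustainable per-biomass oxygen uptake.
#'
#' @param kLa oxygen transfer coefficient (1/h).
#' @param X biomass density (gdw/L).
#' @param O_star saturation concentration (mM).
#' @param p [uptake_params()] with `v_o_max`, `K_o`.
#' @return sustainable oxygen uptake magnitude (mmol/gdw/h).
#' @export
oxygen_supply_cap <- function(kLa, X, O_star, p) {
  if (kLa <= 0 || is.na(p$v_o_max)) return(0)
  a <- kLa
  b <- p$v_o_max * X + kLa * p$K_o - kLa * O_star
  cc <- -kLa * O_star * p$K_o
  O <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  p$v_o_max * O / (p$K_o + O)
}

#' Minimum aeration level supporting growth on ethanol
#'
#' For an organism growing on ethanol as sole carbon source, finds by
#' bisection the smallest kLa at which the FBA problem remains feasible
#' with the ATP maintenance demand enforced and oxygen uptake capped by
#' the steady-state supply balance at the assumed biomass density. Below
#' the threshold respiration cannot generate the maintenance ATP, so no
#' growth on ethanol is possible.
#'
#' @param net [metabolic_network()] able to take up ethanol.
#' @param p [uptake_params()] supplying the oxygen kinetics.
#' @param biomass assumed biomass density (gdw/L); the threshold scales
#'   with it (default 1).
#' @param O_star oxygen saturation (mM).
#' @param ethanol_cap ethanol uptake magnitude offered (mmol/gdw/h).
#' @param upper bisection upper limit (1/h); an error if still infeasible
#'   there.
#' @param tol bisection tolerance on kLa (1/h).
#' @return list: `kLa_min` (1/h; 0 with a note when feasible unaerated),
#'   `biomass`, `feasible_at_upper`.
#' @export
min_kla_for_ethanol_growth <- function(net, p, biomass = 1, O_star = 0.24,
                                       ethanol_cap = 100, upper = 100,
                                       tol = 1e-3) {
  feasible <- function(kla) {
    caps <- c(glucose = 0, xylose = 0, ethanol = ethanol_cap,
              oxygen = oxygen_supply_cap(kla, biomass, O_star, p))
    solve_fba(net, caps, pfba = FALSE)$status == "optimal"
  }
  if (feasible(0))
    return(list(kLa_min = 0, biomass = biomass, feasible_at_upper = TRUE,
                note = "feasible without aeration"))
  if (!feasible(upper))
    return(list(kLa_min = NA_real_, biomass = biomass,
                feasible_at_upper = FALSE,
                note = "infeasible over the whole bisection range"))
  lo <- 0; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  list(kLa_min = hi, biomass = biomass, feasible_at_upper = TRUE)
}
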