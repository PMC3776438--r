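#' Construct a stoichiometric metabolic network
#'
#' The basic container for flux balance analysis: a metabolite-by-reaction
#' stoichiometric matrix, per-reaction flux bounds (mmol/gdw/h), biomass
#' objective weights, a map from the extracellular species tracked by the
#' batch model (glucose, xylose, ethanol, oxygen) to exchange reaction ids,
#' per-reaction compartment labels, and the id of the non-growth-associated
#' ATP maintenance reaction. Exchange fluxes follow the usual SBML sign
#' convention: uptake is negative, secretion positive.
#'
#' @param stoichiometry metabolite x reaction matrix; dimnames supply
#'   metabolite/reaction ids unless given explicitly.
#' @param lower_bounds,upper_bounds per-reaction flux bounds (mmol/gdw/h).
#' @param objective_weights per-reaction contribution to the biomass
#'   objective; the growth rate is `sum(w * v)` at the FBA optimum (1/h).
#' @param reaction_ids,metabolite_ids character identifiers; must be unique.
#' @param exchange_map named list mapping any of `"glucose"`, `"xylose"`,
#'   `"ethanol"`, `"oxygen"` to a reaction id; species the organism cannot
#'   exchange are simply absent (or `NA`).
#' @param compartments named character vector, one compartment label
#'   (`"cytoplasm"`, `"mitochondria"`, `"extracellular"`, ...) per reaction;
#'   defaults to `"cytoplasm"`.
#' @param maintenance_id reaction id of the ATP maintenance demand, or `NULL`.
#' @param species species label used when networks are combined.
#' @return an object of class `metabolic_network`.
#' @seealso [apply_knockouts()], [combine_networks()], [solve_fba()]
#' @export
metabolic_network <- function(stoichiometry, lower_bounds, upper_bounds,
                              objective_weights,
                              reaction_ids = colnames(stoichiometry),
                              metabolite_ids = rownames(stoichiometry),
                              exchange_map = list(),
                              compartments = NULL,
                              maintenance_id = NULL,
                              species = "species") {
  S <- as.matrix(stoichiometry)
  n <- ncol(S)
  if (is.null(reaction_ids)) reaction_ids <- paste0("R", seq_len(n))
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(nrow(S)))
  if (anyDuplicated(reaction_ids)) stop("duplicate reaction ids")
  if (anyDuplicated(metabolite_ids)) stop("duplicate metabolite ids")
  if (length(reaction_ids) != n || length(metabolite_ids) != nrow(S))
    stop("id lengths do not match the stoichiometric matrix")
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  lb <- rep_len(as.numeric(lower_bounds), n)
  ub <- rep_len(as.numeric(upper_bounds), n)
  w <- rep_len(as.numeric(objective_weights), n)
  if (any(lb > ub)) stop("lower_bounds must be <= upper_bounds")
  if (is.null(compartments)) {
    compartments <- setNames(rep("cytoplasm", n), reaction_ids)
  } else {
    compartments <- setNames(rep_len(as.character(compartments), n),
                             reaction_ids)
  }
  exchange_map <- exchange_map[!vapply(exchange_map, function(x)
    is.null(x) || is.na(x), logical(1))]
  bad <- setdiff(names(exchange_map), c("glucose", "xylose", "ethanol",
                                        "oxygen"))
  if (length(bad)) stop("unknown exchange species: ", paste(bad, collapse = ", "))
  for (rid in unlist(exchange_map, use.names = FALSE))
    if (!rid %in% reaction_ids)
      stop("exchange_map reaction not in network: ", rid)
  if (!is.null(maintenance_id) && !maintenance_id %in% reaction_ids)
    stop("maintenance reaction not in network: ", maintenance_id)
  structure(list(
    species = species,
    reaction_ids = reaction_ids,
    metabolite_ids = metabolite_ids,
    stoichiometry = S,
    lower_bounds = setNames(lb, reaction_ids),
    upper_bounds = setNames(ub, reaction_ids),
    objective_weights = setNames(w, reaction_ids),
    exchange_map = exchange_map,
    compartments = compartments,
    maintenance_id = maintenance_id
  ), class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network '%s': %d metabolites x %d reactions>\n",
              x$species, length(x$metabolite_ids), length(x$reaction_ids)))
  if (length(x$exchange_map))
    cat("  exchanges:", paste(names(x$exchange_map),
                              unlist(x$exchange_map), sep = "=",
                              collapse = ", "), "\n")
  if (!is.null(x$maintenance_id))
    cat("  maintenance:", x$maintenance_id, "\n")
  invisible(x)
}

#' Constrain reactions to zero flux
#'
#' Returns a copy of the network with both bounds of every listed reaction
#' set to zero, the in silico equivalent of a gene/enzyme knockout. The
#' input network is not modified.
#'
#' @param net a [metabolic_network()].
#' @param knockout_ids character vector of reaction ids (may be empty).
#' @return a `metabolic_network` with the listed reactions blocked.
#' @export
apply_knockouts <- function(net, knockout_ids) {
  stopifnot(inherits(net, "metabolic_network"))
  knockout_ids <- as.character(knockout_ids)
  unknown <- setdiff(knockout_ids, net$reaction_ids)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  net$lower_bounds[knockout_ids] <- 0
  net$upper_bounds[knockout_ids] <- 0
  net
}

#' Assemble a block-diagonal community network
#'
#' Stacks member stoichiometric matrices on the diagonal of a single
#' community matrix, so the members share no metabolites and interact only
#' through the extracellular balances of the dynamic layer. The community
#' growth objective is the sum of the members' biomass objectives.
#'
#' @param members list of [metabolic_network()] objects with unique species
#'   labels.
#' @return an object of class `community_network` with fields `members`,
#'   `stoichiometry`, `lower_bounds`, `upper_bounds`, `objective_weights`
#'   and `index` (per-member column ranges in the combined matrix).
#' @export
combine_networks <- function(members) {
  if (inherits(members, "metabolic_network")) members <- list(members)
  stopifnot(length(members) >= 1,
            all(vapply(members, inherits, logical(1), "metabolic_network")))
  labels <- vapply(members, `[[`, character(1), "species")
  if (anyDuplicated(labels)) stop("duplicate species labels")
  names(members) <- labels
  nm <- vapply(members, function(m) length(m$metabolite_ids), integer(1))
  nr <- vapply(members, function(m) length(m$reaction_ids), integer(1))
  S <- matrix(0, sum(nm), sum(nr))
  roff <- cumsum(c(0, head(nm, -1)))
  coff <- cumsum(c(0, head(nr, -1)))
  index <- vector("list", length(members))
  for (i in seq_along(members)) {
    S[roff[i] + seq_len(nm[i]), coff[i] + seq_len(nr[i])] <-
      members[[i]]$stoichiometry
    index[[i]] <- coff[i] + seq_len(nr[i])
  }
  names(index) <- labels
  rid <- unlist(lapply(members, function(m)
    paste(m$species, m$reaction_ids, sep = ".")), use.names = FALSE)
  mid <- unlist(lapply(members, function(m)
    paste(m$species, m$metabolite_ids, sep = ".")), use.names = FALSE)
  dimnames(S) <- list(mid, rid)
  structure(list(
    members = members,
    stoichiometry = S,
    lower_bounds = setNames(unlist(lapply(members, `[[`, "lower_bounds"),
                                   use.names = FALSE), rid),
    upper_bounds = setNames(unlist(lapply(members, `[[`, "upper_bounds"),
                                   use.names = FALSE), rid),
    objective_weights = setNames(unlist(lapply(members, `[[`,
                                               "objective_weights"),
                                        use.names = FALSE), rid),
    index = index
  ), class = "community_network")
}

#' @export
print.community_network <- function(x, ...) {
  cat(sprintf("<community_network: %d members, %d x %d combined>\n",
              length(x$members), nrow(x$stoichiometry),
              ncol(x$stoichiometry)))
  for (m in x$members) print(m)
  invisible(x)
}

# Apply nonnegative uptake-magnitude caps to the community lower bounds.
# uptake_bounds: list(species = c(glucose = 5, oxygen = 2, ...))
.apply_uptake_caps <- function(comm, uptake_bounds) {
  lb <- comm$lower_bounds
  ub <- comm$upper_bounds
  if (is.null(uptake_bounds)) return(list(lb = lb, ub = ub))
  for (sp in names(uptake_bounds)) {
    if (!sp %in% names(comm$members))
      stop("uptake bounds for unknown species: ", sp)
    caps <- uptake_bounds[[sp]]
    net <- comm$members[[sp]]
    for (what in names(caps)) {
      cap <- caps[[what]]
      if (is.na(cap)) next
      if (cap < 0) stop("uptake caps are nonnegative magnitudes")
      rid <- net$exchange_map[[what]]
      if (is.null(rid)) next  # species lacks this exchange: nothing to cap
      j <- comm$index[[sp]][match(rid, net$reaction_ids)]
      # cap restricts the uptake (negative) direction; secretion bound kept
      lb[j] <- max(-cap, net$lower_bounds[[rid]])
    }
  }
  list(lb = lb, ub = ub)
}

#' Solve the community flux balance linear program
#'
#' Maximizes the community growth rate, the sum of the members' biomass
#' objectives, subject to per-member steady-state stoichiometry and flux
#' bounds. Substrate uptake caps computed by the kinetic layer are applied
#' as magnitudes to the mapped exchange reactions. Because the optimum's
#' flux vector is generally degenerate, a second (parsimonious) LP
#' minimizes the total absolute flux at the fixed optimal growth rate so
#' that the exchange fluxes handed to the ODE layer are unique and
#' reproducible.
#'
#' @param comm a [combine_networks()] community (a single
#'   `metabolic_network` is promoted to a one-member community).
#' @param uptake_bounds named list (by species label) of named nonnegative
#'   magnitude caps for `glucose`, `xylose`, `ethanol`, `oxygen`.
#' @param pfba logical; run the parsimonious secondary LP (default `TRUE`).
#' @param tol solver tolerance.
#' @param bound_overrides optional named numeric vectors `lower`/`upper`
#'   (names = combined reaction ids) applied after uptake caps; used by the
#'   maintenance toggle.
#' @return a `flux_solution`: `status` (`"optimal"`/`"infeasible"`/...),
#'   `objective` (total growth rate, 1/h), and per-species entries
#'   `growth_rates`, `exchange_fluxes` (signed, uptake negative) and
#'   `fluxes`; plus `residual`, the largest steady-state violation.
#' @export
solve_community_fba <- function(comm, uptake_bounds = NULL, pfba = TRUE,
                                tol = 1e-9, bound_overrides = NULL) {
  if (inherits(comm, "metabolic_network")) comm <- combine_networks(list(comm))
  stopifnot(inherits(comm, "community_network"))
  bb <- .apply_uptake_caps(comm, uptake_bounds)
  lb <- bb$lb; ub <- bb$ub
  if (!is.null(bound_overrides)) {
    for (rid in names(bound_overrides$lower))
      lb[rid] <- bound_overrides$lower[[rid]]
    for (rid in names(bound_overrides$upper))
      ub[rid] <- bound_overrides$upper[[rid]]
  }
  S <- comm$stoichiometry
  w <- comm$objective_weights
  m <- nrow(S)
  sol <- lp_solve(w, S, rep(0, m), lb, ub, maximize = TRUE, tol = tol)
  if (sol$status != "optimal")
    return(structure(list(status = sol$status, objective = NA_real_),
                     class = "flux_solution"))
  v <- sol$x
  if (pfba) v <- .pfba_refine(S, w, lb, ub, sol$objective, v, tol)
  names(v) <- colnames(S)

  growth <- exch <- fluxes <- list()
  for (sp in names(comm$members)) {
    idx <- comm$index[[sp]]
    net <- comm$members[[sp]]
    vi <- setNames(v[idx], net$reaction_ids)
    growth[[sp]] <- sum(net$objective_weights * vi)
    ex <- vapply(c("glucose", "xylose", "ethanol", "oxygen"), function(what) {
      rid <- net$exchange_map[[what]]
      if (is.null(rid)) 0 else unname(vi[rid])
    }, numeric(1))
    exch[[sp]] <- ex
    fluxes[[sp]] <- vi
  }
  structure(list(
    status = "optimal",
    objective = sol$objective,
    growth_rates = unlist(growth),
    exchange_fluxes = exch,
    fluxes = fluxes,
    residual = max(abs(S %*% v))
  ), class = "flux_solution")
}

# Parsimonious refinement: min sum |v| at fixed community growth, via the
# split v = p - q with bound-respecting boxes for p and q.
.pfba_refine <- function(S, w, lb, ub, mu_opt, v_primal, tol) {
  n <- ncol(S)
  pl <- pmax(lb, 0); pu <- pmax(ub, 0)
  ql <- pmax(-ub, 0); qu <- pmax(-lb, 0)
  A <- rbind(cbind(S, -S), c(w, -w))
  b <- c(rep(0, nrow(S)), mu_opt)
  obj <- rep(1, 2 * n)
  sol <- lp_solve(obj, A, b, c(pl, ql), c(pu, qu), maximize = FALSE,
                  tol = tol)
  if (sol$status != "optimal") return(v_primal)  # keep the primal vertex
  sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution>", x$status, "\n")
  if (x$status == "optimal") {
    cat("  total growth rate:", format(x$objective, digits = 6), "1/h\n")
    for (sp in names(x$fluxes)) {
      ex <- x$exchange_fluxes[[sp]]
      cat(sprintf("  %s: mu=%.4g  glc=%.3g xyl=%.3g eth=%.3g o2=%.3g\n",
                  sp, x$growth_rates[[sp]], ex["glucose"], ex["xylose"],
                  ex["ethanol"], ex["oxygen"]))
    }
  }
  invisible(x)
}

#' Solve single-organism flux balance analysis
#'
#' Convenience wrapper promoting one network to a one-member community and
#' calling [solve_community_fba()]. The uptake caps are given directly as
#' a named vector.
#'
#' @param net a [metabolic_network()].
#' @param uptake_bounds named nonnegative magnitude caps
#'   (`glucose`/`xylose`/`ethanol`/`oxygen`).
#' @param ... passed to [solve_community_fba()].
#' @return a `flux_solution` (see [solve_community_fba()]).
#' @export
solve_fba <- function(net, uptake_bounds = NULL, ...) {
  ub <- if (is.null(uptake_bounds)) NULL else
    setNames(list(uptake_bounds), net$species)
  solve_community_fba(combine_networks(list(net)), uptake_bounds = ub, ...)
}
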