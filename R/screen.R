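#' Phenotype criteria for the respiratory-deficiency screen
#'
#' Direction of each phenotype measure in the mutant relative to the wild
#' type: the petite (respiratory-deficient) phenotype is a lower biomass
#' yield, a higher ethanol yield and a smaller oxygen demand, with no
#' growth on non-fermentable carbon sources.
#'
#' @param biomass_yield,ethanol_yield,oxygen_demand `"lower"` or
#'   `"higher"` relative to the wild-type reference.
#' @param growth_on_nonfermentable logical target for growth on a
#'   non-fermentable substrate (ethanol); `NA` skips the check.
#' @return object of class `phenotype_criteria`.
#' @export
phenotype_criteria <- function(biomass_yield = "lower",
                               ethanol_yield = "higher",
                               oxygen_demand = "lower",
                               growth_on_nonfermentable = FALSE) {
  dirs <- c(biomass_yield = biomass_yield, ethanol_yield = ethanol_yield,
            oxygen_demand = oxygen_demand)
  if (!all(dirs %in% c("lower", "higher")))
    stop("directions must be 'lower' or 'higher'")
  structure(list(biomass_yield = biomass_yield,
                 ethanol_yield = ethanol_yield,
                 oxygen_demand = oxygen_demand,
                 growth_on_nonfermentable = growth_on_nonfermentable),
            class = "phenotype_criteria")
}

# FBA phenotype on a fixed reference medium: biomass yield mu/|v_g|,
# ethanol yield v_e/|v_g|, oxygen demand |v_o|.
.fba_phenotype <- function(net, medium) {
  sol <- solve_fba(net, medium)
  if (sol$status != "optimal")
    return(list(feasible = FALSE))
  ex <- sol$exchange_fluxes[[net$species]]
  vg <- -ex[["glucose"]]
  list(feasible = TRUE, mu = sol$objective,
       biomass_yield = if (vg > 1e-12) sol$objective / vg else NA_real_,
       ethanol_yield = if (vg > 1e-12) ex[["ethanol"]] / vg else NA_real_,
       oxygen_demand = -ex[["oxygen"]])
}

#' Screen mitochondrial knockouts for the respiratory-deficient phenotype
#'
#' Systematically blocks mitochondrial-compartment reactions (singly and,
#' optionally, in pairs) and keeps the knockout sets whose FBA phenotype on
#' a fixed reference medium moves in the required direction for every
#' criterion: biomass yield, ethanol yield and oxygen demand relative to
#' the wild-type solution, plus (optionally) loss of growth on a
#' non-fermentable substrate. Candidates are returned in a deterministic
#' order (singles by reaction id, then pairs lexicographically).
#'
#' @param net wild-type [metabolic_network()] with compartment labels.
#' @param criteria a [phenotype_criteria()].
#' @param medium named uptake-magnitude caps defining the reference medium
#'   (must allow glucose uptake).
#' @param nonfermentable_medium caps for the growth-on-ethanol check;
#'   default: the reference medium with sugars removed and ethanol opened.
#' @param pairs also screen knockout pairs (default `TRUE`).
#' @param tol strictness tolerance for the direction comparisons.
#' @return list of candidate knockout sets (character vectors), each with
#'   attribute `"phenotype"` carrying the mutant's yields.
#' @export
screen_respiratory_knockouts <- function(net, criteria, medium,
                                         nonfermentable_medium = NULL,
                                         pairs = TRUE, tol = 1e-9) {
  stopifnot(inherits(net, "metabolic_network"),
            inherits(criteria, "phenotype_criteria"))
  mito <- names(net$compartments)[net$compartments == "mitochondria"]
  mito <- sort(mito)
  if (!length(mito)) stop("network has no mitochondrial reactions")
  ref <- .fba_phenotype(net, medium)
  if (!ref$feasible) stop("wild-type FBA infeasible on the reference medium")
  if (is.null(nonfermentable_medium)) {
    nonfermentable_medium <- medium
    nonfermentable_medium[c("glucose", "xylose")] <- 0
    nonfermentable_medium[["ethanol"]] <-
      max(medium, 10)  # ethanol freely available
  }

  cmp <- function(val, refval, direction) {
    if (is.na(val) || is.na(refval)) return(FALSE)
    if (direction == "lower") val < refval - tol else val > refval + tol
  }
  candidates <- list()
  sets <- as.list(mito)
  if (pairs && length(mito) >= 2)
    sets <- c(sets, utils::combn(mito, 2, simplify = FALSE))
  for (ko in sets) {
    mut <- apply_knockouts(net, ko)
    ph <- .fba_phenotype(mut, medium)
    if (!ph$feasible) next
    ok <- cmp(ph$biomass_yield, ref$biomass_yield, criteria$biomass_yield) &&
      cmp(ph$ethanol_yield, ref$ethanol_yield, criteria$ethanol_yield) &&
      cmp(ph$oxygen_demand, ref$oxygen_demand, criteria$oxygen_demand)
    if (ok && !is.na(criteria$growth_on_nonfermentable)) {
      nf <- .fba_phenotype(mut, nonfermentable_medium)
      grows <- nf$feasible && nf$mu > tol
      ok <- grows == criteria$growth_on_nonfermentable
    }
    if (ok) {
      attr(ko, "phenotype") <- ph
      candidates[[length(candidates) + 1]] <- ko
    }
  }
  candidates
}
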