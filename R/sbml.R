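# Minimal SBML Level 3 (+fbc version 2) reader/writer covering the subset
# this package exchanges: compartments, species, stoichiometry, flux
# bounds, and the active biomass objective. Metabolite ids are written
# with an "M_" prefix and reactions with "R_", the common convention, and
# stripped again on read so write/read round-trips are identities.

.sbml_core <- "http://www.sbml.org/sbml/level3/version1/core"
.sbml_fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.met_compartment <- function(mid) {
  if (grepl("_e$", mid)) "e" else if (grepl("_m$", mid)) "m" else "c"
}

#' Write a metabolic network to SBML
#'
#' Emits SBML L3V1 with the fbc (flux balance constraints) version 2
#' extension: flux bounds as global parameters referenced by
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound`, and the biomass objective as
#' the active `fbc:objective`. Reaction compartment labels, which core
#' SBML does not model, are carried in each reaction's notes element.
#'
#' @param net a [metabolic_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [load_sbml()]
#' @export
write_sbml <- function(net, path) {
  stopifnot(inherits(net, "metabolic_network"))
  doc <- xml2::xml_new_root(
    "sbml", xmlns = .sbml_core, "xmlns:fbc" = .sbml_fbc,
    level = "3", version = "1", "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = net$species,
                               "fbc:strict" = "false")
  comps <- unique(vapply(net$metabolite_ids, .met_compartment, character(1)))
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cp in comps)
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (mid in net$metabolite_ids)
    xml2::xml_add_child(ls, "species", id = paste0("M_", mid),
                        compartment = .met_compartment(mid),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  lp <- xml2::xml_add_child(model, "listOfParameters")
  num <- function(x) format(x, digits = 17)
  for (i in seq_along(net$reaction_ids)) {
    rid <- net$reaction_ids[i]
    xml2::xml_add_child(lp, "parameter", id = paste0("R_", rid, "_lb"),
                        value = num(net$lower_bounds[[i]]), constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0("R_", rid, "_ub"),
                        value = num(net$upper_bounds[[i]]), constant = "true")
  }
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_along(net$reaction_ids)) {
    rid <- net$reaction_ids[i]
    col <- net$stoichiometry[, i]
    rx <- xml2::xml_add_child(
      lr, "reaction", id = paste0("R_", rid),
      reversible = if (net$lower_bounds[[i]] < 0) "true" else "false",
      "fbc:lowerFluxBound" = paste0("R_", rid, "_lb"),
      "fbc:upperFluxBound" = paste0("R_", rid, "_ub"))
    notes <- xml2::xml_add_child(rx, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p",
                        paste0("compartment: ", net$compartments[[i]]))
    reac <- which(col < 0); prod <- which(col > 0)
    if (length(reac)) {
      n1 <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in reac)
        xml2::xml_add_child(n1, "speciesReference",
                            species = paste0("M_", net$metabolite_ids[k]),
                            stoichiometry = num(-col[k]), constant = "true")
    }
    if (length(prod)) {
      n2 <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in prod)
        xml2::xml_add_child(n2, "speciesReference",
                            species = paste0("M_", net$metabolite_ids[k]),
                            stoichiometry = num(col[k]), constant = "true")
    }
  }
  lo <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  for (i in which(net$objective_weights != 0))
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", net$reaction_ids[i]),
                        "fbc:coefficient" = num(net$objective_weights[[i]]))
  xml2::write_xml(doc, path)
  invisible(path)
}

# patterns matching common BiGG-style extracellular metabolite ids
.exchange_patterns <- c(glucose = "^glc", xylose = "^xyl",
                        ethanol = "^(etoh|eth)", oxygen = "^o2")

#' Load a metabolic network from SBML
#'
#' Reads the SBML subset written by [write_sbml()] (L3 + fbc flux bounds
#' and objective). The exchange map is resolved by locating single-species
#' boundary reactions on extracellular metabolites and matching the
#' metabolite identifier against standard patterns for glucose, xylose,
#' ethanol and oxygen; species with no match are simply absent from the
#' map (e.g. no xylose exchange for *S. cerevisiae*). An ambiguous match
#' (two exchange reactions for one species) is an error asking for an
#' explicit mapping.
#'
#' @param path SBML file path.
#' @param exchange_overrides named list mapping
#'   glucose/xylose/ethanol/oxygen to reaction ids, taking precedence over
#'   pattern resolution.
#' @param maintenance_id reaction id of the ATP maintenance demand;
#'   `NULL` auto-detects a reaction named `ATPM`.
#' @param species species label; defaults to the SBML model id.
#' @return a [metabolic_network()].
#' @export
load_sbml <- function(path, exchange_overrides = NULL,
                      maintenance_id = NULL, species = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = .sbml_core, fbc = .sbml_fbc)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_name(model, ns))) stop("no <model> element found")
  if (is.null(species)) {
    species <- xml2::xml_attr(model, "id")
    if (is.na(species)) species <- "model"
  }
  sp_nodes <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  met_ids <- sub("^M_", "", xml2::xml_attr(sp_nodes, "id"))
  met_comp <- setNames(xml2::xml_attr(sp_nodes, "compartment"), met_ids)
  par_nodes <- xml2::xml_find_all(model,
                                  ".//s:listOfParameters/s:parameter", ns)
  pars <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                   xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx_nodes)) stop("model has no reactions")
  rxn_ids <- sub("^R_", "", xml2::xml_attr(rx_nodes, "id"))
  S <- matrix(0, length(met_ids), length(rx_nodes),
              dimnames = list(met_ids, rxn_ids))
  lb <- ub <- numeric(length(rx_nodes))
  comp <- character(length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    rx <- rx_nodes[[i]]
    for (ref in xml2::xml_find_all(rx, "./s:listOfReactants/s:speciesReference",
                                   ns)) {
      mid <- sub("^M_", "", xml2::xml_attr(ref, "species"))
      S[mid, i] <- S[mid, i] -
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(rx, "./s:listOfProducts/s:speciesReference",
                                   ns)) {
      mid <- sub("^M_", "", xml2::xml_attr(ref, "species"))
      S[mid, i] <- S[mid, i] +
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    lbid <- xml2::xml_attr(rx, "lowerFluxBound")
    ubid <- xml2::xml_attr(rx, "upperFluxBound")
    if (is.na(lbid) || is.na(ubid) || !lbid %in% names(pars) ||
        !ubid %in% names(pars))
      stop("reaction ", rxn_ids[i], " lacks resolvable flux bounds")
    lb[i] <- pars[[lbid]]
    ub[i] <- pars[[ubid]]
    note <- xml2::xml_find_first(rx, ".//s:notes//*[local-name()='p']", ns)
    txt <- if (!inherits(note, "xml_missing")) xml2::xml_text(note) else ""
    if (grepl("compartment:", txt)) {
      comp[i] <- trimws(sub(".*compartment:\\s*", "", txt))
    } else {
      parts <- met_comp[met_ids[S[, i] != 0]]
      comp[i] <- if (any(parts == "m", na.rm = TRUE)) "mitochondria"
      else if (all(parts == "e", na.rm = TRUE)) "extracellular"
      else "cytoplasm"
    }
  }

  w <- numeric(length(rx_nodes))
  fo <- xml2::xml_find_all(model, ".//fbc:fluxObjective", ns)
  if (!length(fo)) stop("no active objective reaction found in SBML model")
  for (node in fo) {
    rid <- sub("^R_", "", xml2::xml_attr(node, "reaction"))
    w[match(rid, rxn_ids)] <- as.numeric(xml2::xml_attr(node, "coefficient"))
  }

  # exchange reactions: single participating species in compartment "e"
  ex_map <- list()
  nz <- lapply(seq_along(rxn_ids), function(i) which(S[, i] != 0))
  is_ex <- vapply(nz, function(k)
    length(k) == 1 && identical(unname(met_comp[met_ids[k]]), "e"),
    logical(1))
  for (what in names(.exchange_patterns)) {
    if (!is.null(exchange_overrides[[what]])) {
      ex_map[[what]] <- exchange_overrides[[what]]
      next
    }
    hits <- which(is_ex & vapply(nz, function(k)
      length(k) == 1 && grepl(.exchange_patterns[[what]], met_ids[k]),
      logical(1)))
    if (length(hits) > 1)
      stop("ambiguous ", what, " exchange (",
           paste(rxn_ids[hits], collapse = ", "),
           "); supply exchange_overrides")
    if (length(hits) == 1) ex_map[[what]] <- rxn_ids[hits]
  }
  if (is.null(maintenance_id) && "ATPM" %in% rxn_ids)
    maintenance_id <- "ATPM"

  metabolic_network(S, lb, ub, w, exchange_map = ex_map,
                    compartments = comp, maintenance_id = maintenance_id,
                    species = species)
}
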