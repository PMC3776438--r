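#' Configuration for a hand-solvable toy metabolic network
#'
#' Defines the stoichiometric yields of a minimal yeast-like network with a
#' Crabtree structure: a low-ATP fermentative route producing ethanol and a
#' high-ATP oxygen-consuming respiratory route, an ATP maintenance demand,
#' and a biomass reaction draining ATP. Yields are integer-friendly by
#' default so that linear-programming optima have exact closed forms. The
#' optional ethanol route is purely respiratory, so a respiratory-deficient
#' mutant cannot grow on this non-fermentable substrate.
#'
#' @param substrates subset of `c("glucose", "xylose", "ethanol")`.
#' @param respiration include the mitochondrial respiratory routes.
#' @param atp_per_glc_ferm,eth_per_glc_ferm fermentation yields per glucose.
#' @param atp_per_glc_resp,o2_per_glc_resp respiration yields per glucose.
#' @param atp_per_xyl_ferm,eth_per_xyl_ferm,atp_per_xyl_resp,o2_per_xyl_resp
#'   corresponding xylose route yields.
#' @param atp_per_eth_resp,o2_per_eth_resp respiratory ethanol route yields.
#' @param atp_per_biomass mmol ATP consumed per gdw of biomass formed; the
#'   biomass reaction flux is the growth rate (1/h).
#' @param maintenance non-growth-associated ATP demand (mmol/gdw/h),
#'   enforced as the lower bound of the maintenance reaction.
#' @param big finite stand-in for an unbounded flux (keeps the toy LP
#'   enumerable by the brute-force oracle).
#' @return a list of class `toy_network_config`.
#' @export
toy_network_config <- function(substrates = "glucose",
                               respiration = TRUE,
                               atp_per_glc_ferm = 2, eth_per_glc_ferm = 2,
                               atp_per_glc_resp = 26, o2_per_glc_resp = 6,
                               atp_per_xyl_ferm = 2, eth_per_xyl_ferm = 2,
                               atp_per_xyl_resp = 26, o2_per_xyl_resp = 6,
                               atp_per_eth_resp = 8, o2_per_eth_resp = 3,
                               atp_per_biomass = 100, maintenance = 1,
                               big = 1000) {
  substrates <- match.arg(substrates, c("glucose", "xylose", "ethanol"),
                          several.ok = TRUE)
  cfg <- as.list(environment())
  yields <- unlist(cfg[grep("^(atp|eth|o2)_per", names(cfg))])
  if (any(yields <= 0)) stop("yields must be strictly positive")
  if (atp_per_glc_ferm >= atp_per_glc_resp ||
      atp_per_xyl_ferm >= atp_per_xyl_resp)
    stop("fermentative ATP yield must be below the respiratory yield")
  if (maintenance < 0) stop("maintenance must be nonnegative")
  if ("ethanol" %in% substrates && !respiration)
    stop("an ethanol-consuming toy requires the respiratory route")
  structure(cfg, class = "toy_network_config")
}

#' Build a toy species network from a configuration
#'
#' Produces a [metabolic_network()] of at most 10 reactions whose FBA
#' optimum under any uptake caps is computable by hand: exchange reactions
#' for the configured substrates plus ethanol and oxygen, the fermentative
#' and respiratory routes of [toy_network_config()], the ATP maintenance
#' demand and the biomass drain. Respiratory reactions carry the
#' `"mitochondria"` compartment label so the knockout screen applies.
#'
#' @param cfg a [toy_network_config()].
#' @param species species label.
#' @return a `metabolic_network`.
#' @export
make_toy_species <- function(cfg = toy_network_config(), species = "toy") {
  stopifnot(inherits(cfg, "toy_network_config"))
  big <- cfg$big
  mets <- c("atp_c")
  rxn <- list()  # name -> list(stoich = named vec, lb, ub, obj, comp)
  add <- function(id, stoich, lb, ub, obj = 0, comp = "cytoplasm") {
    rxn[[id]] <<- list(stoich = stoich, lb = lb, ub = ub, obj = obj,
                       comp = comp)
    mets <<- union(mets, names(stoich))
  }
  has_eth_route <- FALSE
  if ("glucose" %in% cfg$substrates) {
    add("EX_glc", c(glc__D_e = -1), -big, 0, comp = "extracellular")
    add("GLCferm", c(glc__D_e = -1, atp_c = cfg$atp_per_glc_ferm,
                     etoh_e = cfg$eth_per_glc_ferm), 0, big)
    if (cfg$respiration)
      add("GLCresp", c(glc__D_e = -1, o2_e = -cfg$o2_per_glc_resp,
                       atp_c = cfg$atp_per_glc_resp), 0, big,
          comp = "mitochondria")
    has_eth_route <- TRUE
  }
  if ("xylose" %in% cfg$substrates) {
    add("EX_xyl", c(xyl__D_e = -1), -big, 0, comp = "extracellular")
    add("XYLferm", c(xyl__D_e = -1, atp_c = cfg$atp_per_xyl_ferm,
                     etoh_e = cfg$eth_per_xyl_ferm), 0, big)
    if (cfg$respiration)
      add("XYLresp", c(xyl__D_e = -1, o2_e = -cfg$o2_per_xyl_resp,
                       atp_c = cfg$atp_per_xyl_resp), 0, big,
          comp = "mitochondria")
    has_eth_route <- TRUE
  }
  if ("ethanol" %in% cfg$substrates) {
    if (!cfg$respiration)
      stop("an ethanol-consuming toy requires the respiratory route")
    add("ETHresp", c(etoh_e = -1, o2_e = -cfg$o2_per_eth_resp,
                     atp_c = cfg$atp_per_eth_resp), 0, big,
        comp = "mitochondria")
    has_eth_route <- TRUE
  }
  if (has_eth_route)
    add("EX_eth", c(etoh_e = -1),
        if ("ethanol" %in% cfg$substrates) -big else 0, big,
        comp = "extracellular")
  if (cfg$respiration)
    add("EX_o2", c(o2_e = -1), -big, 0, comp = "extracellular")
  add("ATPM", c(atp_c = -1), cfg$maintenance, big)
  add("BIOMASS", c(atp_c = -cfg$atp_per_biomass), 0, big, obj = 1)

  S <- matrix(0, length(mets), length(rxn),
              dimnames = list(mets, names(rxn)))
  for (id in names(rxn)) S[names(rxn[[id]]$stoich), id] <- rxn[[id]]$stoich
  ex_map <- list()
  if ("EX_glc" %in% names(rxn)) ex_map$glucose <- "EX_glc"
  if ("EX_xyl" %in% names(rxn)) ex_map$xylose <- "EX_xyl"
  if ("EX_eth" %in% names(rxn)) ex_map$ethanol <- "EX_eth"
  if ("EX_o2" %in% names(rxn)) ex_map$oxygen <- "EX_o2"
  metabolic_network(
    S,
    lower_bounds = vapply(rxn, `[[`, numeric(1), "lb"),
    upper_bounds = vapply(rxn, `[[`, numeric(1), "ub"),
    objective_weights = vapply(rxn, `[[`, numeric(1), "obj"),
    exchange_map = ex_map,
    compartments = vapply(rxn, `[[`, character(1), "comp"),
    maintenance_id = "ATPM",
    species = species)
}

#' Build the two-member toy co-culture
#'
#' A glucose-only "cerevisiae-like" member and a glucose+xylose
#' "stipitis-like" member with diauxic, ethanol-inhibited uptake kinetics
#' at the calibrated yeast magnitudes, so the synthetic co-culture
#' reproduces the study system's qualitative dynamics: fermentative
#' ethanol overflow, microaerobic diauxic sugar use, and the inability of
#' the respiratory-deficient member to meet its ATP maintenance demand
#' once glucose is gone.
#'
#' @param context `"co_culture"` (default) or `"pure_culture"`; selects the
#'   *S. cerevisiae* maximum glucose uptake rate (18.5 vs 21.5 mmol/gdw/h).
#' @param respiratory_deficient knock out the cerevisiae-like member's
#'   respiratory reaction (the petite phenotype of the study strain).
#' @param cer_cfg,stip_cfg optional [toy_network_config()] overrides.
#' @return list of two [species_model()]s named `cerevisiae`, `stipitis`.
#' @export
make_toy_community <- function(context = c("co_culture", "pure_culture"),
                               respiratory_deficient = TRUE,
                               cer_cfg = NULL, stip_cfg = NULL) {
  context <- match.arg(context)
  if (is.null(cer_cfg)) cer_cfg <- toy_network_config("glucose")
  if (is.null(stip_cfg)) stip_cfg <- toy_network_config(c("glucose", "xylose"))
  cer <- make_toy_species(cer_cfg, species = "cerevisiae")
  stip <- make_toy_species(stip_cfg, species = "stipitis")
  ko <- if (respiratory_deficient && "GLCresp" %in% cer$reaction_ids)
    "GLCresp" else character()
  list(
    cerevisiae = species_model(cer, yeast_uptake_params("cerevisiae", context),
                               knockouts = ko),
    stipitis = species_model(stip, yeast_uptake_params("stipitis", context)))
}

#' Brute-force LP oracle by vertex enumeration
#'
#' Exhaustively enumerates the basic solutions of the bounded flux balance
#' LP (every choice of basis columns with the remaining variables pinned at
#' a bound), keeps the feasible ones, and returns the maximum-objective
#' vertex. Exponential in the reaction count, so it refuses networks with
#' more than `max_reactions` reactions; intended purely as an independent
#' testing oracle for [solve_community_fba()].
#'
#' @param comm a `community_network` or `metabolic_network` with finite
#'   bounds.
#' @param uptake_bounds as in [solve_community_fba()].
#' @param max_reactions refusal threshold (default 12).
#' @param tol feasibility tolerance for vertex screening.
#' @return list with `status` (`"optimal"` or `"infeasible"`), `objective`
#'   and `x` (an optimal vertex).
#' @export
bruteforce_lp <- function(comm, uptake_bounds = NULL, max_reactions = 12,
                          tol = 1e-7) {
  if (inherits(comm, "metabolic_network")) {
    if (!is.null(uptake_bounds) && !is.list(uptake_bounds))
      uptake_bounds <- setNames(list(uptake_bounds), comm$species)
    comm <- combine_networks(list(comm))
  }
  stopifnot(inherits(comm, "community_network"))
  n <- ncol(comm$stoichiometry)
  if (n > max_reactions)
    stop("brute-force oracle refuses networks with > ", max_reactions,
         " reactions")
  bb <- .apply_uptake_caps(comm, uptake_bounds)
  lb <- unname(bb$lb); ub <- unname(bb$ub)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("brute-force oracle requires finite bounds")
  A <- unname(comm$stoichiometry)
  w <- unname(comm$objective_weights)
  # drop linearly dependent rows so bases are square and invertible
  qrA <- qr(t(A))
  rk <- qrA$rank
  if (rk < nrow(A)) A <- A[qrA$pivot[seq_len(rk)], , drop = FALSE]
  m <- nrow(A)

  best <- -Inf
  bestx <- NULL
  feasible <- FALSE
  # nonbasic bound patterns as an (n - m) x 2^(n - m) matrix of 0/1
  nn <- n - m
  combos <- if (nn > 0)
    as.matrix(expand.grid(rep(list(c(0, 1)), nn))) else
    matrix(0, 1, 0)
  for (basis in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, basis, drop = FALSE]
    qB <- qr(B)
    if (qB$rank < m) next
    nonbasis <- setdiff(seq_len(n), basis)
    # columns of XN: each nonbasic var at lb (0) or ub (1)
    XN <- lb[nonbasis] + t(combos) * (ub - lb)[nonbasis]
    if (nn == 0) XN <- matrix(0, 0, 1)
    XB <- solve(qB, -A[, nonbasis, drop = FALSE] %*% XN)
    ok <- colSums(XB < lb[basis] - tol | XB > ub[basis] + tol) == 0
    if (!any(ok)) next
    feasible <- TRUE
    obj <- colSums(w[basis] * XB[, ok, drop = FALSE]) +
      colSums(w[nonbasis] * XN[, ok, drop = FALSE])
    k <- which.max(obj)
    if (obj[k] > best) {
      best <- obj[k]
      x <- numeric(n)
      x[basis] <- XB[, ok, drop = FALSE][, k]
      x[nonbasis] <- XN[, ok, drop = FALSE][, k]
      bestx <- x
    }
  }
  if (!feasible) return(list(status = "infeasible", objective = NA_real_,
                             x = NULL))
  list(status = "optimal", objective = best,
       x = setNames(bestx, colnames(comm$stoichiometry)))
}

#' Noise specification for synthetic batch datasets
#'
#' @param relative relative (multiplicative Gaussian) noise level, a single
#'   value or a named vector per series.
#' @param interval sampling interval (h).
#' @param seed integer RNG seed; the same seed reproduces the dataset
#'   bit-for-bit.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(relative = 0.05, interval = 1, seed = 1L) {
  if (any(relative < 0)) stop("noise level must be nonnegative")
  structure(list(relative = relative, interval = interval,
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Generate a noisy synthetic batch dataset
#'
#' Simulates the batch, samples the trajectory on a uniform grid, applies
#' multiplicative Gaussian noise per series, and returns a
#' [batch_dataset()] whose metadata records the generating conditions and
#' the true kinetic parameters, so calibration tests can score parameter
#' recovery.
#'
#' @param models list of [species_model()]s.
#' @param cond a [batch_conditions()].
#' @param noise a [noise_spec()].
#' @param series which series to include (default: biomass per species,
#'   sugars, ethanol, dissolved oxygen).
#' @param ... passed to [simulate_batch()].
#' @return a [batch_dataset()].
#' @export
generate_batch_profiles <- function(models, cond, noise = noise_spec(),
                                    series = NULL, ...) {
  sim <- simulate_batch(models, cond, ...)
  traj <- sim$trajectory
  tt <- seq(0, max(traj$time_h), by = noise$interval)
  cols <- setdiff(names(traj), "time_h")
  if (is.null(series)) series <- cols
  vals <- lapply(series, function(cn)
    approx(traj$time_h, traj[[cn]], xout = tt)$y)
  names(vals) <- series

  if (exists(".Random.seed", envir = globalenv()))
    old <- get(".Random.seed", envir = globalenv()) else old <- NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(noise$seed)
  rel <- noise$relative
  for (cn in series) {
    r <- if (length(rel) == 1) rel else
      if (cn %in% names(rel)) rel[[cn]] else 0
    if (r > 0)
      vals[[cn]] <- pmax(0, vals[[cn]] * (1 + r * rnorm(length(tt))))
  }
  truth <- lapply(models, function(m) unclass(m$uptake))
  batch_dataset(time = tt, series = vals,
                kLa = cond$kLa, initial = cond$initial,
                metadata = list(true_params = truth, seed = noise$seed,
                                noise = rel, context = cond$context))
}
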