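#' Substrate uptake kinetic parameters
#'
#' Bundles the maximum uptake rates and saturation/inhibition constants of
#' the Michaelis-Menten uptake expressions that bound the exchange fluxes
#' of one organism. Capabilities the organism lacks (e.g. xylose transport
#' in *S. cerevisiae*) are encoded as `NA`; the corresponding bound is then
#' identically zero and the dependent constants must also be `NA`.
#'
#' Units follow the batch model throughout: sugars and ethanol in g/L,
#' dissolved oxygen in mM, uptake rates in mmol/gdw/h. No unit conversion
#' happens inside the kinetics.
#'
#' @param v_g_max,v_z_max,v_o_max maximum glucose/xylose/oxygen uptake
#'   rates (mmol/gdw/h); `NA` marks an absent capability.
#' @param K_g,K_z sugar saturation constants (g/L).
#' @param K_o oxygen saturation constant (mM).
#' @param K_ieg,K_iez ethanol inhibition constants for glucose and xylose
#'   uptake (g/L).
#' @param K_igz glucose inhibition constant for xylose uptake (g/L),
#'   responsible for diauxic sugar use.
#' @return an object of class `uptake_params`.
#' @seealso [yeast_uptake_params()] for the calibrated defaults.
#' @export
uptake_params <- function(v_g_max = NA, K_g = NA, K_ieg = NA,
                          v_z_max = NA, K_z = NA, K_iez = NA, K_igz = NA,
                          v_o_max = NA, K_o = NA) {
  p <- list(v_g_max = v_g_max, K_g = K_g, K_ieg = K_ieg,
            v_z_max = v_z_max, K_z = K_z, K_iez = K_iez, K_igz = K_igz,
            v_o_max = v_o_max, K_o = K_o)
  p <- lapply(p, as.numeric)
  present <- !vapply(p, is.na, logical(1))
  if (any(unlist(p[present]) <= 0))
    stop("kinetic parameters must be strictly positive where present")
  if (is.na(p$v_z_max) && !all(is.na(c(p$K_z, p$K_iez, p$K_igz))))
    stop("xylose constants given but v_z_max is absent")
  if (!is.na(p$v_g_max) && is.na(p$K_g))
    stop("v_g_max requires K_g")
  if (!is.na(p$v_z_max) && is.na(p$K_z))
    stop("v_z_max requires K_z")
  if (!is.na(p$v_o_max) && is.na(p$K_o))
    stop("v_o_max requires K_o")
  structure(p, class = "uptake_params")
}

#' @export
print.uptake_params <- function(x, ...) {
  cat("<uptake_params>\n")
  v <- unlist(x)
  cat(" ", paste(names(v), format(v, digits = 4), sep = "=",
                 collapse = "  "), "\n")
  invisible(x)
}

#' Calibrated uptake parameter sets for the two yeasts
#'
#' Returns the uptake kinetic parameters of respiratory-deficient
#' *S. cerevisiae* and wild-type *S. stipitis* estimated from microaerobic
#' batch pure cultures. The *S. cerevisiae* maximum glucose uptake rate
#' depends on the culture context: 21.5 mmol/gdw/h in pure culture but
#' 18.5 mmol/gdw/h in co-culture, where *S. stipitis* competes more
#' effectively for glucose than the pure-culture models predict. The
#' context is always chosen explicitly by the caller, never inferred.
#'
#' @param species `"cerevisiae"` or `"stipitis"`.
#' @param context `"pure_culture"` or `"co_culture"`; only affects
#'   *S. cerevisiae*'s `v_g_max`.
#' @return an [uptake_params()] object.
#' @export
yeast_uptake_params <- function(species = c("cerevisiae", "stipitis"),
                                context = c("pure_culture", "co_culture")) {
  species <- match.arg(species)
  context <- match.arg(context)
  if (species == "cerevisiae") {
    uptake_params(
      v_g_max = if (context == "co_culture") 18.5 else 21.5,
      K_g = 0.5, K_ieg = 10,
      v_o_max = 2.5, K_o = 0.005)
  } else {
    uptake_params(
      v_g_max = 6.5, K_g = 1, K_ieg = 10,
      v_z_max = 5.5, K_z = 0.25, K_iez = 4.5, K_igz = 0.5,
      v_o_max = 11, K_o = 0.0125)
  }
}

.check_nonneg <- function(...) {
  vals <- c(...)
  if (any(vals < 0)) stop("concentrations must be nonnegative")
}

#' Kinetic bound on glucose uptake
#'
#' `v_g = v_g_max * G/(K_g + G) * 1/(1 + E/K_ieg)`: Michaelis-Menten in
#' glucose with noncompetitive ethanol inhibition. Returns 0 for species
#' without a glucose uptake system.
#'
#' @param G glucose concentration (g/L).
#' @param E ethanol concentration (g/L).
#' @param p an [uptake_params()].
#' @return uptake magnitude (mmol/gdw/h), the cap on the glucose exchange.
#' @export
glucose_uptake_bound <- function(G, E, p) {
  .check_nonneg(G, E)
  if (is.na(p$v_g_max)) return(0)
  inhib <- if (is.na(p$K_ieg)) 1 else 1 / (1 + E / p$K_ieg)
  p$v_g_max * G / (p$K_g + G) * inhib
}

#' Kinetic bound on xylose uptake
#'
#' `v_z = v_z_max * Z/(K_z + Z) * 1/(1 + G/K_igz) * 1/(1 + E/K_iez)`. The
#' glucose inhibition factor produces diauxic growth: xylose uptake is
#' repressed until glucose nears depletion. Returns 0 for species without
#' xylose transport.
#'
#' @param Z xylose concentration (g/L).
#' @param G glucose concentration (g/L).
#' @param E ethanol concentration (g/L).
#' @param p an [uptake_params()].
#' @param ignore_glucose_inhibition logical; drop the `1/(1 + G/K_igz)`
#'   factor (the idealized non-diauxic transporter scenario).
#' @return uptake magnitude (mmol/gdw/h).
#' @export
xylose_uptake_bound <- function(Z, G, E, p,
                                ignore_glucose_inhibition = FALSE) {
  .check_nonneg(Z, G, E)
  if (is.na(p$v_z_max)) return(0)
  gi <- if (ignore_glucose_inhibition || is.na(p$K_igz)) 1 else
    1 / (1 + G / p$K_igz)
  ei <- if (is.na(p$K_iez)) 1 else 1 / (1 + E / p$K_iez)
  p$v_z_max * Z / (p$K_z + Z) * gi * ei
}

#' Kinetic bound on oxygen uptake
#'
#' `v_o = v_o_max * O/(K_o + O)`, Michaelis-Menten in the dissolved oxygen
#' concentration.
#'
#' @param O dissolved oxygen (mM).
#' @param p an [uptake_params()].
#' @return uptake magnitude (mmol/gdw/h).
#' @export
oxygen_uptake_bound <- function(O, p) {
  .check_nonneg(O)
  if (is.na(p$v_o_max)) return(0)
  p$v_o_max * O / (p$K_o + O)
}

#' All uptake caps for one organism at one culture state
#'
#' @param state named numeric with `G`, `Z`, `E` (g/L) and `O` (mM).
#' @param p an [uptake_params()].
#' @param ignore_glucose_inhibition passed to [xylose_uptake_bound()].
#' @return named vector of magnitudes `c(glucose=, xylose=, oxygen=)`.
#' @export
uptake_caps <- function(state, p, ignore_glucose_inhibition = FALSE) {
  c(glucose = unname(glucose_uptake_bound(state[["G"]], state[["E"]], p)),
    xylose = unname(xylose_uptake_bound(state[["Z"]], state[["G"]],
                                        state[["E"]], p,
                                        ignore_glucose_inhibition)),
    oxygen = unname(oxygen_uptake_bound(state[["O"]], p)))
}
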