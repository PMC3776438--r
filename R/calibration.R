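#' Batch concentration dataset
#'
#' Measured (or synthetic) concentration series sampled at common times,
#' with the operating metadata needed to re-simulate the batch: kLa and
#' the initial state. Series are any subset of `X_<species>` (gdw/L),
#' `biomass_gdw_L` totals, `glucose_g_L`, `xylose_g_L`, `ethanol_g_L`,
#' `DO_mM`; missing values are allowed and skipped in residuals.
#'
#' @param time sample times (h).
#' @param series named list of numeric vectors, one value per sample time.
#' @param kLa oxygen transfer coefficient of the experiment (1/h).
#' @param initial a [culture_state()] at inoculation.
#' @param metadata free-form list (replicates, noise level, generating
#'   parameters for synthetic data, ...).
#' @return object of class `batch_dataset`.
#' @export
batch_dataset <- function(time, series, kLa, initial, metadata = list()) {
  stopifnot(is.numeric(time), length(series) >= 1, kLa >= 0,
            inherits(initial, "culture_state"))
  bad <- names(series)[vapply(series, length, integer(1)) != length(time)]
  if (length(bad))
    stop("series with wrong length: ", paste(bad, collapse = ", "))
  structure(list(time = time, series = series, kLa = kLa,
                 initial = initial, metadata = metadata),
            class = "batch_dataset")
}

#' Read a batch dataset from wide-form CSV
#'
#' Expected header: `time_h` plus any of the trajectory columns written by
#' [write_batch_dataset()] / [simulate_batch()] (`X_<species>_gdw_L`,
#' `glucose_g_L`, `xylose_g_L`, `ethanol_g_L`, `DO_mM`). kLa and the
#' initial state are passed separately (they are operating metadata, not
#' measurements).
#'
#' @param path CSV file path.
#' @param kLa,initial,metadata as in [batch_dataset()].
#' @return a [batch_dataset()].
#' @export
read_batch_dataset <- function(path, kLa, initial, metadata = list()) {
  df <- read.csv(path, check.names = FALSE)
  if (!"time_h" %in% names(df)) stop("CSV must have a time_h column")
  batch_dataset(df$time_h, as.list(df[setdiff(names(df), "time_h")]),
                kLa = kLa, initial = initial, metadata = metadata)
}

#' @rdname read_batch_dataset
#' @param data a [batch_dataset()] to write.
#' @export
write_batch_dataset <- function(data, path) {
  df <- data.frame(time_h = data$time, data$series, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# interpolate a simulated trajectory to sample times, per series name;
# monotone piecewise-cubic so no overshoot artifacts enter the residuals
.sim_series_at <- function(sim, name, times) {
  traj <- sim$trajectory
  col <- if (name %in% names(traj)) traj[[name]]
  else if (name == "biomass_gdw_L")
    rowSums(traj[grep("^X_.*_gdw_L$", names(traj))])
  else stop("simulation has no series matching '", name, "'")
  f <- splinefun(traj$time_h, col, method = "monoH.FC")
  f(pmin(pmax(times, min(traj$time_h)), max(traj$time_h)))
}

#' Weighted least-squares distance between simulation and data
#'
#' Sum over series and sample times of squared residuals between the
#' measured values and the simulated trajectory interpolated (monotone
#' piecewise-cubic) to the sample times. By default each series is
#' normalized by its maximum absolute measured value, so g/L-scale sugars
#' and mM-scale dissolved oxygen contribute comparably; pass unit weights
#' to override.
#'
#' @param sim a `simulation_result` covering the data time span.
#' @param data a [batch_dataset()].
#' @param weights optional named numeric weights per series (applied to
#'   squared residuals); default `1/max(|series|)^2`.
#' @return the scalar weighted sum of squared residuals.
#' @export
profile_sse <- function(sim, data, weights = NULL) {
  sum(.profile_residuals(sim, data, weights)^2)
}

# weighted residual vector (for least-squares optimizers)
.profile_residuals <- function(sim, data, weights = NULL) {
  common <- names(data$series)
  if (!length(common)) stop("dataset has no series")
  res <- numeric(0)
  for (nm in common) {
    obs <- data$series[[nm]]
    pred <- .sim_series_at(sim, nm, data$time)
    w <- if (!is.null(weights)) {
      if (!nm %in% names(weights)) 1 else weights[[nm]]
    } else {
      mx <- max(abs(obs), na.rm = TRUE)
      if (mx > 0) 1 / mx^2 else 1
    }
    keep <- !is.na(obs)
    res <- c(res, sqrt(w) * (pred[keep] - obs[keep]))
  }
  res
}

#' Stage specification for uptake-parameter fitting
#'
#' One stage of the staged estimation protocol: which parameters are free
#' (named `"species.parameter"`, e.g. `"stipitis.v_g_max"`), their bounds,
#' and which datasets the stage fits. Later stages inherit earlier
#' results as fixed values, mirroring the protocol of estimating glucose
#' kinetics from anaerobic cultures first and oxygen kinetics from aerobic
#' cultures with the glucose parameters fixed.
#'
#' @param free character vector of `"species.parameter"` names.
#' @param lower,upper named finite positive bounds (names as in `free`;
#'   a single unnamed value is recycled).
#' @param datasets integer indices into the dataset list.
#' @param weights optional per-series weights for [profile_sse()].
#' @return object of class `fit_stage`.
#' @export
fit_stage <- function(free, lower, upper, datasets = 1L, weights = NULL) {
  rec <- function(x) {
    if (is.null(names(x)) && length(x) == 1) x <- rep(x, length(free))
    if (is.null(names(x))) names(x) <- free
    x[free]
  }
  lower <- rec(lower); upper <- rec(upper)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower <= 0) || any(lower > upper))
    stop("bounds must be finite, positive and ordered")
  structure(list(free = free, lower = lower, upper = upper,
                 datasets = as.integer(datasets), weights = weights),
            class = "fit_stage")
}

.set_param <- function(models, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% names(models))
    stop("parameter name must be 'species.parameter': ", name)
  if (!parts[2] %in% names(unclass(models[[parts[1]]]$uptake)))
    stop("unknown kinetic parameter: ", name)
  models[[parts[1]]]$uptake[[parts[2]]] <- unname(value)
  models
}

.get_param <- function(models, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  models[[parts[1]]]$uptake[[parts[2]]]
}

#' Estimate uptake kinetic parameters from batch datasets
#'
#' Staged bounded least-squares estimation: each stage minimizes the
#' weighted profile distance ([profile_sse()]) between DFBA simulations
#' and its datasets over its free parameters with the Levenberg-Marquardt
#' method (bounded), holding everything else fixed; later stages start
#' from the earlier stages' estimates. Optional seeded multistart guards
#' against local minima. Non-convergence is reported, with the best
#' parameters found so far returned.
#'
#' @param models list of [species_model()]s whose uptake parameters hold
#'   the starting values (and any fixed values).
#' @param datasets list of [batch_dataset()]s; each must carry the kLa and
#'   initial state of its experiment.
#' @param stages list of [fit_stage()]s, executed in order.
#' @param context culture context for the simulations.
#' @param n_starts multistart count per stage (1 = start from the model's
#'   current values).
#' @param seed RNG seed for multistart draws.
#' @param sim_control list of [simulate_batch()] settings used during
#'   fitting (coarser tolerances make fitting cheap; defaults
#'   `rtol = 1e-5`, `atol = 1e-7`, `pfba = TRUE`, `flux_trace = FALSE`).
#' @param t_end simulation horizon; default: each dataset's last sample.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return list with `models` (updated), `estimates` (named vector over
#'   all stages), and `stages` (per-stage convergence report: estimates,
#'   final SSE, convergence flag, optimizer message).
#' @export
fit_uptake_parameters <- function(models, datasets, stages,
                                  context = c("co_culture", "pure_culture"),
                                  n_starts = 1L, seed = 1L,
                                  sim_control = list(), t_end = NULL,
                                  maxiter = 30) {
  context <- match.arg(context)
  ctrl <- modifyList(list(rtol = 1e-5, atol = 1e-7, pfba = TRUE,
                          flux_trace = FALSE), sim_control)
  simulate_ds <- function(mods, ds) {
    cond <- batch_conditions(
      initial = ds$initial, kLa = ds$kLa, context = context,
      t_end = if (is.null(t_end)) max(ds$time) else t_end,
      output_dt = max(diff(range(ds$time)) / 200, 0.05))
    suppressWarnings(
      do.call(simulate_batch, c(list(models = mods, cond = cond), ctrl)))
  }
  reports <- list()
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    stopifnot(inherits(st, "fit_stage"))
    ds_list <- datasets[st$datasets]
    nres <- sum(vapply(ds_list, function(ds)
      sum(!is.na(unlist(ds$series))), integer(1)))
    resid_fn <- function(theta) {
      mods <- models
      for (k in seq_along(st$free))
        mods <- .set_param(mods, st$free[k], theta[k])
      # a parameter vector whose stiff simulation fails gets a flat
      # penalty, steering the optimizer back to integrable regions
      tryCatch(
        unlist(lapply(ds_list, function(ds)
          .profile_residuals(simulate_ds(mods, ds), ds, st$weights))),
        error = function(e) rep(1e4, nres))
    }
    start0 <- vapply(st$free, function(nm) {
      v <- .get_param(models, nm)
      if (is.na(v)) sqrt(st$lower[nm] * st$upper[nm]) else v
    }, numeric(1))
    start0 <- pmin(pmax(start0, st$lower), st$upper)
    starts <- list(start0)
    if (n_starts > 1) {
      if (exists(".Random.seed", envir = globalenv()))
        old <- get(".Random.seed", envir = globalenv()) else old <- NULL
      set.seed(seed + si)
      for (k in seq_len(n_starts - 1))
        starts[[k + 1]] <- st$lower +
          runif(length(st$free)) * (st$upper - st$lower)
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }
    best <- NULL
    for (s0 in starts) {
      fit <- minpack.lm::nls.lm(
        par = s0, lower = unname(st$lower), upper = unname(st$upper),
        fn = resid_fn,
        # epsfcn widens the finite-difference step (~1% relative) so the
        # jacobian rises above the adaptive integrator's output noise
        control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                             ptol = 1e-8, ftol = 1e-10,
                                             epsfcn = 1e-4))
      sse <- sum(fit$fvec^2)
      if (is.null(best) || sse < best$sse)
        best <- list(par = setNames(fit$par, st$free), sse = sse,
                     converged = fit$info %in% 1:4,
                     message = fit$message, rsstrace = fit$rsstrace)
    }
    for (k in seq_along(st$free))
      models <- .set_param(models, st$free[k], best$par[[k]])
    reports[[si]] <- best
  }
  list(models = models,
       estimates = unlist(lapply(reports, `[[`, "par")),
       stages = reports)
}
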