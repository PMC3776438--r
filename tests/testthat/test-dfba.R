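test_that("kLa follows the two-point sparge calibration", {
  expect_equal(kla_from_sparge(25), 5.5)
  expect_equal(kla_from_sparge(50), 10.1)
  expect_equal(kla_from_sparge(37.5), 7.8)
  expect_error(kla_from_sparge(-1), "nonnegative")
})

test_that("the right-hand side honors its limiting cases", {
  models <- toy_study_models()
  cond <- toy_study_conditions(kLa = 10.1)
  # no biomass: sugars and ethanol frozen, oxygen relaxes toward O*
  y0 <- c(X.cerevisiae = 0, X.stipitis = 0, G = 10, Z = 5, E = 1, O = 0.1)
  d <- dfba_rhs(y0, models, cond)$derivatives
  expect_equal(unname(d[c("G", "Z", "E")]), c(0, 0, 0))
  expect_equal(unname(d[["O"]]), 10.1 * (0.24 - 0.1))
  # at saturation with no biomass, the oxygen balance is at equilibrium
  y1 <- y0; y1["O"] <- 0.24
  expect_equal(unname(dfba_rhs(y1, models, cond)$derivatives[["O"]]), 0)
})

test_that("growth matches the hand-computed LP rate in the rhs", {
  cfg <- toy_network_config("glucose", maintenance = 0.5)
  models <- list(c = species_model(make_toy_species(cfg, "c"),
                                   yeast_uptake_params("stipitis")))
  cond <- batch_conditions(culture_state(X = c(c = 0.5), G = 100, O = 0.24),
                           kLa = 5, t_end = 1, context = "pure_culture")
  y <- c(X.c = 0.5, G = 100, Z = 0, E = 0, O = 0.24)
  d <- dfba_rhs(y, models, cond)
  p <- yeast_uptake_params("stipitis")
  cf <- toy_closed_form(cfg, u_g = glucose_uptake_bound(100, 0, p),
                        u_o = oxygen_uptake_bound(0.24, p))
  expect_equal(unname(d$derivatives[["X.c"]]), cf$mu * 0.5, tolerance = 1e-9)
  expect_equal(d$solution$growth_rates[["c"]], cf$mu, tolerance = 1e-9)
})

test_that("maintenance toggle relaxes only the glucose-only member", {
  models <- toy_study_models()
  ov <- maintenance_toggle(models)
  expect_identical(names(ov$lower), "cerevisiae.ATPM")
  expect_equal(unname(ov$lower), 0)
  cond <- toy_study_conditions()
  comm <- combine_networks(lapply(models, `[[`, "network"))
  # glucose present: cerevisiae grows fermentatively, maintenance enforced
  y <- c(X.cerevisiae = 0.3, X.stipitis = 0.3, G = 10, Z = 5, E = 0, O = 0.01)
  sol <- codfba:::.solve_at_state(comm, models, y, cond)
  expect_gt(sol$fluxes$cerevisiae[["ATPM"]], 1 - 1e-9)
  # glucose depleted: community stays feasible because the cerevisiae
  # maintenance bound is dropped; stipitis maintenance stays enforced
  y2 <- c(X.cerevisiae = 0.3, X.stipitis = 0.3, G = 0, Z = 5, E = 0, O = 0.01)
  sol2 <- codfba:::.solve_at_state(comm, models, y2, cond)
  expect_identical(sol2$status, "optimal")
  expect_equal(sol2$growth_rates[["cerevisiae"]], 0, tolerance = 1e-9)
  expect_gte(sol2$fluxes$stipitis[["ATPM"]], 1 - 1e-9)
  # without the toggle the same state is infeasible
  raw <- solve_community_fba(comm, lapply(models, function(m)
    uptake_caps(c(G = 0, Z = 5, E = 0, O = 0.01), m$uptake)))
  expect_identical(raw$status, "infeasible")
})

test_that("total starvation returns zero fluxes rather than an error", {
  models <- toy_study_models()
  cond <- toy_study_conditions()
  comm <- combine_networks(lapply(models, `[[`, "network"))
  y <- c(X.cerevisiae = 0.3, X.stipitis = 0.3, G = 0, Z = 0, E = 0, O = 0)
  # all substrates gone: every maintenance demand is relaxed and the
  # community settles on the all-zero flux vector
  sol <- codfba:::.solve_at_state(comm, models, y, cond)
  expect_equal(unname(sol$growth_rates), c(0, 0), tolerance = 1e-12)
  expect_equal(max(abs(unlist(sol$exchange_fluxes))), 0, tolerance = 1e-9)
  d <- dfba_rhs(y, models, cond)$derivatives
  expect_equal(unname(d[c("X.cerevisiae", "X.stipitis", "G", "Z", "E")]),
               rep(0, 5))
})

test_that("batch with non-limiting bounds follows the analytic exponential", {
  # saturated kinetics, no maintenance: constant mu, X grows exponentially
  cfg <- toy_network_config("glucose", respiration = FALSE, maintenance = 0)
  p <- uptake_params(v_g_max = 5, K_g = 0.001, K_ieg = 1e6)
  models <- list(c = species_model(make_toy_species(cfg, "c"), p))
  X0 <- 0.05
  cond <- batch_conditions(culture_state(X = c(c = X0), G = 400, O = 0.24),
                           kLa = 0, t_end = 6, context = "pure_culture",
                           output_dt = 0.05)
  sim <- simulate_batch(models, cond, flux_trace = FALSE,
                        rtol = 1e-8, atol = 1e-10)
  mu <- 5 * cfg$atp_per_glc_ferm / cfg$atp_per_biomass  # 0.1 / h
  tt <- sim$trajectory$time_h
  expect_equal(sim$trajectory$X_c_gdw_L, X0 * exp(mu * tt),
               tolerance = 1e-5)
  # ethanol follows the integrated exponential
  Eexp <- 2 * 5 * 0.04607 * X0 * (exp(mu * tt) - 1) / mu
  expect_equal(sim$trajectory$ethanol_g_L, Eexp, tolerance = 1e-4)
})

test_that("zero inoculum leaves chemistry frozen while oxygen saturates", {
  models <- toy_study_models()
  cond <- batch_conditions(
    culture_state(X = c(cerevisiae = 0, stipitis = 0), G = 8, Z = 4, E = 1,
                  O = 0.05),
    kLa = 5.5, t_end = 2, context = "co_culture", output_dt = 0.1)
  sim <- simulate_batch(models, cond, flux_trace = FALSE)
  tr <- sim$trajectory
  expect_equal(tr$glucose_g_L, rep(8, nrow(tr)), tolerance = 1e-8)
  expect_equal(tr$xylose_g_L, rep(4, nrow(tr)), tolerance = 1e-8)
  expect_equal(tr$ethanol_g_L, rep(1, nrow(tr)), tolerance = 1e-8)
  # O relaxes exponentially to O* at rate kLa
  expect_equal(tr$DO_mM, 0.24 + (0.05 - 0.24) * exp(-5.5 * tr$time_h),
               tolerance = 1e-5)
})

test_that("above-envelope aeration warns about unmodeled reassimilation", {
  models <- toy_study_models()
  cond <- toy_study_conditions(kLa = 15, t_end = 0.2)
  expect_warning(simulate_batch(models, cond, flux_trace = FALSE),
                 "envelope")
})

test_that("batch metrics interpolate the xylose cutoff crossing", {
  # constructed trajectory: Z crosses 0.5 exactly at t = 17.15, E there 9.43
  traj <- data.frame(time_h = c(0, 10, 17, 17.3, 20),
                     xylose_g_L = c(8, 4, 0.65, 0.35, 0.1),
                     ethanol_g_L = c(0, 5, 9.355, 9.505, 9.8))
  m <- batch_metrics(list(trajectory = traj))
  expect_equal(m$batch_time_h, 17.15)
  expect_equal(m$titer_g_L, 9.43)
  expect_equal(m$productivity_g_L_h, 9.43 / 17.15)
  expect_true(m$defined)
  # grid-point crossing needs no interpolation
  traj2 <- data.frame(time_h = 0:3, xylose_g_L = c(4, 2, 0.4, 0.1),
                      ethanol_g_L = c(0, 1, 2, 3))
  expect_equal(batch_metrics(list(trajectory = traj2),
                             xylose_cutoff = 0.4000001)$batch_time_h, 2,
               tolerance = 1e-5)
  # starting below the cutoff: batch time zero, productivity undefined
  traj3 <- data.frame(time_h = 0:1, xylose_g_L = c(0.2, 0.1),
                      ethanol_g_L = c(0, 0))
  m3 <- batch_metrics(list(trajectory = traj3))
  expect_equal(m3$batch_time_h, 0)
  expect_false(m3$defined)
  # never crossed: flagged undefined, not an error
  traj4 <- data.frame(time_h = 0:1, xylose_g_L = c(8, 7),
                      ethanol_g_L = c(0, 1))
  expect_false(batch_metrics(list(trajectory = traj4))$defined)
})

test_that("trajectory times increase and metrics are recomputable", {
  models <- toy_study_models()
  sim <- simulate_batch(models, toy_study_conditions(t_end = 30),
                        flux_trace = FALSE)
  expect_true(all(diff(sim$trajectory$time_h) > 0))
  expect_equal(batch_metrics(sim), sim$metrics)
})
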