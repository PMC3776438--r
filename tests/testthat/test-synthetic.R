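test_that("toy species match their closed-form optima", {
  set.seed(404)
  for (rep in 1:10) {
    cfg <- random_toy_config(equal_sugar_yields = TRUE)
    net <- make_toy_species(cfg)
    caps <- random_caps(cfg)
    got <- solve_fba(net, caps, pfba = FALSE)
    cf <- toy_closed_form(cfg, u_g = caps[["glucose"]],
                          u_z = if ("xylose" %in% cfg$substrates)
                            caps[["xylose"]] else 0,
                          u_o = caps[["oxygen"]])
    expect_identical(got$status, cf$status)
    if (cf$status == "optimal")
      expect_equal(got$objective, cf$mu, tolerance = 1e-9)
  }
  # zero caps: no growth (or infeasible under positive maintenance)
  net <- make_toy_species(toy_network_config("glucose", maintenance = 0))
  z <- solve_fba(net, c(glucose = 0, oxygen = 0))
  expect_equal(z$objective, 0)
  netm <- make_toy_species(toy_network_config("glucose", maintenance = 1))
  expect_identical(solve_fba(netm, c(glucose = 0, oxygen = 0))$status,
                   "infeasible")
})

test_that("toy configuration rejects inconsistent yields", {
  expect_error(toy_network_config(atp_per_glc_ferm = 30),
               "below the respiratory")
  expect_error(toy_network_config(atp_per_glc_ferm = 0), "strictly positive")
  expect_error(toy_network_config("ethanol", respiration = FALSE),
               "respiratory route")
})

test_that("toy community has the study structure", {
  models <- make_toy_community()
  expect_named(models, c("cerevisiae", "stipitis"))
  # respiratory-deficient cerevisiae: respiration blocked, no xylose system
  expect_equal(unname(models$cerevisiae$network$upper_bounds["GLCresp"]), 0)
  expect_true(is.na(models$cerevisiae$uptake$v_z_max))
  expect_equal(models$cerevisiae$uptake$v_g_max, 18.5)  # co-culture context
  expect_equal(make_toy_community("pure_culture")$cerevisiae$uptake$v_g_max,
               21.5)
  expect_equal(models$stipitis$uptake$v_z_max, 5.5)
  # identical members with equal caps grow equally at the optimum
  twin_a <- species_model(make_toy_species(toy_network_config("glucose"),
                                           "a"),
                          yeast_uptake_params("stipitis"))
  twin_b <- species_model(make_toy_species(toy_network_config("glucose"),
                                           "b"),
                          yeast_uptake_params("stipitis"))
  comm <- combine_networks(list(twin_a$network, twin_b$network))
  caps <- c(glucose = 4, oxygen = 3)
  sol <- solve_community_fba(comm, list(a = caps, b = caps))
  expect_equal(sol$growth_rates[["a"]], sol$growth_rates[["b"]],
               tolerance = 1e-12)
  # diauxic member alone at G = 0 follows the xylose closed form
  cfgs <- toy_network_config(c("glucose", "xylose"))
  stip <- make_toy_species(cfgs, "s")
  p <- yeast_uptake_params("stipitis")
  caps0 <- uptake_caps(c(G = 0, Z = 4, E = 0, O = 0.24), p)
  cf <- toy_closed_form(cfgs, u_g = 0, u_z = caps0[["xylose"]],
                        u_o = caps0[["oxygen"]])
  expect_equal(solve_fba(stip, caps0)$objective, cf$mu, tolerance = 1e-9)
})

test_that("batch profile generation is seeded and honest about noise", {
  models <- make_toy_community(context = "pure_culture")["stipitis"]
  cond <- batch_conditions(culture_state(X = c(stipitis = 0.4), G = 15.7,
                                         Z = 8.4, O = 0.24),
                          kLa = 10.1, t_end = 10, context = "pure_culture")
  sim <- simulate_batch(models, cond, flux_trace = FALSE)
  # zero noise reproduces the simulation at the sample times
  ds0 <- generate_batch_profiles(models, cond,
                                 noise_spec(relative = 0, interval = 1))
  expect_equal(ds0$series$glucose_g_L,
               approx(sim$trajectory$time_h, sim$trajectory$glucose_g_L,
                      ds0$time)$y, tolerance = 1e-9)
  # same seed -> identical dataset; different seed -> different
  d1 <- generate_batch_profiles(models, cond,
                                noise_spec(0.05, 1, seed = 11))
  d2 <- generate_batch_profiles(models, cond,
                                noise_spec(0.05, 1, seed = 11))
  d3 <- generate_batch_profiles(models, cond,
                                noise_spec(0.05, 1, seed = 12))
  expect_identical(d1$series, d2$series)
  expect_false(identical(d1$series, d3$series))
  # metadata carries the generating truth for recovery scoring
  expect_equal(d1$metadata$true_params$stipitis$v_g_max, 6.5)
  expect_equal(d1$metadata$seed, 11L)
})

test_that("the noise generator delivers the requested relative spread", {
  models <- make_toy_community(context = "pure_culture")["stipitis"]
  cond <- batch_conditions(culture_state(X = c(stipitis = 0.4), G = 15.7,
                                         Z = 8.4, O = 0.24),
                          kLa = 10.1, t_end = 10, context = "pure_culture")
  clean <- generate_batch_profiles(models, cond,
                                   noise_spec(relative = 0, interval = 0.5))
  devs <- c()
  for (seed in 1:30) {
    noisy <- generate_batch_profiles(models, cond,
                                     noise_spec(0.05, 0.5, seed = seed))
    ref <- clean$series$glucose_g_L
    keep <- ref > 1   # relative deviation meaningful away from zero
    devs <- c(devs, (noisy$series$glucose_g_L[keep] - ref[keep]) / ref[keep])
  }
  expect_equal(sd(devs), 0.05, tolerance = 0.1)
  expect_lt(abs(mean(devs)), 0.005)
})

test_that("the brute-force oracle enforces its own limits", {
  net <- make_toy_species(toy_network_config(c("glucose", "xylose")))
  expect_error(bruteforce_lp(net, max_reactions = 5), "refuses")
  wide <- metabolic_network(matrix(1, 1, 2), c(-Inf, 0), c(Inf, 1), c(0, 1))
  expect_error(bruteforce_lp(wide), "finite bounds")
  # infeasible instances are reported as such
  netm <- make_toy_species(toy_network_config("glucose", maintenance = 5))
  expect_identical(bruteforce_lp(netm, c(glucose = 0.1, oxygen = 0))$status,
                   "infeasible")
})
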