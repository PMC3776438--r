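test_that("metabolic_network validates its invariants", {
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("a", "b"), "r1"))
  expect_s3_class(metabolic_network(S, 0, 10, 1), "metabolic_network")
  expect_error(metabolic_network(S, 5, 1, 1), "lower_bounds")
  expect_error(metabolic_network(S, 0, 10, 1,
                                 exchange_map = list(glucose = "nope")),
               "not in network")
  expect_error(metabolic_network(S, 0, 10, 1, maintenance_id = "nope"),
               "not in network")
  expect_error(metabolic_network(S, 0, 10, 1,
                                 exchange_map = list(sucrose = "r1")),
               "unknown exchange species")
  S2 <- S; colnames(S2) <- NULL
  expect_error(metabolic_network(S2, 0, 10, 1,
                                 reaction_ids = c("r1", "r1", "r2")),
               "lengths|duplicate")
})

test_that("apply_knockouts blocks reactions on a copy only", {
  net <- make_toy_species(toy_network_config("glucose"))
  expect_identical(apply_knockouts(net, character()), net)
  ko <- apply_knockouts(net, "GLCresp")
  expect_equal(unname(ko$lower_bounds["GLCresp"]), 0)
  expect_equal(unname(ko$upper_bounds["GLCresp"]), 0)
  expect_gt(net$upper_bounds[["GLCresp"]], 0)  # original untouched
  expect_error(apply_knockouts(net, "NOPE"), "unknown reaction")
})

test_that("knocking out respiration reduces growth to the fermentative closed form", {
  cfg <- toy_network_config("glucose", maintenance = 0.5)
  net <- make_toy_species(cfg)
  caps <- c(glucose = 8, oxygen = 6)
  aerobic <- solve_fba(net, caps)
  ferm <- solve_fba(apply_knockouts(net, "GLCresp"), caps)
  cf_aer <- toy_closed_form(cfg, u_g = 8, u_o = 6)
  cfg0 <- cfg; cfg0$respiration <- FALSE
  cf_frm <- toy_closed_form(cfg0, u_g = 8)
  expect_equal(aerobic$objective, cf_aer$mu, tolerance = 1e-9)
  expect_equal(ferm$objective, cf_frm$mu, tolerance = 1e-9)
  expect_lt(ferm$objective, aerobic$objective)
  # fermentation-only optimum secretes ethanol
  expect_equal(ferm$exchange_fluxes$toy[["ethanol"]], cf_frm$ethanol,
               tolerance = 1e-9)
})

test_that("community assembly is block-diagonal and preserves member optima", {
  a <- make_toy_species(toy_network_config("glucose"), species = "a")
  b <- make_toy_species(toy_network_config(c("glucose", "xylose"),
                                           maintenance = 0),
                        species = "b")
  comm <- combine_networks(list(a, b))
  na_ <- length(a$reaction_ids); nb <- length(b$reaction_ids)
  expect_equal(dim(comm$stoichiometry),
               c(length(a$metabolite_ids) + length(b$metabolite_ids),
                 na_ + nb))
  # zero off-diagonal blocks
  expect_true(all(comm$stoichiometry[seq_along(a$metabolite_ids),
                                     na_ + seq_len(nb)] == 0))
  expect_true(all(comm$stoichiometry[-seq_along(a$metabolite_ids),
                                     seq_len(na_)] == 0))
  expect_error(combine_networks(list(a, a)), "duplicate species")

  # zeroing one member reproduces the pure-culture optimum
  caps_a <- c(glucose = 5, oxygen = 3)
  pure <- solve_fba(a, caps_a)
  both <- solve_community_fba(comm, list(
    a = caps_a, b = c(glucose = 0, xylose = 0, oxygen = 0)))
  expect_identical(both$status, "optimal")
  expect_equal(both$growth_rates[["a"]], pure$objective, tolerance = 1e-9)
  expect_equal(both$growth_rates[["b"]], 0, tolerance = 1e-9)

  # single-member community is the member
  one <- combine_networks(list(a))
  expect_equal(solve_community_fba(one, list(a = caps_a))$objective,
               pure$objective, tolerance = 1e-12)
})

test_that("community optimum matches hand-computed values and stays conservative", {
  cfg1 <- toy_network_config("glucose", maintenance = 1)
  cfg2 <- toy_network_config(c("glucose", "xylose"), maintenance = 1)
  models <- list(make_toy_species(cfg1, "c"), make_toy_species(cfg2, "s"))
  comm <- combine_networks(models)
  caps <- list(c = c(glucose = 10, oxygen = 2),
               s = c(glucose = 3, xylose = 2, oxygen = 6))
  sol <- solve_community_fba(comm, caps)
  cf1 <- toy_closed_form(cfg1, u_g = 10, u_o = 2)
  cf2 <- toy_closed_form(cfg2, u_g = 3, u_z = 2, u_o = 6)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$growth_rates[["c"]], cf1$mu, tolerance = 1e-9)
  expect_equal(sol$growth_rates[["s"]], cf2$mu, tolerance = 1e-9)
  expect_equal(sol$objective, cf1$mu + cf2$mu, tolerance = 1e-9)
  expect_lt(sol$residual, 1e-9)
  # growth rates sum to the objective
  expect_equal(sum(sol$growth_rates), sol$objective, tolerance = 1e-12)
})

test_that("maintenance beyond attainable ATP is infeasible", {
  net <- make_toy_species(toy_network_config("glucose", maintenance = 50))
  sol <- solve_fba(net, c(glucose = 1, oxygen = 0))  # max ATP = 2 < 50
  expect_identical(sol$status, "infeasible")
})

test_that("raising an uptake cap never decreases the community objective", {
  set.seed(202)
  cfg <- toy_network_config(c("glucose", "xylose"))
  net <- make_toy_species(cfg)
  for (rep in 1:10) {
    caps <- random_caps(cfg)
    base <- solve_fba(net, caps, pfba = FALSE)
    what <- sample(names(caps), 1)
    caps2 <- caps; caps2[what] <- caps2[what] + runif(1, 0.1, 3)
    more <- solve_fba(net, caps2, pfba = FALSE)
    if (base$status == "optimal") {
      expect_identical(more$status, "optimal")
      expect_gte(more$objective + 1e-9, base$objective)
    }
  }
})

test_that("a knockout never increases optimal growth", {
  set.seed(203)
  for (rep in 1:8) {
    cfg <- random_toy_config()
    net <- make_toy_species(cfg)
    caps <- random_caps(cfg)
    full <- solve_fba(net, caps, pfba = FALSE)
    # dominance holds for capability knockouts; ATPM is a demand, and
    # blocking it relaxes the problem instead
    rid <- sample(setdiff(net$reaction_ids, c("BIOMASS", "ATPM")), 1)
    kosol <- solve_fba(apply_knockouts(net, rid), caps, pfba = FALSE)
    if (full$status == "optimal" && kosol$status == "optimal")
      expect_lte(kosol$objective, full$objective + 1e-9)
  }
})

test_that("parsimonious refinement keeps the optimum and trims futile flux", {
  # add a futile cycle: two opposed interconversions of inert metabolites
  # that any flux level can spin without affecting the optimum
  cfg <- toy_network_config("glucose")
  net <- make_toy_species(cfg)
  S <- rbind(net$stoichiometry, junk1_c = 0, junk2_c = 0)
  S <- cbind(S, cycle_f = 0, cycle_r = 0)
  S[c("junk1_c", "junk2_c"), "cycle_f"] <- c(-1, 1)
  S[c("junk1_c", "junk2_c"), "cycle_r"] <- c(1, -1)
  net2 <- metabolic_network(
    S, c(net$lower_bounds, 0, 0), c(net$upper_bounds, 100, 100),
    c(net$objective_weights, 0, 0), exchange_map = net$exchange_map,
    compartments = c(net$compartments, "cytoplasm", "cytoplasm"),
    maintenance_id = net$maintenance_id, species = net$species)
  sol <- solve_fba(net2, c(glucose = 5, oxygen = 3), pfba = TRUE)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$fluxes$toy[["cycle_f"]], 0, tolerance = 1e-9)
  expect_equal(sol$fluxes$toy[["cycle_r"]], 0, tolerance = 1e-9)
  expect_equal(sol$objective,
               solve_fba(net2, c(glucose = 5, oxygen = 3),
                         pfba = FALSE)$objective, tolerance = 1e-9)
})
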