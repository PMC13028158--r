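test_that("generator is reproducible and validates its configuration", {
  cfg <- generator_config(n_species = 10L, seed = 99L)
  a <- generate_species_set(cfg)
  b <- generate_species_set(cfg)
  expect_identical(a, b)
  # n = 0 yields just the reference set
  empty <- generate_species_set(generator_config(n_species = 0L))
  expect_equal(nrow(empty), 4L)
  expect_error(generator_config(sd_e_zpe = -1), "sds")
  expect_error(generator_config(ts_offset_min = 0), "offsets")
  expect_error(generator_config(c_range = c(3L, 1L)), "degenerate")
})

test_that("a generated set of 50 has finite energies and computable G_rel", {
  sp <- generate_species_set(generator_config(n_species = 50L, seed = 4L))
  expect_true(all(is.finite(sp$e_zpe)))
  expect_true(all(sp$s_gas > 0))
  g <- grel_from_components(sp)
  expect_true(all(is.finite(g)))
  expect_length(g, 54L)
})

test_that("generated networks are balanced, cycle-consistent and unsubmerged", {
  cfg <- generator_config(n_species = 14L, seed = 12L)
  sp <- generate_species_set(cfg)
  net <- generate_network(sp, n_reactions = 14L, seed = 12L, config = cfg)
  net2 <- generate_network(sp, n_reactions = 14L, seed = 12L, config = cfg)
  expect_identical(net$reactions, net2$reactions)   # seed determinism
  for (id in net$reactions$id) {
    expect_length(element_balance_check(net, id), 0)
  }
  cyc <- hess_cycle_residuals(net)
  expect_gt(nrow(cyc), 0)
  expect_lt(max(abs(cyc$residual)), 1e-9)
  for (id in net$reactions$id[!is.na(net$reactions$ts_id)]) {
    expect_false(activation_barriers(net, id)$submerged)
  }
  expect_true(audit_map(net, tol = 1e-9)$ok)
})

test_that("corruption of 0.5 kcal/mol is detected, quantified and localized", {
  cfg <- generator_config(n_species = 14L, seed = 12L)
  sp <- generate_species_set(cfg)
  net <- generate_network(sp, n_reactions = 14L, seed = 12L, config = cfg)
  cc <- corrupt_map(net, magnitude = 0.5, seed = 3L)
  expect_s3_class(cc$record, "corruption_record")
  expect_false(audit_map(cc$map)$ok)
  loc <- localize_corruption(cc$map)
  expect_true(loc$detected)
  expect_equal(loc$max_residual, 0.5, tolerance = 1e-9)
  expect_equal(loc$species[1], cc$record$species_id)
  expect_true(cc$record$reaction_id %in% loc$reactions)
})

test_that("sub-threshold corruption passes the audit and is noted", {
  cfg <- generator_config(n_species = 14L, seed = 12L)
  sp <- generate_species_set(cfg)
  net <- generate_network(sp, n_reactions = 14L, seed = 12L, config = cfg)
  cc <- corrupt_map(net, magnitude = 0.005, seed = 5L)
  expect_true(cc$record$sub_threshold)
  expect_true(audit_map(cc$map, tol = 0.01)$ok)
  expect_error(corrupt_map(net, magnitude = 0), "nonzero")
})

test_that("corrupting an acyclic map is refused", {
  sp <- data.frame(id = c("a", "b"), formula = "C2H4O2", role = "minimum",
                   g_rel = c(0, -1))
  acyc <- free_energy_map(sp, data.frame(id = "r", reactants = "a", products = "b"))
  expect_error(corrupt_map(acyc, 0.5), "acyclic")
})

test_that("the packaged fixture satisfies its contract", {
  m <- fixture_map()
  sp <- m$species
  # spot checks quoted from the running text
  grel <- stats::setNames(sp$g_rel, sp$id)
  expect_equal(unname(grel["7"]), -12.8)
  expect_equal(unname(grel["9"]), 18.3)
  expect_equal(unname(grel[c("CO2", "H2", "H2O", "H2SO3")]), rep(0, 4))
  # the minimum promised species complement is present
  need <- c("1", "2", "3", "4", "5", "6", "7", "8", "9", "16", "17", "18",
            "20", "21", "31rib", "32xyl", "33rib", "30lyx")
  expect_true(all(need %in% sp$id))
  # provenance annotation: every row labelled, stand-ins clearly marked
  expect_true(all(sp$anchor %in% c("reference", "text", "text-derived", "standin")))
  expect_gt(sum(sp$anchor == "text"), 15)
  # text-anchored subset loads cleanly and keeps the quoted values
  mt <- load_paper_fixture(text_anchored_only = TRUE)
  expect_false(any(mt$species$anchor == "standin"))
  expect_true(all(c("7", "8", "9") %in% mt$species$id))
  expect_true(audit_map(mt, tol = 0.15)$ok)
})
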