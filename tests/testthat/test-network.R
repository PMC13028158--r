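test_that("element balance check counts atoms with multiplicity", {
  m <- fixture_map()
  # 4 + H2SO3 -> 7 + H2O is balanced
  expect_length(element_balance_check(m, "r_add_7"), 0)
  for (id in m$reactions$id) {
    expect_length(element_balance_check(m, id), 0)
  }
  # constructed negative case: product formula typo'd to C2H4O3
  sp <- data.frame(id = c("a", "b"), formula = c("C2H4O2", "C2H4O3"),
                   role = "minimum", g_rel = c(0, 0))
  rx <- data.frame(id = "r1", reactants = "a", products = "b")
  bad <- free_energy_map(sp, rx, check_balance = FALSE)
  expect_equal(element_balance_check(bad, "r1"), c(O = 1))
  expect_error(free_energy_map(sp, rx), "imbalanced")
  # identity reaction is trivially balanced
  rx2 <- data.frame(id = "r1", reactants = "a", products = "a")
  expect_length(element_balance_check(free_energy_map(sp, rx2), "r1"), 0)
})

test_that("reaction dG reproduces the printed worked examples", {
  m <- fixture_map()
  expect_kcal(reaction_delta_g(m, "r_shift_68"), -2.6)       # 6 -> 8
  expect_kcal(reaction_delta_g(m, "r_aldol_1720"), -12.6)    # 17 + 1 + H2O -> 20 + H2SO3
  expect_kcal(reaction_delta_g(m, "r_dehyd_8"), -0.8)
  expect_kcal(reaction_delta_g(m, "r_can_c1"), -22.2)
  expect_kcal(reaction_delta_g(m, "r_xcan_iii"), -3.1)
  # unknown ids and missing G_rel are rejected with names
  expect_error(reaction_delta_g(m, "nope"), "unknown reaction")
  sp <- data.frame(id = c("a", "b"), formula = "C2H4O2", role = "minimum",
                   g_rel = c(0, NA))
  m2 <- free_energy_map(sp, data.frame(id = "r", reactants = "a", products = "b"))
  expect_error(reaction_delta_g(m2, "r"), "\\bb\\b")
})

test_that("dG of a composed path equals the sum of step dGs", {
  m <- fixture_map()
  # rearrangement 6 -> 8 -> 7 + H2O: overall -3.4
  expect_equal(path_delta_g(m, c("r_shift_68", "r_dehyd_8")),
               reaction_delta_g(m, "r_shift_68") + reaction_delta_g(m, "r_dehyd_8"),
               tolerance = 1e-12)
  # reversal flips the sign
  expect_equal(path_delta_g(m, c("r_shift_68", "-r_shift_68")), 0, tolerance = 1e-12)
})

test_that("activation barriers: forward minus reverse is dG, identity to 1e-12", {
  m <- fixture_map()
  with_ts <- m$reactions$id[!is.na(m$reactions$ts_id)]
  expect_gt(length(with_ts), 20)
  for (id in with_ts) {
    ab <- activation_barriers(m, id)
    expect_equal(ab$forward - ab$reverse, ab$delta_g, tolerance = 1e-12)
  }
  # O-attack on CH2O: forward +5.2, dG -3.0 -> reverse 8.2
  ab <- activation_barriers(m, "r_add_1O")
  expect_kcal(ab$forward, 5.2)
  expect_kcal(ab$reverse, 8.2)
  expect_false(ab$submerged)
})

test_that("submerged barriers are flagged, not silently negative", {
  m <- fixture_map()
  # ring-shift pathway: flanking TS (+16.9) below intermediate 9 (+18.3)
  ab <- activation_barriers(m, "r_shift_69")
  expect_true(ab$submerged)
  expect_kcal(ab$reverse, 16.9 - 18.3)
  # absence of a TS is a typed no-barrier result, distinct from zero
  nb <- activation_barriers(m, "r_hyd_1")
  expect_false(nb$has_barrier)
  expect_true(is.na(nb$forward))
})

test_that("Hess residuals vanish on registry-derived maps and catch injections", {
  m <- fixture_map()
  cyc <- hess_cycle_residuals(m)
  expect_gt(nrow(cyc), 5)
  expect_lt(max(abs(cyc$residual)), 1e-9)
  # acyclic toy map -> empty result
  sp <- data.frame(id = c("a", "b"), formula = "C2H4O2", role = "minimum",
                   g_rel = c(0, -1))
  acyc <- free_energy_map(sp, data.frame(id = "r", reactants = "a", products = "b"))
  expect_equal(nrow(hess_cycle_residuals(acyc)), 0)
  # perturbing one reaction's stored dG by +0.5 shows up as a 0.5 residual
  tri <- toy_triangle_map()
  dg <- vapply(tri$reactions$id, function(id) reaction_delta_g(tri, id), numeric(1))
  dg[2] <- dg[2] + 0.5
  tri$reactions$delta_g <- unname(dg)
  cyc2 <- hess_cycle_residuals(tri)
  expect_equal(max(abs(cyc2$residual)), 0.5, tolerance = 1e-12)
})

test_that("the variant ledger reports ddG and barrier differences", {
  m <- fixture_map()
  led <- variant_ledger(m, data.frame(base = "r_aldol_7ec17",
                                      variant = "r_aldol_7ec16",
                                      label = "SO2-eliminating aldol"))
  # TS pair +19.3 vs +5.3: barrier reduced by 14.0
  expect_kcal(led$ddG_ts, -14.0)
  # threose retro-aldol vs non-sulfur: the ledger compares overall dGs
  led2 <- variant_ledger(m, data.frame(base = "r_retro_29thr", variant = "r_retro_thr"))
  expect_true(is.finite(led2$ddG))
  # identity correspondence: all zeros
  led3 <- variant_ledger(m, data.frame(base = "r_add_7", variant = "r_add_7"))
  expect_equal(led3$ddG, 0)
  expect_equal(led3$ddG_ts, 0)
  expect_error(variant_ledger(m, data.frame(base = "r_add_7", variant = "zzz")),
               "unmatched")
})

test_that("map construction enforces the transition-state invariants", {
  sp <- data.frame(id = c("a", "b", "ts1"), formula = "C2H4O2",
                   role = c("minimum", "minimum", "transition_state"),
                   g_rel = c(0, -1, 10))
  # ts attached to one reaction: fine
  good <- free_energy_map(sp, data.frame(id = "r", reactants = "a",
                                         products = "b", ts_id = "ts1"))
  expect_s3_class(good, "fe_map")
  # orphan TS rejected
  expect_error(free_energy_map(sp, data.frame(id = "r", reactants = "a",
                                              products = "b")),
               "not attached")
  # ts_id pointing at a minimum rejected
  expect_error(free_energy_map(sp, data.frame(id = "r", reactants = "a",
                                              products = "b", ts_id = "b")),
               "non-transition-state")
  # one TS on two reactions rejected
  rx <- data.frame(id = c("r1", "r2"), reactants = "a", products = "b",
                   ts_id = "ts1")
  expect_error(free_energy_map(sp, rx), "more than one")
})

test_that("audit passes the fixture at printed-rounding tolerance", {
  audit <- audit_map(fixture_map(), tol = 0.15)
  expect_true(audit$ok)
  expect_lte(audit$max_residual, 0.15)
  # the single flagged printed discrepancy is reported but does not fail
  expect_equal(audit$printed_mismatch$id, "r_aldol_1721")
  expect_equal(audit$printed_mismatch$flag, "printed_arithmetic_discrepancy")
})
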