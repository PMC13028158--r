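test_that("Eyring rates: prefactor, worked value, RT*ln10 decade rule", {
  # dG^ = 0 gives the bare prefactor k_B T / h
  expect_equal(eyring_rate(0), 6.212e12, tolerance = 1e-3)
  # the +5.2 kcal/mol O-attack barrier
  expect_equal(eyring_rate(5.2), 9.6e8, tolerance = 0.01)
  # +RT*ln10 divides the rate by exactly ten
  rt_ln10 <- R_KCAL * 298.15 * log(10)
  for (b in c(0, 5.2, 18.6, 27.5)) {
    expect_equal(eyring_rate(b + rt_ln10) / eyring_rate(b), 0.1,
                 tolerance = 1e-12)
  }
  expect_error(eyring_rate(5, temperature = 0), "temperature")
})

test_that("rate models obey detailed balance and the molecularity rule", {
  tri <- toy_triangle_map()
  model <- build_rate_model(tri, initial = c(A = 1))
  RT <- R_KCAL * 298.15
  for (i in seq_len(nrow(model$steps))) {
    expect_equal(model$steps$k_fwd[i] / model$steps$k_rev[i],
                 exp(-model$steps$delta_g[i] / RT), tolerance = 1e-12)
  }
  # dG = 0 makes forward and reverse equal
  sp <- data.frame(id = c("A", "B"), formula = "C2H4O2", role = "minimum",
                   g_rel = c(-5, -5))
  m0 <- free_energy_map(sp, data.frame(id = "r", reactants = "A", products = "B"))
  mod0 <- build_rate_model(m0, initial = c(A = 1))
  expect_equal(mod0$steps$k_fwd, mod0$steps$k_rev)
  expect_true(mod0$steps$imputed)
  # a three-body step (after clamping) is rejected
  sp3 <- data.frame(id = c("A", "B", "C", "D"),
                    formula = c("CH2O", "CH2O", "CH2O", "C3H6O3"),
                    role = "minimum", g_rel = c(0, 0, 0, -5))
  m3 <- free_energy_map(sp3, data.frame(id = "r", reactants = "A + B + C",
                                        products = "D"))
  expect_error(build_rate_model(m3, initial = c(A = 1)), "molecularity")
  # missing TS with no barrierless policy is an error naming the step
  expect_error(build_rate_model(m0, barrierless_barrier = NA), "\\br\\b")
})

test_that("detailed-balance barrier arithmetic: k_fwd/k_rev from dG, not the TS", {
  m <- fixture_map()
  mod <- build_rate_model(m, "r_add_1O", initial = c("1" = 1),
                          clamped = c("H2O", "H2SO3"))
  RT <- R_KCAL * 298.15
  # dG^_fwd 5.2 with dG -3.0: ratio is exp(+3.0/RT)
  expect_equal(mod$steps$k_fwd / mod$steps$k_rev, exp(3.0 / RT), tolerance = 1e-9)
})

test_that("A<=>B with dG = 0 relaxes to 50/50; zero-rate model stays constant", {
  sp <- data.frame(id = c("A", "B", "ts"), formula = "C2H4O2",
                   role = c("minimum", "minimum", "transition_state"),
                   g_rel = c(-5, -5, 5))
  m <- free_energy_map(sp, data.frame(id = "r", reactants = "A", products = "B",
                                      ts_id = "ts"))
  mod <- build_rate_model(m, initial = c(A = 1))
  k <- mod$steps$k_fwd
  tr <- simulate_kinetics(mod, 20 / k, n_out = 60)
  eq <- tr$conc[, ncol(tr$conc)]
  expect_equal(unname(eq["A"]), 0.5, tolerance = 1e-4)
  expect_equal(unname(eq["B"]), 0.5, tolerance = 1e-4)
  # a model whose only step has an astronomically high barrier is inert
  sp$g_rel[3] <- 80
  m2 <- free_energy_map(sp, data.frame(id = "r", reactants = "A", products = "B",
                                       ts_id = "ts"))
  mod2 <- build_rate_model(m2, initial = c(A = 1))
  tr2 <- simulate_kinetics(mod2, 1, n_out = 10)
  expect_equal(unname(tr2$conc["A", ]), rep(1, length(tr2$time)), tolerance = 1e-9)
})

test_that("closed reversible chain relaxes to the Boltzmann distribution", {
  # detailed-balance oracle: long-time fractions of A<=>B<=>C match the
  # speciation module within 1%
  tri <- toy_triangle_map(gA = -5, gB = -6.2, gC = -4.1, ts_off = 8)
  model <- build_rate_model(tri, reaction_ids = c("rAB", "rBC"),
                            initial = c(A = 1))
  k_slow <- min(model$steps$k_fwd, model$steps$k_rev)
  tr <- simulate_kinetics(model, 50 / k_slow, n_out = 80)
  eq <- tr$conc[, ncol(tr$conc)]
  frac <- eq / sum(eq)
  bd <- boltzmann_distribution(isomer_group(c("A", "B", "C"), exchange = "H2O"), tri)
  expect_equal(unname(frac[bd$id]), bd$fraction, tolerance = 0.01)
})

test_that("trajectories conserve elemental totals including clamped exchange", {
  m <- fixture_map()
  mod <- build_rate_model(m, c("r_add_7", "r_dehyd_8", "r_add_6i"),
                          initial = c("4" = 0.5), clamped = c("H2O", "H2SO3"))
  tr <- simulate_kinetics(mod, 1e3)
  drift <- conservation_drift(tr)
  expect_lt(max(drift), 1e-6)
  expect_named(drift, c("C", "H", "O", "S"))
})

test_that("autocatalysis metrics: exponential pool gives rate r; zero drain leaks 0", {
  # build a fake trajectory with [C2](t) = c*exp(r*t)
  m <- fixture_map()
  mod <- build_rate_model(m, "r_add_7", initial = c("4" = 1),
                          clamped = c("H2O", "H2SO3"))
  tt <- seq(0, 10, length.out = 101)
  r <- 0.37
  conc <- rbind("4" = 0.01 * exp(r * tt), "7" = rep(1, 101))
  traj <- structure(list(time = tt, conc = conc,
                         clamped_net = matrix(0, 2, 101,
                                              dimnames = list(c("H2O", "H2SO3"), NULL)),
                         model = mod, n_steps = 0L), class = "trajectory")
  met <- autocatalysis_metrics(traj, "4", drain_pool = "7", food_pool = "7")
  expect_equal(met$max_per_capita_rate, r, tolerance = 1e-3)
  # no food consumed -> leakage 0 by convention
  expect_equal(met$leakage_fraction, 0)
  expect_error(autocatalysis_metrics(traj, "zzz", "7", "7"), "absent")
})

test_that("integration failure carries a structured error with the last state", {
  sp <- data.frame(id = c("A", "B"), formula = "C2H4O2", role = "minimum",
                   g_rel = c(0, -20))
  m <- free_energy_map(sp, data.frame(id = "r", reactants = "A", products = "B"))
  mod <- build_rate_model(m, initial = c(A = 1))
  err <- tryCatch(simulate_kinetics(mod, 1e6, max_steps = 3L),
                  kinetics_integration_error = function(e) e)
  expect_s3_class(err, "kinetics_integration_error")
  expect_true(is.numeric(err$state) && length(err$state) == 2)
})
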