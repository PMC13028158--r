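# Shared helpers: small hand-built maps and cached fixture.

fixture_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_paper_fixture()
    cache
  }
})

# A tiny consistent triangle map: A <-> B <-> C <-> A plus refs, with a TS
# on each edge. G_rel chosen arbitrarily; all same formula so no refs
# needed in the reactions.
toy_triangle_map <- function(gA = -5, gB = -8, gC = -2, ts_off = 10) {
  sp <- data.frame(
    id = c("A", "B", "C", "tsAB", "tsBC", "tsCA"),
    formula = "C2H4O2",
    role = c(rep("minimum", 3), rep("transition_state", 3)),
    g_rel = c(gA, gB, gC,
              max(gA, gB) + ts_off, max(gB, gC) + ts_off, max(gC, gA) + ts_off))
  rx <- data.frame(id = c("rAB", "rBC", "rCA"),
                   reactants = c("A", "B", "C"),
                   products = c("B", "C", "A"),
                   ts_id = c("tsAB", "tsBC", "tsCA"),
                   category = "other")
  free_energy_map(sp, rx)
}

# absolute-tolerance energy comparison (default: half a printed 0.1 unit)
expect_kcal <- function(actual, expected, tol = 0.05) {
  expect_lt(abs(actual - expected), tol + 1e-12)
}
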