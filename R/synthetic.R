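#' Configuration for the synthetic thermochemistry generator
#'
#' Component energies are drawn from distributions with magnitudes
#' plausible for small neutral CHOS molecules; they are test scaffolding,
#' not science. Transition-state offsets are strictly positive so no
#' generated barrier is submerged.
#'
#' @param n_species Number of non-reference species to generate.
#' @param c_range,s_range Inclusive integer ranges for carbon / sulfur
#'   counts (hydrogen and oxygen are drawn to plausible valence ranges).
#' @param mean_e_zpe,sd_e_zpe Normal parameters for electronic energy +
#'   ZPE, kcal/mol.
#' @param mean_h_corr,sd_h_corr Enthalpy correction, kcal/mol.
#' @param mean_s_gas,sd_s_gas Gas-phase entropy, kcal/(mol K); values are
#'   taken as absolute, so entropies are strictly positive.
#' @param mean_g_solv,sd_g_solv Solvation free energy, kcal/mol.
#' @param ts_offset_min,ts_offset_mean TS `G_rel` offset above the higher
#'   of reactant/product sums: `min + Exponential(mean)`.
#' @param seed Integer seed; the generator is reproducible for fixed seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_species = 20L,
                             c_range = c(1L, 6L), s_range = c(0L, 2L),
                             mean_e_zpe = -50, sd_e_zpe = 20,
                             mean_h_corr = 3, sd_h_corr = 1,
                             mean_s_gas = 0.08, sd_s_gas = 0.02,
                             mean_g_solv = -8, sd_g_solv = 4,
                             ts_offset_min = 2, ts_offset_mean = 8,
                             seed = 1L) {
  if (n_species < 0) stop("n_species must be >= 0", call. = FALSE)
  sds <- c(sd_e_zpe, sd_h_corr, sd_s_gas, sd_g_solv)
  if (any(sds < 0)) stop("component sds must be >= 0", call. = FALSE)
  if (ts_offset_min <= 0 || ts_offset_mean <= 0) {
    stop("TS offsets must be > 0", call. = FALSE)
  }
  if (c_range[1] > c_range[2] || c_range[1] < 1L || s_range[1] > s_range[2] ||
      s_range[1] < 0L) {
    stop("degenerate element-count ranges", call. = FALSE)
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a thermodynamically consistent synthetic species set
#'
#' Draws C/H/O/S formulas and component energies for `n_species` species
#' plus the four reference molecules. Each species carries a hidden "true"
#' formation free energy (attribute `"true_grel"`): its electronic energy
#' is back-solved so that the assembled free energy reproduces that value
#' exactly on the reference scale, making the whole set consistent by
#' construction.
#'
#' @param config A [generator_config()].
#' @return Data frame of species (columns `id`, `formula`, `role`,
#'   `e_zpe`, `h_corr`, `s_gas`, `g_solv`) with attributes `true_grel`
#'   (named numeric) and `refs`.
#' @export
generate_species_set <- function(config = generator_config()) {
  set.seed(config$seed)
  refs <- reference_set()
  n <- config$n_species
  draw_comp <- function(k) data.frame(
    h_corr = stats::rnorm(k, config$mean_h_corr, config$sd_h_corr),
    s_gas = abs(stats::rnorm(k, config$mean_s_gas, config$sd_s_gas)) + 1e-6,
    g_solv = stats::rnorm(k, config$mean_g_solv, config$sd_g_solv))
  ref_comp <- draw_comp(4L)
  ref_comp$e_zpe <- stats::rnorm(4L, config$mean_e_zpe, config$sd_e_zpe)
  ref_energy <- vapply(seq_len(4L), function(i) {
    assemble_solution_free_energy(thermo_components(
      ref_comp$e_zpe[i], ref_comp$h_corr[i], ref_comp$s_gas[i], ref_comp$g_solv[i]))
  }, numeric(1))
  names(ref_energy) <- refs$ids
  ref_df <- data.frame(id = refs$ids, formula = refs$formulas, role = "minimum",
                       e_zpe = ref_comp$e_zpe, h_corr = ref_comp$h_corr,
                       s_gas = ref_comp$s_gas, g_solv = ref_comp$g_solv,
                       stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(ref_df, "true_grel") <- stats::setNames(numeric(0), character(0))
    attr(ref_df, "refs") <- refs
    attr(ref_df, "ref_energy") <- ref_energy
    return(ref_df)
  }
  nC <- sample(seq(config$c_range[1], config$c_range[2]), n, replace = TRUE)
  nS <- sample(seq(config$s_range[1], config$s_range[2]), n, replace = TRUE)
  nH <- 2L * sample.int(3L, n, replace = TRUE) + nC  # even-ish, scales with C
  nO <- sample.int(4L, n, replace = TRUE) + 2L * nS
  formulas <- vapply(seq_len(n), function(i) {
    format_formula(c(C = nC[i], H = nH[i], O = nO[i], S = nS[i]))
  }, character(1))
  true_grel <- stats::rnorm(n, -15, 10)
  comp <- draw_comp(n)
  ids <- sprintf("syn%02d", seq_len(n))
  e_zpe <- vapply(seq_len(n), function(i) {
    coefs <- balance_formation(formulas[i], refs)
    target_assembled <- sum(coefs * ref_energy) + true_grel[i]
    # back-solve the electronic term so assembly hits the target exactly
    target_assembled - comp$h_corr[i] + T_STANDARD * 0.5 * comp$s_gas[i] - comp$g_solv[i]
  }, numeric(1))
  out <- rbind(ref_df,
               data.frame(id = ids, formula = formulas, role = "minimum",
                          e_zpe = e_zpe, h_corr = comp$h_corr, s_gas = comp$s_gas,
                          g_solv = comp$g_solv, stringsAsFactors = FALSE))
  attr(out, "true_grel") <- stats::setNames(true_grel, ids)
  attr(out, "refs") <- refs
  attr(out, "ref_energy") <- ref_energy
  out
}

#' Assemble G_rel values for a generated species set
#'
#' @param species_df Output of [generate_species_set()].
#' @param entropy_fraction,temperature Passed to
#'   [assemble_solution_free_energy()].
#' @return Named numeric vector of `G_rel`, kcal/mol (references included,
#'   exactly 0).
#' @export
grel_from_components <- function(species_df, entropy_fraction = 0.5,
                                 temperature = T_STANDARD) {
  refs <- attr(species_df, "refs")
  if (is.null(refs)) refs <- reference_set()
  assembled <- vapply(seq_len(nrow(species_df)), function(i) {
    assemble_solution_free_energy(
      thermo_components(species_df$e_zpe[i], species_df$h_corr[i],
                        species_df$s_gas[i], species_df$g_solv[i]),
      temperature, entropy_fraction)
  }, numeric(1))
  names(assembled) <- species_df$id
  missing_refs <- setdiff(refs$ids, species_df$id)
  if (length(missing_refs)) stop(sprintf(
    "species set lacks reference species: %s", paste(missing_refs, collapse = ", ")),
    call. = FALSE)
  ref_energy <- assembled[refs$ids]
  vapply(seq_len(nrow(species_df)), function(i) {
    compute_grel(species_df$formula[i], assembled[i], refs, ref_energy)
  }, numeric(1)) -> g
  stats::setNames(g, species_df$id)
}

#' Generate an element-balanced reaction network over a species set
#'
#' Reactions are built from formula-conserving combinations: 1-2 randomly
#' chosen species on each side, balanced exactly by adding reference
#' molecules. Each reaction gets a transition-state species whose `G_rel`
#' sits a strictly positive offset above the higher of the reactant and
#' product `G_rel` sums, so no generated barrier is submerged and every
#' Hess cycle closes exactly.
#'
#' @param species_df Output of [generate_species_set()].
#' @param n_reactions Number of reactions to attempt.
#' @param seed Integer seed.
#' @param config A [generator_config()] (for the TS-offset distribution).
#' @return An `fe_map` whose species carry `G_rel` from the assembled
#'   components.
#' @export
generate_network <- function(species_df, n_reactions = 12L, seed = 1L,
                             config = generator_config()) {
  ids <- species_df$id[species_df$role == "minimum"]
  refs <- attr(species_df, "refs")
  if (is.null(refs)) refs <- reference_set()
  ids <- setdiff(ids, refs$ids)
  if (length(ids) < 2L) stop("need at least 2 non-reference species", call. = FALSE)
  g <- grel_from_components(species_df)
  set.seed(seed)
  E <- formula_matrix(species_df$formula)
  colnames(E) <- species_df$id
  sp_rows <- data.frame(id = species_df$id, formula = species_df$formula,
                        role = "minimum", g_rel = unname(g[species_df$id]),
                        provenance = "synthetic", stringsAsFactors = FALSE)
  rx <- list(); ts_rows <- list()
  # closed triads (A->B, B->C, A->C) guarantee Hess cycles to audit;
  # remaining reactions are random formula-conserving combinations
  n_triads <- if (length(ids) >= 3L && n_reactions >= 3L) max(1L, n_reactions %/% 6L) else 0L
  triad_sides <- list()
  for (tr in seq_len(n_triads)) {
    abc <- sample(ids, 3L)
    triad_sides[[length(triad_sides) + 1L]] <- abc[c(1, 2)]
    triad_sides[[length(triad_sides) + 1L]] <- abc[c(2, 3)]
    triad_sides[[length(triad_sides) + 1L]] <- abc[c(1, 3)]
  }
  for (k in seq_len(n_reactions)) {
    if (k <= length(triad_sides)) {
      lhs_ids <- triad_sides[[k]][1]; rhs_ids <- triad_sides[[k]][2]
    } else {
      nl <- sample.int(2L, 1L); nr <- sample.int(2L, 1L)
      lhs_ids <- sample(ids, nl); rhs_ids <- sample(setdiff(ids, lhs_ids), nr)
    }
    v <- rowSums(E[, rhs_ids, drop = FALSE]) - rowSums(E[, lhs_ids, drop = FALSE])
    x <- tryCatch(rat_solve(refs$elements, as.integer(v))$solution,
                  error = function(e) NULL)
    if (is.null(x)) next
    lhs <- stats::setNames(rep(1, length(lhs_ids)), lhs_ids)
    rhs <- stats::setNames(rep(1, length(rhs_ids)), rhs_ids)
    for (j in seq_along(refs$ids)) {
      if (x[j] > 0) lhs[refs$ids[j]] <- x[j]
      if (x[j] < 0) rhs[refs$ids[j]] <- -x[j]
    }
    g_l <- sum(lhs * g[names(lhs)]); g_r <- sum(rhs * g[names(rhs)])
    off <- config$ts_offset_min + stats::rexp(1, 1 / config$ts_offset_mean)
    ts_id <- sprintf("ts%02d", k)
    ts_formula <- format_formula(round(rowSums(E[, rep(names(lhs), lhs), drop = FALSE])))
    ts_rows[[k]] <- data.frame(id = ts_id, formula = ts_formula,
                               role = "transition_state",
                               g_rel = max(g_l, g_r) + off,
                               provenance = "synthetic", stringsAsFactors = FALSE)
    rx[[k]] <- data.frame(id = sprintf("r%02d", k),
                          reactants = format_side(lhs), products = format_side(rhs),
                          ts_id = ts_id, category = "other",
                          stringsAsFactors = FALSE)
  }
  if (!length(rx)) {
    warning("no balanceable combination found; returning empty network")
    return(free_energy_map(species_registry(sp_rows),
                           data.frame(id = character(0), reactants = character(0),
                                      products = character(0)), refs))
  }
  species <- rbind(sp_rows, do.call(rbind, ts_rows))
  free_energy_map(species_registry(species), do.call(rbind, rx), refs)
}

#' Inject a localized thermodynamic inconsistency
#'
#' Shifts the `G_rel` of one species in a strict subset of the reactions it
#' participates in (its "reaction-local copies"): the per-reaction stored
#' `delta_g` values of the affected reactions are displaced by `nu * shift`
#' while the registry keeps the pristine value, so Hess-cycle residuals
#' through the affected reactions become nonzero and the defect is
#' recoverable.
#'
#' @param map An `fe_map` with at least one cycle through a species that
#'   appears in two or more reactions.
#' @param magnitude Injected shift in kcal/mol (nonzero).
#' @param seed Integer seed for choosing the victim.
#' @param audit_tol Audit tolerance used to note sub-threshold injections
#'   (default 0.01 kcal/mol).
#' @return List: `map` (perturbed, with a stored `delta_g` column) and
#'   `record` (class `corruption_record`: `species_id`, `reaction_id`,
#'   `shift`, `seed`, `sub_threshold`).
#' @export
corrupt_map <- function(map, magnitude = 0.5, seed = 1L, audit_tol = 0.01) {
  if (magnitude == 0) stop("shift must be nonzero", call. = FALSE)
  cyc <- hess_cycle_residuals(map)
  if (!nrow(cyc)) stop("acyclic map: injected inconsistency would be undetectable",
                       call. = FALSE)
  set.seed(seed)
  cyc_rxns <- unique(unlist(cyc$members))
  # candidate = (species, reaction) with the species duplicated across
  # reactions and the reaction on a cycle
  N <- stoich_matrix(map)
  n_rxns_of <- rowSums(N != 0)
  cand <- list()
  for (s in setdiff(rownames(N)[n_rxns_of >= 2], map$refs$ids)) {
    for (r in intersect(colnames(N)[N[s, ] != 0], cyc_rxns)) {
      cand[[length(cand) + 1L]] <- c(s, r)
    }
  }
  if (!length(cand)) stop("no species duplicated across reactions on a cycle",
                          call. = FALSE)
  pick <- cand[[sample.int(length(cand), 1L)]]
  s <- pick[1]; r <- pick[2]
  dg <- vapply(map$reactions$id, function(id) reaction_delta_g(map, id), numeric(1))
  j <- match(r, map$reactions$id)
  dg[j] <- dg[j] + N[s, j] * magnitude
  map$reactions$delta_g <- unname(dg)
  rec <- structure(list(species_id = s, reaction_id = r, shift = magnitude,
                        seed = seed, sub_threshold = abs(magnitude) < audit_tol),
                   class = "corruption_record")
  list(map = map, record = rec)
}

#' Localize an injected inconsistency by residual intersection
#'
#' Finds the Hess cycles whose residual exceeds `tol`, intersects their
#' reaction supports to isolate the defective reaction(s), and implicates
#' the non-reference species of those reactions that appear in two or more
#' reactions of the map (only a duplicated species can carry a
#' reaction-local defect). Candidates are ranked by how consistently a
#' single shift in that species explains all residuals.
#'
#' @param map A (possibly corrupted) `fe_map` carrying stored `delta_g`.
#' @param tol Residual tolerance (default 0.01 kcal/mol).
#' @return List: `detected` (logical), `reactions` (candidate defective
#'   reaction ids), `species` (implicated species ids, best first),
#'   `max_residual`.
#' @export
localize_corruption <- function(map, tol = 0.01) {
  cyc <- hess_cycle_residuals(map)
  if (!nrow(cyc)) return(list(detected = FALSE, reactions = character(0),
                              species = character(0), max_residual = 0))
  bad <- cyc[abs(cyc$residual) > tol, , drop = FALSE]
  if (!nrow(bad)) return(list(detected = FALSE, reactions = character(0),
                              species = character(0),
                              max_residual = max(abs(cyc$residual))))
  supp <- Reduce(intersect, bad$members)
  if (!length(supp)) supp <- unique(unlist(bad$members))
  # restrict to reactions whose stored dG actually deviates from the registry
  dev <- vapply(supp, function(id) {
    j <- match(id, map$reactions$id)
    stored <- map$reactions[["delta_g"]][j]
    if (is.na(stored)) 0 else abs(stored - reaction_delta_g(map, id))
  }, numeric(1))
  if (any(dev > tol)) supp <- supp[dev > tol]
  N <- stoich_matrix(map)
  dup <- rownames(N)[rowSums(N != 0) >= 2]
  cand <- character(0)
  for (r in supp) {
    j <- match(r, map$reactions$id)
    sp <- rownames(N)[N[, j] != 0]
    cand <- union(cand, setdiff(intersect(sp, dup), map$refs$ids))
  }
  # score: a shift delta in species s changes reaction r's dG by N[s, r] *
  # delta; keep species for which one delta explains every deviating reaction
  score <- vapply(cand, function(s) {
    deltas <- vapply(supp, function(r) {
      j <- match(r, map$reactions$id)
      stored <- map$reactions[["delta_g"]][j]
      d <- if (is.na(stored)) 0 else stored - reaction_delta_g(map, r)
      if (N[s, j] != 0) d / N[s, j] else NA_real_
    }, numeric(1))
    if (anyNA(deltas)) Inf else max(deltas) - min(deltas)
  }, numeric(1))
  ord <- order(score, cand)
  list(detected = TRUE, reactions = supp, species = cand[ord],
       max_residual = max(abs(cyc$residual)))
}
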