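#' Energy components of a solute at 298.15 K
#'
#' Bundles the four ingredients of a solution-phase free energy in the
#' composition scheme used here: gas-phase electronic energy including the
#' zero-point correction, the temperature-dependent enthalpy correction,
#' the gas-phase entropy (of which a configurable fraction is retained in
#' solution), and the implicit-solvent solvation free energy.
#'
#' @param electronic_plus_zpe Electronic energy + ZPE, kcal/mol.
#' @param enthalpy_correction Thermal enthalpy correction at 298.15 K, kcal/mol.
#' @param gas_entropy Gas-phase entropy, kcal/(mol K); must be >= 0.
#' @param solvation_g Solvation free energy, kcal/mol.
#' @return An object of class `thermo_components`.
#' @export
thermo_components <- function(electronic_plus_zpe, enthalpy_correction,
                              gas_entropy, solvation_g) {
  vals <- c(electronic_plus_zpe = electronic_plus_zpe,
            enthalpy_correction = enthalpy_correction,
            gas_entropy = gas_entropy,
            solvation_g = solvation_g)
  bad <- names(vals)[!is.finite(vals)]
  if (length(bad)) {
    stop(sprintf("non-finite thermo component(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (gas_entropy < 0) stop("gas_entropy must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "thermo_components")
}

#' Assemble a solution-phase free energy from components
#'
#' The free energy is `E_zpe + H_corr - T * f * S_gas + G_solv`, where the
#' entropy fraction `f` encodes the assumption that a solute retains only a
#' fraction (default one half) of its gas-phase entropy in water.
#'
#' @param components A [thermo_components()] object.
#' @param temperature Temperature in kelvin (default 298.15).
#' @param entropy_fraction Fraction of gas-phase entropy retained in
#'   solution, in `[0, 1]` (default 0.5).
#' @return Free energy in kcal/mol.
#' @examples
#' assemble_solution_free_energy(thermo_components(-10, 1, 0.020, -5))
#' @export
assemble_solution_free_energy <- function(components,
                                          temperature = T_STANDARD,
                                          entropy_fraction = 0.5) {
  if (!inherits(components, "thermo_components")) {
    components <- do.call(thermo_components, as.list(components))
  }
  if (!is.finite(temperature) || temperature <= 0) {
    stop("temperature must be > 0", call. = FALSE)
  }
  if (!is.finite(entropy_fraction) || entropy_fraction < 0 || entropy_fraction > 1) {
    stop("entropy_fraction must be in [0, 1]", call. = FALSE)
  }
  with(components,
       electronic_plus_zpe + enthalpy_correction -
         temperature * entropy_fraction * gas_entropy + solvation_g)
}

#' The thermodynamic reference set
#'
#' An ordered basis of reference molecules, each assigned a relative free
#' energy of exactly zero. The default basis is CO2, H2, H2O and H2SO3,
#' which spans every neutral C/H/O/S formula uniquely.
#'
#' @param ids Character vector of reference species ids.
#' @param formulas Character vector of formulas, parallel to `ids`.
#' @return An object of class `reference_set` with the element-count matrix
#'   attached.
#' @export
reference_set <- function(ids = c("CO2", "H2", "H2O", "H2SO3"),
                          formulas = ids) {
  if (length(ids) != length(formulas) || anyDuplicated(ids)) {
    stop("reference set needs unique ids parallel to formulas", call. = FALSE)
  }
  E <- formula_matrix(formulas)
  colnames(E) <- ids
  # basis must make every representable formula uniquely balanceable:
  # the element matrix must have full column rank
  if (qr(E)$rank < ncol(E)) {
    stop("degenerate reference basis: element-count matrix is rank-deficient",
         call. = FALSE)
  }
  structure(list(ids = ids, formulas = formulas, elements = E),
            class = "reference_set")
}

#' Balance the formation reaction of a target formula
#'
#' Finds the exact stoichiometric coefficients `x_r` of the reference
#' species such that `sum_r x_r * ref_r -> target` conserves every element;
#' negative coefficients place the reference on the product side alongside
#' the target. For the default basis this is the unique solution of a 4x4
#' integer linear system (e.g. `2 CO2 + 4 H2 + H2SO3 -> C2H4SO4 + 3 H2O`).
#' Coefficients are computed in exact rational arithmetic.
#'
#' @param target Formula string or element-count vector.
#' @param refs A [reference_set()].
#' @return Named numeric vector of coefficients, one per reference species.
#' @examples
#' balance_formation("C2H4SO4")
#' @export
balance_formation <- function(target, refs = reference_set()) {
  f <- if (is.character(target)) parse_formula(target) else target[ELEMENTS]
  E <- refs$elements
  present <- rowSums(abs(E)) > 0
  if (any(f[!present] > 0)) {
    stop(sprintf("formula contains element(s) outside the reference basis span: %s",
                 paste(ELEMENTS[!present & f > 0], collapse = ", ")), call. = FALSE)
  }
  sol <- rat_solve(E, as.integer(f))
  if (!sol$unique) {
    stop(sprintf("ambiguous reference basis: rank %d < %d references",
                 sol$rank, ncol(E)), call. = FALSE)
  }
  stats::setNames(sol$solution, refs$ids)
}

#' Reference-state relative free energy of a species
#'
#' `G_rel` of a species is the free-energy change of its balanced formation
#' reaction from the reference set, i.e. `G(target) + sum over product-side
#' references - sum over reactant-side references`, using assembled
#' solution-phase free energies. Every reference species has `G_rel = 0`
#' exactly, by construction.
#'
#' @param target_formula Formula string or count vector of the target.
#' @param target_energy Assembled solution free energy of the target, kcal/mol.
#' @param refs A [reference_set()].
#' @param ref_energies Named numeric vector of assembled free energies for
#'   every reference species (names matching `refs$ids`).
#' @return `G_rel` in kcal/mol.
#' @export
compute_grel <- function(target_formula, target_energy,
                         refs = reference_set(), ref_energies) {
  missing_ids <- setdiff(refs$ids, names(ref_energies))
  if (length(missing_ids)) {
    stop(sprintf("missing assembled energies for reference species: %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  if (!is.finite(target_energy)) stop("target energy missing or non-finite", call. = FALSE)
  coefs <- balance_formation(target_formula, refs)
  # formation reaction: reactant side = positive coefs, product side = target
  # plus references with negative coefs
  dG <- target_energy - sum(coefs * ref_energies[refs$ids])
  unname(dG)
}
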