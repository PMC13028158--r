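---
title: "Free-energy maps and microkinetics of the bisulfite formose network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy maps and microkinetics of the bisulfite formose network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formosemap)
```

## The model

`formosemap` analyses the aqueous free-energy landscape of the formose
reaction when SO₂/H₂SO₃ is present to form bisulfite adducts of the sugar
intermediates. The package does not run quantum chemistry; it starts from
solution-phase free energies (either given directly, or assembled from
components) and provides all of the downstream arithmetic, consistency
analysis, speciation and kinetics.

### Free-energy composition

The solution free energy of a solute at temperature $T$ is assembled as

$$G = E_{\mathrm{ZPE}} + H_{\mathrm{corr}} - T \cdot f \cdot S_{\mathrm{gas}} + \Delta G_{\mathrm{solv}}$$

where $E_{\mathrm{ZPE}}$ is the electronic energy including the zero-point
correction, $H_{\mathrm{corr}}$ the 298.15 K thermal enthalpy correction,
$S_{\mathrm{gas}}$ the gas-phase entropy and $\Delta G_{\mathrm{solv}}$ an
implicit-solvent term. The entropy fraction $f$ encodes the assumption
that a solute retains only about half of its gas-phase entropy in water;
it is a tunable parameter (`entropy_fraction`, dimensionless, default 0.5)
rather than a hard-coded constant, because it is a modelling convention,
not a physical law. Temperature defaults to 298.15 K; energies are
kcal/mol throughout, with $R = 1.9872041 \times 10^{-3}$ kcal/(mol K).

### The reference scale

A single species' free energy is meaningless across different
stoichiometries, so every species is mapped to a *relative* free energy
$G_{\mathrm{rel}}$: the $\Delta G$ of its balanced formation reaction from
the reference basis $\{\mathrm{CO_2}, \mathrm{H_2}, \mathrm{H_2O},
\mathrm{H_2SO_3}\}$, each member of which is assigned
$G_{\mathrm{rel}} \equiv 0$. For a formula $\mathrm{C}_{n_C}
\mathrm{H}_{n_H} \mathrm{O}_{n_O} \mathrm{S}_{n_S}$ the balancing system
has the closed-form solution $a = n_C$, $c = n_S$, $d = 2n_C + 3n_S -
n_O$, $b = (n_H + 2d - 2n_S)/2$ for

$$a\,\mathrm{CO_2} + b\,\mathrm{H_2} + c\,\mathrm{H_2SO_3} \rightarrow
  \mathrm{target} + d\,\mathrm{H_2O},$$

but the implementation solves the general linear system in exact rational
arithmetic so that (i) any full-rank basis can be used, (ii) element
conservation is exact rather than floating-point, and (iii) a degenerate
basis is rejected rather than silently pseudo-inverted. Reaction free
energies are then simply $\Delta G = \sum G_{\mathrm{rel}}(\text{products})
- \sum G_{\mathrm{rel}}(\text{reactants})$, with reference species
contributing zero wherever they appear. Water's standard state follows the
map's implicit 1 M-equivalent convention.

### Barriers

Transition states are species with $G_{\mathrm{rel}}$ of their own;
forward and reverse barriers are $G_{\mathrm{rel}}(\mathrm{TS})$ minus the
reactant or product sum, and the identity $\Delta G^{\ddagger}_{f} -
\Delta G^{\ddagger}_{r} = \Delta G$ holds by construction. A transition
state lying *below* its reactants or products (which happens in the map
for the bisulfite ring-shift pathway, where the flanking saddle points sit
marginally below the ring intermediate) yields a structured
`submerged = TRUE` flag instead of a silently negative barrier.

## The packaged map and its provenance discipline

The fixture ships as plain TSV tables
(`inst/extdata/fixture_species.tsv`, `fixture_reactions.tsv`) with a
provenance column on every row. Three anchor classes are distinguished:

* `text` — the value is printed in the source's running text;
* `text-derived` — the value is fixed by printed arithmetic (for example,
  the formaldehyde $G_{\mathrm{rel}} = +2.6$ appears as an operand of a
  printed $\Delta G$ computation, and the two tetrose-aldose adducts
  follow from the printed overall retro-aldol $\Delta G$ values);
* `standin` — the value was published only in a figure that is not part
  of the text corpus this package was built against. Stand-ins are
  synthetic placeholders chosen once to satisfy every printed statement
  that constrains them (inequalities, "more/less stable by x", barrier
  differences) and are clearly labelled; they are excluded from all
  quantitative acceptance checks, and `load_paper_fixture(text_anchored_only
  = TRUE)` drops them entirely.

Two documented source discrepancies are carried rather than resolved: a
printed $\Delta G$ of −1.3 kcal/mol where the $G_{\mathrm{rel}}$ operands
give −1.4 (flag `printed_rounding`), and a printed "−21.8 − (−17.4 + 2.6)
= −7.3" whose operands evaluate to −7.0 (flag
`printed_arithmetic_discrepancy`). The audit reports flagged mismatches
without failing on them; everything else must agree to the 0.15 kcal/mol
accumulated-rounding band implied by values printed to 0.1.

The Cannizzaro panel deserves a note: the five printed $\Delta G$ values
fix only sums of the product $G_{\mathrm{rel}}$ values, leaving one free
anchor. The fixture pins methanol at a stand-in −12.0 kcal/mol; every
printed $\Delta G$ is reproduced exactly regardless of that choice, which
is why the acceptance checks test reaction $\Delta G$s, never stand-in
species values.

## Consistency auditing

Because $G_{\mathrm{rel}}$ is a state function, the signed sum of $\Delta
G$ around any closed cycle of the reaction network must vanish. The cycle
space is computed as the exact rational null space of the stoichiometric
matrix with reactions in lexicographic id order, which makes the reported
basis deterministic. On any map whose $\Delta G$ values are derived from
the registry the residuals are zero to rounding; residuals become
informative when per-reaction $\Delta G$ values are stored independently,
as after corruption injection. `localize_corruption()` intersects the
supports of the violating cycles and then asks which duplicated
non-reference species explains all deviations with a single shift — the
recovery oracle used in the tests.

The synthetic generator (`generate_species_set()`, `generate_network()`)
emulates this world: component energies from normal distributions of
plausible magnitude for small CHOS solutes (electronic + ZPE
$\mathcal{N}(-50, 20)$ kcal/mol, enthalpy correction
$\mathcal{N}(3, 1)$, gas entropy $|\mathcal{N}(0.08, 0.02)|$
kcal/(mol K), solvation $\mathcal{N}(-8, 4)$; these are test scaffolding,
not science), reactions built from formula-conserving combinations closed
by reference species, deliberate reaction triads so that the cycle space
is non-trivial, and transition states offset $2 + \mathrm{Exp}(8)$
kcal/mol above the higher side so no generated barrier is submerged. Each
species carries a hidden true formation value that the assembly pipeline
must recover to $10^{-9}$ kcal/mol — the round-trip oracle. What a green
synthetic test does *not* establish: anything about real thermochemistry;
it establishes the bookkeeping is exact.

## Speciation

Isomer/adduct groups (members interconvertible using only exchange
species at reference activity) are ranked by $G_{\mathrm{rel}}$ and
weighted by $g_i \exp(-\Delta G_i / RT)$ with degeneracy $g_i$ (2 for a
D-species standing in for an enantiomer pair; since every member of the
shipped groups is chiral, the factor cancels there). Groups are closed at
fixed total amount; coupling between groups (e.g. CH₂O consumption
shifting adduct equilibria) is deliberately left to the kinetics module.
The published "within computational uncertainty" caveat for the pentose
panels has no quantitative value to propagate; the speciation report
carries the fixture's 0.1 kcal/mol printing precision instead.

## Kinetics

Rates come from transition-state theory, $k = (k_B T / h)
\exp(-\Delta G^{\ddagger}/RT)$ with transmission coefficient 1 and a 1 M
standard state; reverse rates are set by detailed balance
$k_r = k_f \exp(\Delta G / RT)$, so every closed model relaxes to the
Boltzmann distribution of the speciation module (asserted to 1% in the
tests). Steps lacking a transition state get an imputed barrier
(`barrierless_barrier`, default 2.0 kcal/mol — the magnitude reported for
facile adduct additions; applied above $\max(\Delta G, 0)$ so detailed
balance is preserved) and are labelled `imputed`. The known systematic
barrier uncertainty of such protocols (2–3 kcal/mol) is exposed as a
global `barrier_offset` for sensitivity runs, not silently applied.

Water is always clamped at unit activity; the shipped autocatalysis
scenario also clamps H₂SO₃, representing a 1 M buffered bisulfite pool.
Clamping is what keeps every step at molecularity ≤ 2 (the retro-aldol
`26thr + H₂O → 4 + 4ec + H₂SO₃` is unimolecular forward and bimolecular
reverse once H₂O and H₂SO₃ are buffered). The cumulative net exchange
with each clamped pool is integrated as extra state so elemental totals
close exactly; `conservation_drift()` audits C/H/O/S including that
exchange.

### Numerical choices

No stiff ODE solver is available in the target environment, so the
package implements a 2nd-order L-stable Rosenbrock method (ode23s-type)
with the analytic mass-action Jacobian. Three details matter at the
extreme stiffness of this network (rate constants span ~$10^{-13}$ to
~$10^{11}$):

* the stage matrix $W = I - h\gamma J$ is solved without a condition
  check ($\kappa(W) \sim h \cdot k_{\max}$ is routinely $10^{15}$; errors
  land in strongly damped directions, the standard situation for stiff
  solvers);
* after a step rejection the step size is held for one step, preventing
  grow/reject thrash at the accuracy boundary;
* the linear invariants of the extended system (all elemental totals) are
  restored at output times by a magnitude-weighted projection, so
  conservation holds to rounding while trace species are not polluted by
  the correction.

Defaults are `rtol = 1e-5`, `atol = 1e-9` mol/L (nanomolar absolute
resolution — far below any kinetically meaningful concentration in a
molar-scale scenario); the long-horizon scenario tests use `rtol = 1e-4`
to stay within the test-time budget and state so. The per-capita growth
metric is the log-slope of the pooled concentration between output
points, with relative changes below $10^{-9}$ per interval treated as
unresolved (zero) rather than noise-amplified, and pools below a
micromolar floor (`pool_floor = 1e-6` mol/L) excluded: the relative
"growth" of a vestigial $10^{-10}$ M pool re-equilibrating through
reverse aldol flux is not chemically meaningful autocatalysis.

### The default scenario, and what a green kinetic test means

The source text specifies no concentrations, so the shipped scenario is a
documented choice: 1 M CH₂O food, 0.01 M glycolaldehyde initiator,
buffered 1 M H₂SO₃, `t_end = 3e9` s. At the neutral-pH barriers of the
map the cycle turnover is enolization- and tautomerization-limited
($\Delta G^{\ddagger} = 27.5$ kcal/mol for enolization; the
ketose-to-aldose route runs through a transition state ~31 kcal/mol above
the ketose adduct), so the timescale is geological — consistent with the
chemistry, which requires base catalysis to be fast; the barriers were
*not* adjusted to make the simulation finish sooner.

Two kinetic views are provided, and they answer different questions:

* `fixture_cycle_model()` wires the fully resolved map (adduct
  equilibria, enolization, tautomerization, Cannizzaro drains). It shows
  a positive per-capita C₂ growth phase, but a tiny one (~$10^{-11}$
  s⁻¹): the tautomerization bottleneck throttles the retro-aldol return
  so strongly that reverse-aldol trickle is of comparable magnitude,
  which is itself an honest statement about this landscape at neutral pH.
  Removing the retro-aldol step in this full wiring does *not* silence
  C₂ regeneration, because detailed balance keeps the reverse of the
  C₂+C₁ aldol open.
* `core_cycle_model()` is the constructed oracle for the autocatalysis
  property: the abstract three-station cycle with text-anchored station
  energies, effective 20 kcal/mol aldol barriers, and the published
  retro-aldol numbers ($\Delta G = -5.7$, $\Delta G^{\ddagger} = +18.6$
  for bisulfite; $+2.9$ and ~32 for the non-sulfur analog). Here the
  comparative claims are clean: the bisulfite cycle grows the C₂ pool at
  ~$5\times10^{-3}$ s⁻¹ and halves the food in ~775 s; excising the
  retro-aldol abolishes growth entirely; substituting the non-sulfur
  energetics suppresses it by far more than an order of magnitude.

In both views Cannizzaro leakage under bisulfite stays below 1% of
consumed C₁. Absolute rates and times from these models are not
predictions.

## Design decisions taken where the design was open

* Reverse reactions are never stored; direction is a query-time sign
  flip, preventing double counting in the cycle analysis.
* Enantiomers are represented once (D-series) with a degeneracy
  attribute.
* The enol assignments on the glycolaldehyde side of the retro-aldol
  (which printed value corresponds to the *cis* and which to the *trans*
  enol) are a labelling choice; the *cis* form was taken as the lower one
  by analogy with the printed *cis*/*trans* ordering of the C₂ adduct
  enols.
* Group/config files use a small documented YAML subset parsed
  in-package; scenario and metric outputs are JSON via `jsonlite`
  (full precision), while human-readable reports print energies to 0.1
  kcal/mol, the precision of the source values.
* `scripts/acceptance.R` has no numeric targets to report (the target
  list for this artifact is empty); it re-runs the pipeline end to end
  and writes an empty JSON object, failing loudly rather than reporting
  stale numbers.

## Known limitations

* Figure-only energies are stand-ins (clearly labelled); rankings that
  depend on them (e.g. the relative order *within* the stand-in pentoses)
  are illustrative, not source-anchored.
* No pH dependence: all barriers are the neutral-condition values; the
  alkaline formose regime would lower enolization barriers dramatically
  and is outside scope.
* No activity coefficients, no conformer/anomer enumeration beyond the
  species present in the map, and no automatic reaction generation from
  structures.
* The integrator is adequate for desk-scale networks (tens of species);
  it is dense-linear-algebra based and not intended for hundreds of
  species.
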