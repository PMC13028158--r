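#' Physical constants used throughout the package
#'
#' All energies are carried in kcal/mol, entropies in kcal/(mol K),
#' temperatures in kelvin. `R_KCAL` is the molar gas constant in
#' kcal/(mol K); `KB_SI` and `PLANCK_SI` are the Boltzmann and Planck
#' constants in SI units (used only inside the Eyring prefactor).
#'
#' @format Named numeric constants.
#' @name constants
NULL

#' @rdname constants
#' @export
R_KCAL <- 1.9872041e-3

#' @rdname constants
#' @export
T_STANDARD <- 298.15

KB_SI <- 1.380649e-23
PLANCK_SI <- 6.62607015e-34

ELEMENTS <- c("C", "H", "O", "S")
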