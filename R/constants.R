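#' Physical constants used by the engine
#'
#' CODATA values, the single source of truth for all unit conversions in the
#' package. Internally every energy is carried in joules per molecule;
#' positions are Angstrom and dipole moments Debye at the interfaces, and
#' reported energies are kcal/mol.
#'
#' @return Named list with elements `eps0` (vacuum permittivity,
#'   C^2 J^-1 m^-1), `kb` (Boltzmann constant, J/K), `gas_constant`
#'   (J mol^-1 K^-1), `avogadro` (mol^-1), `debye_to_si` (C m per Debye),
#'   `kcal` (J per kcal) and `angstrom` (m per Angstrom).
#' @examples
#' physical_constants()$kb
#' @export
physical_constants <- function() {
  list(
    eps0 = 8.8541878128e-12,
    kb = 1.380649e-23,
    gas_constant = 8.31446261815324,
    avogadro = 6.02214076e23,
    debye_to_si = 3.33564e-30,
    kcal = 4184,
    angstrom = 1e-10
  )
}

.const <- physical_constants()

#' Convert joules per molecule to kcal/mol
#'
#' @param x energy in J per molecule.
#' @return energy in kcal/mol.
#' @export
joule_to_kcalmol <- function(x) x * .const$avogadro / .const$kcal

#' Convert kcal/mol to joules per molecule
#'
#' @param x energy in kcal/mol.
#' @return energy in J per molecule.
#' @export
kcalmol_to_joule <- function(x) x * .const$kcal / .const$avogadro

# molar mass (g/mol) -> kg per molecule
.mass_kg <- function(mass_gmol) mass_gmol * 1e-3 / .const$avogadro
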