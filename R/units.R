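# Coherent internal unit system: Angstrom, femtosecond, amu, Kelvin,
# kcal/mol, elementary charge. Everything else is derived from these.

#' Physical constants of the internal unit system
#'
#' The package works in a single coherent unit system (Angstrom, fs, amu, K,
#' kcal/mol, elementary charge). `unit_constants()` returns the conversion
#' factors used throughout, so user code and tests can share exactly the same
#' numbers.
#'
#' @return Named list with elements:
#'   \describe{
#'     \item{kB}{Boltzmann constant, kcal/(mol K).}
#'     \item{coulomb}{Electrostatic constant 1/(4 pi eps0), kcal Angstrom/(mol e^2).}
#'     \item{acc}{Acceleration conversion: 1 kcal/(mol Angstrom amu) in Angstrom/fs^2.}
#'     \item{ev}{1 eV in kcal/mol.}
#'     \item{freq_cm}{Wavenumber of a mode with unit mass-weighted curvature:
#'       sqrt(1 kcal/(mol Angstrom^2 amu)) expressed in cm^-1.}
#'     \item{kB_si}{Boltzmann constant, J/K (for Eyring prefactors in s^-1).}
#'     \item{planck_si}{Planck constant, J s.}
#'   }
#' @examples
#' unit_constants()$kB * 300  # thermal energy at 300 K in kcal/mol
#' @export
unit_constants <- function() {
  list(
    kB = 1.987204e-3,
    coulomb = 332.0637,
    acc = 4.184e-4,
    ev = 23.0609,
    freq_cm = 108.5915,
    kB_si = 1.380649e-23,
    planck_si = 6.62607015e-34
  )
}

.kB <- 1.987204e-3
.COULOMB <- 332.0637
.ACC <- 4.184e-4
.EV <- 23.0609
# sqrt(4184 / NA / 1e-20 / amu) / (2 pi c): converts sqrt(kcal/(mol A^2 amu))
# to cm^-1.  Derived from CODATA values; see unit_constants().
.FREQ_CM <- 108.5915

# IUPAC 2021 standard atomic weights (abridged), amu.
.ELEMENT_MASSES <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933,
  Ni = 58.693, Cu = 63.546, Zn = 65.38, Se = 78.971, Br = 79.904, I = 126.90
)

#' Atomic mass lookup
#'
#' @param element Character vector of element symbols (case-sensitive, e.g.
#'   `"Mn"`).
#' @return Numeric vector of masses in amu. Unknown symbols are an error, not
#'   a silent default.
#' @export
element_mass <- function(element) {
  m <- .ELEMENT_MASSES[element]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}
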