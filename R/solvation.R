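# Continuum-solvation and interaction-energy bookkeeping: Born cavity
# correction, four-component solvation decomposition, binding energy, and
# the three-body synergy energy of enzyme-metal-substrate complexes.

#' Born-model solvation parameters
#'
#' @param epsilon Solvent dielectric constant (>= 1); default 78.39, water at
#'   300 K.
#' @param q Solute net charge, elementary charges.
#' @param r_cav Cavity radius, Angstrom (> 0).
#' @return Object of class `solvation_parameters`.
#' @export
solvation_parameters <- function(epsilon = 78.39, q = 1, r_cav = 2) {
  if (epsilon < 1) stop("epsilon must be >= 1")
  if (r_cav <= 0) stop("r_cav must be > 0")
  structure(list(epsilon = epsilon, q = q, r_cav = r_cav),
            class = "solvation_parameters")
}

#' Born continuum solvation free energy
#'
#' Electrostatic free energy of transferring a point charge `q` in a
#' spherical cavity of radius `r_cav` from vacuum into a dielectric
#' `epsilon`: `-1/2 (1 - 1/epsilon) q^2 / (4 pi eps0 r_cav)`. Always
#' stabilizing (<= 0), vanishing for `epsilon = 1` or `q = 0`.
#'
#' @param params A [solvation_parameters()] object.
#' @return Solvation free energy, kcal/mol.
#' @examples
#' born_solvation(solvation_parameters(78.39, q = 1, r_cav = 2))
#' @export
born_solvation <- function(params) {
  stopifnot(inherits(params, "solvation_parameters"))
  -0.5 * (1 - 1 / params$epsilon) * params$q^2 * .COULOMB / params$r_cav
}

#' Four-component solvation decomposition
#'
#' Bookkeeping of a total solvation free energy as electrostatic + cavity
#' formation + dispersion + repulsion (the decomposition reported by SMD-type
#' continuum models). The components are user- or generator-supplied; no
#' continuum solver is run.
#'
#' @param elec,cav,disp,rep Component free energies, kcal/mol.
#' @return An [energy_breakdown()] with the sum in its `solvation` slot and
#'   the individual components as attribute `"solvation_components"`.
#' @export
solvation_decomposition <- function(elec, cav, disp, rep) {
  comp <- c(elec = elec, cav = cav, disp = disp, rep = rep)
  if (!all(is.finite(comp))) stop("solvation components must be finite")
  out <- energy_breakdown(solvation = sum(comp))
  attr(out, "solvation_components") <- comp
  out
}

#' Substrate-catalyst binding energy
#'
#' `E_bind = E_complex - (E_enzyme + E_substrate)`: zero for non-interacting
#' parts, negative for favourable binding.
#'
#' @param e_complex,e_enzyme,e_substrate Single-point energies, kcal/mol.
#' @return Binding energy, kcal/mol.
#' @export
binding_energy <- function(e_complex, e_enzyme, e_substrate) {
  stopifnot(is.finite(e_complex), is.finite(e_enzyme), is.finite(e_substrate))
  e_complex - (e_enzyme + e_substrate)
}

#' Enzyme-metal synergy energy
#'
#' The non-additive stabilization of the full enzyme-metal-substrate complex
#' beyond the pairwise enzyme-substrate and metal-substrate interactions:
#' `E_syn = E(EMS) - E(ES) - E(MS) + E(S)`. Identically zero for any
#' pairwise-additive energy model; negative values mean genuine three-body
#' (synergistic) stabilization.
#'
#' @param e_ems Energy of the enzyme-metal-substrate complex, kcal/mol.
#' @param e_es Energy of the enzyme-substrate complex.
#' @param e_ms Energy of the metal-substrate complex.
#' @param e_s Energy of the free substrate.
#' @return Synergy energy, kcal/mol.
#' @examples
#' synergy_energy(-27.6 - 10, -8, -2, 0)
#' @export
synergy_energy <- function(e_ems, e_es, e_ms, e_s) {
  stopifnot(is.finite(e_ems), is.finite(e_es), is.finite(e_ms), is.finite(e_s))
  e_ems - e_es - e_ms + e_s
}
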