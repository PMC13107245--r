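# Elementary geometry on Cartesian triples, plus the coordination-shell
# observables (Gaussian-smoothed coordination number, screened effective
# charge) evaluated on toy systems.

#' Euclidean distance between two points
#'
#' @param a,b Numeric length-3 position vectors, Angstrom.
#' @return Distance in Angstrom.
#' @examples
#' distance(c(0, 0, 0), c(0, 0, 2.08))  # ideal Mn-O bond length
#' @export
distance <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("distance: inputs must be finite")
  sqrt(sum((a - b)^2))
}

#' Bond angle at an apex
#'
#' Angle between the vectors apex -> tail1 and apex -> tail2, e.g. the
#' His-Mn-Ser angle of a catalytic triad with the metal at the apex.
#'
#' @param tail1,tail2 Position triples of the two outer atoms.
#' @param apex Position triple of the central atom.
#' @return Angle in degrees, in \[0, 180\].
#' @export
bond_angle <- function(tail1, apex, tail2) {
  v1 <- tail1 - apex
  v2 <- tail2 - apex
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("bond_angle: degenerate geometry (zero-length vector at apex)")
  cosang <- sum(v1 * v2) / (n1 * n2)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Signed dihedral (torsion) angle
#'
#' Torsion about the p2-p3 axis with the right-handed sign convention:
#' 0 for a planar cis arrangement, 180 for trans, signed in (-180, 180\].
#'
#' @param p1,p2,p3,p4 Position triples.
#' @return Signed angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("dihedral: degenerate geometry (three consecutive points collinear)")
  b2n <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2n)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Gaussian-smoothed coordination number
#'
#' Each ligand contributes `exp(-(Ri - r0)^2 / (2 sigma^2))`, where `Ri` is
#' its distance from the metal center: a ligand exactly at the ideal bond
#' length counts 1, and the contribution decays smoothly with displacement.
#' The sum over the shell is a differentiable stand-in for the integer
#' coordination count (four ideal Mn-O ligands give exactly 4).
#'
#' @param system A [toy_system()].
#' @param model A [coordination_model()].
#' @return Dimensionless coordination count.
#' @export
coordination_number <- function(system, model) {
  stopifnot(inherits(model, "coordination_model"))
  if (model$sigma <= 0) stop("coordination_number: sigma must be > 0")
  idx <- c(model$center, model$ligands)
  if (any(idx < 1) || any(idx > n_atoms(system)))
    stop("coordination_number: atom index out of range")
  if (length(model$ligands) == 0) return(0)
  center <- system$positions[model$center, ]
  d2 <- colSums((t(system$positions[model$ligands, , drop = FALSE]) - center)^2)
  ri <- sqrt(d2)
  sum(exp(-(ri - model$r0)^2 / (2 * model$sigma^2)))
}

#' Screened effective charge of a metal center
#'
#' Sums the ligand partial charges screened exponentially with distance,
#' `sum_i Zi exp(-k ri) / (4 pi eps0 ri)`, with the electrostatic constant of
#' the internal unit system (1/(4 pi eps0) = 332.0637 kcal Angstrom/(mol e^2)).
#' A descriptor of how strongly the coordination shell polarizes the metal;
#' linear in the ligand charges and invariant under rigid motions.
#'
#' @param system A [toy_system()].
#' @param model A [coordination_model()]; `model$k` is the attenuation
#'   coefficient in 1/Angstrom.
#' @return Charge-like scalar (see Details for units).
#' @details The screened form mixes a potential-like kernel with a charge
#'   label, so its absolute units are conventional; only its internal
#'   consistency (linearity, rigid-motion invariance, distance decay)
#'   matters for the analyses in this package.
#' @export
effective_charge <- function(system, model) {
  stopifnot(inherits(model, "coordination_model"))
  if (length(model$ligands) == 0) return(0)
  idx <- c(model$center, model$ligands)
  if (any(idx < 1) || any(idx > n_atoms(system)))
    stop("effective_charge: atom index out of range")
  center <- system$positions[model$center, ]
  ri <- sqrt(colSums((t(system$positions[model$ligands, , drop = FALSE]) - center)^2))
  if (any(ri == 0))
    stop("effective_charge: geometry error, ligand coincident with center")
  zi <- system$charges[model$ligands]
  sum(zi * exp(-model$k * ri) * .COULOMB / ri)
}
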