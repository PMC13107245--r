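#' Construct a toy molecular system
#'
#' The universal input object of the package: an ordered set of atoms with
#' Cartesian coordinates, masses, partial charges and optional bonded
#' topology. It stands in for the enzyme-metal-substrate complexes whose
#' geometry, energetics and dynamics the other modules analyse.
#'
#' @param elements Character vector of element symbols.
#' @param positions Numeric matrix, one row per atom, columns x, y, z in
#'   Angstrom.
#' @param masses Numeric vector of atomic masses (amu); looked up from the
#'   built-in element table when `NULL`.
#' @param charges Numeric vector of partial charges (e); recycled.
#' @param labels Character role tags (e.g. `"O-Asp224"`); defaults to the
#'   element symbols.
#' @param bonds Integer matrix with two columns of 1-based atom indices, or
#'   `NULL`.
#' @param angles Integer matrix with three columns (i, apex j, k), or `NULL`.
#' @param dihedrals Integer matrix with four columns, or `NULL`.
#' @param box_length Scalar periodic box edge in Angstrom, or `NULL` for a
#'   non-periodic system (the default; toy complexes are gas-phase clusters).
#' @return An object of class `toy_system`.
#' @examples
#' water <- toy_system(
#'   elements = c("O", "H", "H"),
#'   positions = rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
#'   bonds = rbind(c(1, 2), c(1, 3)),
#'   angles = rbind(c(2, 1, 3))
#' )
#' n_atoms(water)
#' @export
toy_system <- function(elements, positions, masses = NULL, charges = 0,
                       labels = elements, bonds = NULL, angles = NULL,
                       dihedrals = NULL, box_length = NULL) {
  elements <- as.character(elements)
  n <- length(elements)
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (nrow(positions) != n)
    stop("positions must have one row per atom (", n, " expected)")
  if (n > 0 && !all(is.finite(positions)))
    stop("all position components must be finite")
  if (is.null(masses)) {
    masses <- if (n > 0) element_mass(elements) else numeric(0)
  }
  masses <- rep_len(as.numeric(masses), n)
  if (any(masses <= 0)) stop("all masses must be > 0")
  charges <- rep_len(as.numeric(charges), n)
  labels <- rep_len(as.character(labels), n)

  bonds <- .check_topology(bonds, 2L, n, "bonds")
  angles <- .check_topology(angles, 3L, n, "angles")
  dihedrals <- .check_topology(dihedrals, 4L, n, "dihedrals")
  if (!is.null(box_length)) {
    box_length <- as.numeric(box_length)
    if (length(box_length) != 1L || !is.finite(box_length) || box_length <= 0)
      stop("box_length must be a positive scalar or NULL")
  }

  structure(
    list(elements = elements, positions = positions, masses = masses,
         charges = charges, labels = labels, bonds = bonds, angles = angles,
         dihedrals = dihedrals, box_length = box_length),
    class = "toy_system"
  )
}

.check_topology <- function(x, width, n_atoms, what) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0) || length(x) == 0)
    return(matrix(integer(0), ncol = width))
  x <- matrix(as.integer(x), ncol = width)
  if (any(x < 1L) || any(x > n_atoms))
    stop(what, ": atom index out of range 1..", n_atoms)
  if (width >= 2L) {
    for (r in seq_len(nrow(x)))
      if (anyDuplicated(x[r, ])) stop(what, ": repeated atom index in entry ", r)
  }
  if (width == 2L) {
    key <- paste(pmin(x[, 1], x[, 2]), pmax(x[, 1], x[, 2]))
    if (anyDuplicated(key))
      stop("bonds: duplicate bond (pair order ignored)")
  }
  x
}

#' @rdname toy_system
#' @param system A `toy_system`.
#' @export
n_atoms <- function(system) length(system$elements)

#' @export
print.toy_system <- function(x, ...) {
  cat("<toy_system> ", n_atoms(x), " atoms",
      if (nrow(x$bonds)) paste0(", ", nrow(x$bonds), " bonds"),
      if (!is.null(x$box_length)) paste0(", box ", format(x$box_length), " A"),
      "\n", sep = "")
  if (n_atoms(x) > 0) {
    tab <- table(x$elements)
    cat("  composition:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Metal-coordination model parameters
#'
#' Holds the geometric parameters of a metal coordination shell: the central
#' ion, its candidate ligand atoms, the ideal metal-ligand bond length `r0`,
#' the bond-length spread `sigma` of the Gaussian-smoothed coordination count,
#' and the screening (attenuation) coefficient `k` of the effective-charge
#' model. Defaults are the Mn-O values used for the CALB-Mn active site:
#' r0 = 2.08 Angstrom, sigma = 0.05 Angstrom, k = 1.2 1/Angstrom.
#'
#' @param center Index of the metal atom.
#' @param ligands Integer vector of ligand atom indices.
#' @param r0 Ideal metal-ligand bond length, Angstrom.
#' @param sigma Bond-length spread, Angstrom; must be > 0.
#' @param k Attenuation coefficient, 1/Angstrom; must be >= 0.
#' @return An object of class `coordination_model`.
#' @seealso [coordination_number()], [effective_charge()]
#' @export
coordination_model <- function(center, ligands, r0 = 2.08, sigma = 0.05,
                               k = 1.2) {
  center <- as.integer(center)
  ligands <- as.integer(ligands)
  if (length(center) != 1L) stop("center must be a single atom index")
  if (r0 <= 0) stop("r0 must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (k < 0) stop("k must be >= 0")
  structure(list(center = center, ligands = ligands, r0 = r0,
                 sigma = sigma, k = k),
            class = "coordination_model")
}
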