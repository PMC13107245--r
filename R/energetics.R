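# Toy molecular-mechanics force field. Harmonic terms carry no 1/2 factor
# (CHARMM convention): E_bond = Kb (r - r0)^2, E_angle = Ktheta (th - th0)^2,
# E_dihedral = Kphi (1 + cos(n phi - delta)), LJ = A/r^12 - B/r^6, plus
# optional point-charge Coulomb with the declared electrostatic constant.

#' Component-wise energy record
#'
#' A named energy decomposition whose `total` is always the sum of its
#' components. Molecular-mechanics evaluation fills the bonded and nonbonded
#' slots; solvation and interaction-decomposition bookkeeping fill
#' `solvation`, `hydrogen_bond` and `van_der_waals`.
#'
#' @param bond,angle,dihedral,lennard_jones,electrostatic,hydrogen_bond,van_der_waals,solvation
#'   Component energies, kcal/mol.
#' @return Object of class `energy_breakdown`.
#' @export
energy_breakdown <- function(bond = 0, angle = 0, dihedral = 0,
                             lennard_jones = 0, electrostatic = 0,
                             hydrogen_bond = 0, van_der_waals = 0,
                             solvation = 0) {
  comp <- c(bond = bond, angle = angle, dihedral = dihedral,
            lennard_jones = lennard_jones, electrostatic = electrostatic,
            hydrogen_bond = hydrogen_bond, van_der_waals = van_der_waals,
            solvation = solvation)
  if (!all(is.finite(comp))) stop("energy components must be finite")
  structure(c(as.list(comp), list(total = sum(comp))),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  comp <- unlist(x[setdiff(names(x), "total")])
  comp <- comp[comp != 0]
  cat("<energy_breakdown> total", format(x$total, digits = 6), "kcal/mol\n")
  for (nm in names(comp))
    cat(sprintf("  %-14s %12.6f\n", nm, comp[[nm]]))
  invisible(x)
}

#' Force-field parameter set
#'
#' Parameters are matched to the topology entries of a [toy_system()] by atom
#' indices (order-insensitive for bonds, reversible for angles and
#' dihedrals). Nonbonded terms act on all atom pairs except the excluded
#' ones; by default 1-2 (bonded) and 1-3 pairs are excluded and 1-4 pairs
#' are kept at full strength.
#'
#' @param bonds `data.frame(i, j, kb, r0)`: force constant kcal/(mol A^2),
#'   equilibrium length Angstrom.
#' @param angles `data.frame(i, j, k, ktheta, theta0)`: apex is `j`; force
#'   constant kcal/(mol rad^2), equilibrium angle radians.
#' @param dihedrals `data.frame(i, j, k, l, kphi, n, delta)`: barrier
#'   kcal/mol, integer multiplicity `n >= 1`, phase radians.
#' @param lj `data.frame(i, j, a, b)`: per-pair Lennard-Jones A
#'   (kcal A^12/mol) and B (kcal A^6/mol) overrides.
#' @param lj_default Length-2 numeric `c(a, b)` applied to every non-excluded
#'   pair without an explicit `lj` row, or `NULL` for no default LJ.
#' @param coulomb If `TRUE`, add point-charge electrostatics over
#'   non-excluded pairs using the system's partial charges.
#' @param exclusions Character subset of `c("12", "13")`.
#' @return Object of class `force_field`.
#' @export
force_field <- function(bonds = NULL, angles = NULL, dihedrals = NULL,
                        lj = NULL, lj_default = NULL, coulomb = FALSE,
                        exclusions = c("12", "13")) {
  chk <- function(df, cols, what) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df)
    if (!all(cols %in% names(df)))
      stop(what, " must have columns ", paste(cols, collapse = ", "))
    df
  }
  bonds <- chk(bonds, c("i", "j", "kb", "r0"), "bonds")
  angles <- chk(angles, c("i", "j", "k", "ktheta", "theta0"), "angles")
  dihedrals <- chk(dihedrals, c("i", "j", "k", "l", "kphi", "n", "delta"),
                   "dihedrals")
  lj <- chk(lj, c("i", "j", "a", "b"), "lj")
  if (!is.null(bonds) && any(bonds$kb < 0)) stop("kb must be >= 0")
  if (!is.null(angles) && any(angles$ktheta < 0)) stop("ktheta must be >= 0")
  if (!is.null(dihedrals) && any(dihedrals$n < 1)) stop("n must be >= 1")
  if (!is.null(lj) && (any(lj$a < 0) || any(lj$b < 0)))
    stop("lj a and b must be >= 0")
  if (!is.null(lj_default)) {
    lj_default <- as.numeric(lj_default)
    if (length(lj_default) != 2 || any(lj_default < 0))
      stop("lj_default must be c(a, b) with a, b >= 0")
  }
  if (!all(exclusions %in% c("12", "13")))
    stop("exclusions must be a subset of c('12', '13')")
  structure(list(bonds = bonds, angles = angles, dihedrals = dihedrals,
                 lj = lj, lj_default = lj_default, coulomb = isTRUE(coulomb),
                 exclusions = exclusions),
            class = "force_field")
}

.pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

# excluded pairs from the bond graph: 1-2 = bonded, 1-3 = two bonds apart
.excluded_pairs <- function(system, exclusions) {
  keys <- character(0)
  b <- system$bonds
  if (nrow(b) == 0) return(keys)
  if ("12" %in% exclusions) keys <- c(keys, .pair_key(b[, 1], b[, 2]))
  if ("13" %in% exclusions) {
    nbr <- split(c(b[, 2], b[, 1]), c(b[, 1], b[, 2]))
    for (j in names(nbr)) {
      nb <- unique(nbr[[j]])
      if (length(nb) >= 2) {
        cmb <- utils::combn(nb, 2)
        keys <- c(keys, .pair_key(cmb[1, ], cmb[2, ]))
      }
    }
  }
  unique(keys)
}

# non-excluded pair table with LJ parameters and charges resolved
.nonbonded_pairs <- function(system, params) {
  n <- n_atoms(system)
  if (n < 2) return(NULL)
  cmb <- utils::combn(n, 2)
  i <- cmb[1, ]; j <- cmb[2, ]
  key <- .pair_key(i, j)
  drop <- key %in% .excluded_pairs(system, params$exclusions)
  i <- i[!drop]; j <- j[!drop]; key <- key[!drop]
  if (length(i) == 0) return(NULL)
  a <- b <- rep(0, length(i))
  if (!is.null(params$lj_default)) {
    a[] <- params$lj_default[1]
    b[] <- params$lj_default[2]
  }
  if (!is.null(params$lj)) {
    m <- match(key, .pair_key(params$lj$i, params$lj$j))
    hit <- !is.na(m)
    a[hit] <- params$lj$a[m[hit]]
    b[hit] <- params$lj$b[m[hit]]
  }
  list(i = i, j = j, a = a, b = b)
}

#' Molecular-mechanics energy of a toy system
#'
#' Evaluates the toy force field (bond + angle + dihedral + Lennard-Jones
#' + optional Coulomb) on the system's topology and returns the component
#' breakdown. Every topology entry must have a matching parameter row.
#'
#' @param system A [toy_system()] carrying the topology.
#' @param params A [force_field()].
#' @return An [energy_breakdown()] in kcal/mol.
#' @export
mm_total_energy <- function(system, params) {
  stopifnot(inherits(system, "toy_system"), inherits(params, "force_field"))
  pos <- system$positions
  e_bond <- e_angle <- e_dih <- e_lj <- e_coul <- 0

  if (nrow(system$bonds) > 0) {
    pb <- params$bonds
    if (is.null(pb)) stop("parameterization error: no bond parameters supplied")
    m <- match(.pair_key(system$bonds[, 1], system$bonds[, 2]),
               .pair_key(pb$i, pb$j))
    if (anyNA(m))
      stop("parameterization error: no bond parameters for atoms ",
           paste(system$bonds[which(is.na(m))[1], ], collapse = "-"))
    d <- pos[system$bonds[, 1], , drop = FALSE] -
         pos[system$bonds[, 2], , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    e_bond <- sum(pb$kb[m] * (r - pb$r0[m])^2)
  }

  if (nrow(system$angles) > 0) {
    pa <- params$angles
    if (is.null(pa)) stop("parameterization error: no angle parameters supplied")
    akey <- function(i, j, k) paste(pmin(i, k), j, pmax(i, k))
    m <- match(akey(system$angles[, 1], system$angles[, 2], system$angles[, 3]),
               akey(pa$i, pa$j, pa$k))
    if (anyNA(m))
      stop("parameterization error: no angle parameters for atoms ",
           paste(system$angles[which(is.na(m))[1], ], collapse = "-"))
    for (r in seq_len(nrow(system$angles))) {
      tri <- system$angles[r, ]
      th <- bond_angle(pos[tri[1], ], pos[tri[2], ], pos[tri[3], ]) * pi / 180
      e_angle <- e_angle + pa$ktheta[m[r]] * (th - pa$theta0[m[r]])^2
    }
  }

  if (nrow(system$dihedrals) > 0) {
    pd <- params$dihedrals
    if (is.null(pd))
      stop("parameterization error: no dihedral parameters supplied")
    dkey <- function(i, j, k, l)
      ifelse(j < k | (j == k & i <= l), paste(i, j, k, l), paste(l, k, j, i))
    m <- match(dkey(system$dihedrals[, 1], system$dihedrals[, 2],
                    system$dihedrals[, 3], system$dihedrals[, 4]),
               dkey(pd$i, pd$j, pd$k, pd$l))
    if (anyNA(m))
      stop("parameterization error: no dihedral parameters for atoms ",
           paste(system$dihedrals[which(is.na(m))[1], ], collapse = "-"))
    for (r in seq_len(nrow(system$dihedrals))) {
      q <- system$dihedrals[r, ]
      phi <- dihedral(pos[q[1], ], pos[q[2], ], pos[q[3], ], pos[q[4], ]) * pi / 180
      e_dih <- e_dih +
        pd$kphi[m[r]] * (1 + cos(pd$n[m[r]] * phi - pd$delta[m[r]]))
    }
  }

  nb <- .nonbonded_pairs(system, params)
  if (!is.null(nb)) {
    d <- pos[nb$i, , drop = FALSE] - pos[nb$j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    has_lj <- nb$a > 0 | nb$b > 0
    if (any(has_lj))
      e_lj <- sum(nb$a[has_lj] / r[has_lj]^12 - nb$b[has_lj] / r[has_lj]^6)
    if (params$coulomb) {
      qq <- system$charges[nb$i] * system$charges[nb$j]
      e_coul <- sum(.COULOMB * qq / r)
    }
  }

  energy_breakdown(bond = e_bond, angle = e_angle, dihedral = e_dih,
                   lennard_jones = e_lj, electrostatic = e_coul)
}

#' Forces of the toy force field
#'
#' Negative gradient of [mm_total_energy()]. Bond, angle, Lennard-Jones and
#' Coulomb gradients are analytic; the dihedral contribution uses a central
#' finite difference confined to its four atoms. `method = "numeric"` falls
#' back to a full central difference of the total energy.
#'
#' @inheritParams mm_total_energy
#' @param method `"analytic"` (default) or `"numeric"`.
#' @param h Finite-difference step, Angstrom.
#' @return Numeric matrix (atoms x 3) of forces, kcal/(mol Angstrom).
#' @export
mm_forces <- function(system, params, method = c("analytic", "numeric"),
                      h = 1e-5) {
  method <- match.arg(method)
  if (method == "numeric") return(.numeric_forces(system, params, h))
  pos <- system$positions
  n <- n_atoms(system)
  grad <- matrix(0, n, 3)

  if (nrow(system$bonds) > 0) {
    pb <- params$bonds
    m <- match(.pair_key(system$bonds[, 1], system$bonds[, 2]),
               .pair_key(pb$i, pb$j))
    for (r in seq_len(nrow(system$bonds))) {
      i <- system$bonds[r, 1]; j <- system$bonds[r, 2]
      d <- pos[i, ] - pos[j, ]
      rr <- sqrt(sum(d^2))
      # dE/dr = 2 kb (r - r0)
      g <- 2 * pb$kb[m[r]] * (rr - pb$r0[m[r]]) * d / rr
      grad[i, ] <- grad[i, ] + g
      grad[j, ] <- grad[j, ] - g
    }
  }

  if (nrow(system$angles) > 0) {
    pa <- params$angles
    akey <- function(i, j, k) paste(pmin(i, k), j, pmax(i, k))
    m <- match(akey(system$angles[, 1], system$angles[, 2], system$angles[, 3]),
               akey(pa$i, pa$j, pa$k))
    for (r in seq_len(nrow(system$angles))) {
      i <- system$angles[r, 1]; j <- system$angles[r, 2]; k <- system$angles[r, 3]
      u <- pos[i, ] - pos[j, ]
      v <- pos[k, ] - pos[j, ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      uh <- u / nu; vh <- v / nv
      cth <- min(1, max(-1, sum(uh * vh)))
      th <- acos(cth)
      sth <- sqrt(max(1e-12, 1 - cth^2))
      dEdth <- 2 * pa$ktheta[m[r]] * (th - pa$theta0[m[r]])
      dth_di <- (cth * uh - vh) / (nu * sth)
      dth_dk <- (cth * vh - uh) / (nv * sth)
      grad[i, ] <- grad[i, ] + dEdth * dth_di
      grad[k, ] <- grad[k, ] + dEdth * dth_dk
      grad[j, ] <- grad[j, ] - dEdth * (dth_di + dth_dk)
    }
  }

  if (nrow(system$dihedrals) > 0) {
    pd <- params$dihedrals
    dkey <- function(i, j, k, l)
      ifelse(j < k | (j == k & i <= l), paste(i, j, k, l), paste(l, k, j, i))
    m <- match(dkey(system$dihedrals[, 1], system$dihedrals[, 2],
                    system$dihedrals[, 3], system$dihedrals[, 4]),
               dkey(pd$i, pd$j, pd$k, pd$l))
    hd <- 1e-6
    for (r in seq_len(nrow(system$dihedrals))) {
      q <- system$dihedrals[r, ]
      eterm <- function(p) {
        phi <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ]) * pi / 180
        pd$kphi[m[r]] * (1 + cos(pd$n[m[r]] * phi - pd$delta[m[r]]))
      }
      p4 <- pos[q, , drop = FALSE]
      for (a in 1:4) for (x in 1:3) {
        pp <- p4; pp[a, x] <- pp[a, x] + hd
        pm <- p4; pm[a, x] <- pm[a, x] - hd
        grad[q[a], x] <- grad[q[a], x] + (eterm(pp) - eterm(pm)) / (2 * hd)
      }
    }
  }

  nb <- .nonbonded_pairs(system, params)
  if (!is.null(nb)) {
    d <- pos[nb$i, , drop = FALSE] - pos[nb$j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    dEdr <- -12 * nb$a / r^13 + 6 * nb$b / r^7
    if (params$coulomb)
      dEdr <- dEdr - .COULOMB * system$charges[nb$i] * system$charges[nb$j] / r^2
    g <- d * (dEdr / r)
    for (p in seq_along(nb$i)) {
      grad[nb$i[p], ] <- grad[nb$i[p], ] + g[p, ]
      grad[nb$j[p], ] <- grad[nb$j[p], ] - g[p, ]
    }
  }

  if (!all(is.finite(grad)))
    stop("mm_forces: non-finite force (overlapping atoms?)")
  -grad
}

.numeric_forces <- function(system, params, h) {
  pos <- system$positions
  n <- n_atoms(system)
  grad <- matrix(0, n, 3)
  sys2 <- system
  for (a in seq_len(n)) for (x in 1:3) {
    sys2$positions <- pos; sys2$positions[a, x] <- pos[a, x] + h
    ep <- mm_total_energy(sys2, params)$total
    sys2$positions[a, x] <- pos[a, x] - h
    em <- mm_total_energy(sys2, params)$total
    grad[a, x] <- (ep - em) / (2 * h)
  }
  -grad
}
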