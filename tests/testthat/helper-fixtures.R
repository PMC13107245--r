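# Shared fixture builders. Everything is generated in code; nothing binary.

# random proper rotation matrix (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(qr_d)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# a 10-atom chain with bonds, angles, one dihedral, default LJ and charges:
# generic fully parameterized system for force-field tests
make_chain_system <- function(n = 10, seed = 1) {
  set.seed(seed)
  # a jittered extended chain avoids overlapping nonbonded pairs
  pos <- cbind(seq_len(n) * 1.5, rnorm(n, 0, 0.25), rnorm(n, 0, 0.25))
  bonds <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
  angles <- if (n >= 3) cbind(seq_len(n - 2), seq_len(n - 2) + 1,
                              seq_len(n - 2) + 2) else NULL
  dihedrals <- if (n >= 4) cbind(1, 2, 3, 4) else NULL
  system <- toy_system(rep("C", n), pos, charges = rnorm(n, 0, 0.2),
                       bonds = bonds, angles = angles, dihedrals = dihedrals)
  params <- force_field(
    bonds = data.frame(i = bonds[, 1], j = bonds[, 2],
                       kb = runif(n - 1, 200, 400),
                       r0 = runif(n - 1, 1.3, 1.6)),
    angles = if (!is.null(angles))
      data.frame(i = angles[, 1], j = angles[, 2], k = angles[, 3],
                 ktheta = runif(nrow(angles), 30, 80),
                 theta0 = runif(nrow(angles), 1.7, 2.1)),
    dihedrals = if (!is.null(dihedrals))
      data.frame(i = 1, j = 2, k = 3, l = 4, kphi = 2.5, n = 3,
                 delta = 0.4),
    lj_default = c(5000, 50),
    coulomb = TRUE
  )
  list(system = system, params = params)
}

# LJ dimer: two atoms with explicit pair parameters, no bonded terms.
# Defaults give a 0.3 kcal/mol well at r = 3.17 A (argon-like scale).
make_lj_dimer <- function(a = 3e5, b = 600, r = NULL) {
  if (is.null(r)) r <- (2 * a / b)^(1 / 6)
  system <- toy_system(c("Ar", "Ar"), rbind(c(0, 0, 0), c(r, 0, 0)))
  params <- force_field(lj = data.frame(i = 1, j = 2, a = a, b = b))
  list(system = system, params = params, rmin = (2 * a / b)^(1 / 6),
       emin = -b^2 / (4 * a))
}

# donor/hydrogen/acceptor positions with exact D..A distance (A) and
# D-H...A angle (deg), |D-H| = 1.0 A: law-of-cosines triangle construction
hbond_frame <- function(d, ang) {
  th <- ang * pi / 180
  q <- cos(th) + sqrt(d^2 - sin(th)^2)
  hx <- (1 + d^2 - q^2) / (2 * d)
  hy <- sqrt(max(0, 1 - hx^2))
  rbind(c(0, 0, 0), c(hx, hy, 0), c(d, 0, 0))
}

# PDB v3.3 ATOM/HETATM line with fixed-width columns
pdb_line <- function(record, serial, name, res, x, y, z, element = NULL) {
  base <- sprintf("%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                  record, serial, name, res, serial, x, y, z, 1, 0)
  if (is.null(element)) return(base)  # element columns absent
  paste0(base, "          ", formatC(element, width = 2))
}

# harmonic-oscillator MD fixture: light atom bonded to a quasi-fixed heavy
# anchor; returns everything needed for period/energy analysis
make_oscillator <- function(kb = 100, m = 12.011, amplitude = 0.2) {
  system <- toy_system(c("C", "C"),
                       rbind(c(0, 0, 0), c(1.5 + amplitude, 0, 0)),
                       masses = c(1e12, m),
                       bonds = cbind(1, 2))
  params <- force_field(bonds = data.frame(i = 1, j = 2, kb = kb, r0 = 1.5))
  acc <- unit_constants()$acc
  omega <- sqrt(2 * kb * acc / m)          # rad/fs (no 1/2 in the bond term)
  list(system = system, params = params, period = 2 * pi / omega,
       amplitude = amplitude, r0 = 1.5)
}
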