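test_that("XYZ files round-trip and degenerate inputs behave", {
  f <- withr::local_tempfile(fileext = ".xyz")

  writeLines(c("1", "lone ion", "Mn 0 0 0"), f)
  sys <- read_xyz(f)
  expect_equal(n_atoms(sys), 1)
  expect_equal(sys$elements, "Mn")
  expect_equal(sys$masses, element_mass("Mn"))

  writeLines(c("0", "empty"), f)
  expect_equal(n_atoms(read_xyz(f)), 0)

  writeLines(c("two", "bad count", "C 0 0 0"), f)
  expect_error(read_xyz(f), "line 1")
  writeLines(c("1", "bad coord", "C 0 zero 0"), f)
  expect_error(read_xyz(f), "line 3")

  set.seed(7)
  sys <- toy_system(sample(c("C", "N", "O", "Mn"), 15, TRUE),
                    matrix(runif(45, -20, 20), 15, 3))
  write_xyz(sys, f)
  back <- read_xyz(f)
  expect_equal(back$positions, sys$positions, tolerance = 1e-6)
  expect_equal(back$elements, sys$elements)
  expect_equal(readLines(f)[1], "15")

  # a 3-atom system is a 5-line file; an empty one has a "0" count line
  write_xyz(toy_system(c("O", "H", "H"), matrix(rnorm(9), 3, 3)), f)
  expect_length(readLines(f), 5)
  write_xyz(toy_system(character(0), matrix(numeric(0), ncol = 3)), f)
  expect_equal(readLines(f)[1], "0")
})

test_that("trajectories export as multi-frame XYZ", {
  g <- gen_hbond_trajectory(trajectory_spec(n_frames = 3, seed = 99))
  sys <- toy_system(c("O", "H", "O"), g$trajectory$positions[1, , ])
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_frames(g$trajectory, sys, f)
  lines <- readLines(f)
  expect_length(lines, 3 * (3 + 2))          # 3 frames of count+comment+atoms
  expect_equal(lines[1], "3")
  first <- read_xyz(f)                        # first frame parses standalone
  expect_equal(first$positions, g$trajectory$positions[1, , ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("PDB ATOM/HETATM parsing follows fixed widths and infers elements", {
  f <- withr::local_tempfile(fileext = ".pdb")

  writeLines(pdb_line("HETATM", 1, "MN", "MN", 1.5, -2.25, 3.125, "MN"), f)
  sys <- read_pdb_coords(f)
  expect_equal(n_atoms(sys), 1)
  expect_equal(sys$elements, "Mn")
  expect_equal(sys$positions[1, ], c(1.5, -2.25, 3.125))

  # element columns missing: inferred from the atom-name field; compare
  # against the hand-built record values
  writeLines(c(pdb_line("ATOM", 1, "OD1", "ASP", 0.1, 0.2, 0.3),
               pdb_line("ATOM", 2, "CA", "ASP", 1, 2, 3)), f)
  sys <- read_pdb_coords(f)
  expect_equal(sys$elements, c("O", "Ca"))
  expect_equal(sys$positions, rbind(c(0.1, 0.2, 0.3), c(1, 2, 3)))

  # 10 mixed records in order, with non-coordinate records ignored
  lines <- c("HEADER    test", "REMARK 1",
             vapply(1:10, function(i)
               pdb_line(if (i %% 2) "ATOM" else "HETATM", i, "C", "LIG",
                        i, 0, 0, "C"), character(1)),
             "END")
  writeLines(lines, f)
  sys <- read_pdb_coords(f)
  expect_equal(n_atoms(sys), 10)
  expect_equal(sys$positions[, 1], as.numeric(1:10))

  writeLines("HEADER only", f)
  expect_warning(sys <- read_pdb_coords(f), "no ATOM/HETATM")
  expect_equal(n_atoms(sys), 0)
})

test_that("distance is Euclidean, symmetric, and obeys the triangle inequality", {
  expect_equal(distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(distance(c(0, 0, 0), c(0, 0, 2.08)), 2.08)
  set.seed(11)
  for (i in 1:50) {
    a <- rnorm(3, 0, 5); b <- rnorm(3, 0, 5); c <- rnorm(3, 0, 5)
    brute <- sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2)
    expect_equal(distance(a, b), brute, tolerance = 1e-12)
    expect_identical(distance(a, b), distance(b, a))
    expect_lte(distance(a, c), distance(a, b) + distance(b, c) + 1e-12)
  }
  expect_error(distance(c(0, 0, Inf), c(0, 0, 0)), "finite")
})

test_that("bond angles match the law-of-cosines oracle", {
  expect_equal(bond_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  expect_equal(bond_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  set.seed(12)
  for (i in 1:50) {
    p1 <- rnorm(3); ap <- rnorm(3); p2 <- rnorm(3)
    a <- distance(ap, p1); b <- distance(ap, p2); c <- distance(p1, p2)
    oracle <- acos(min(1, max(-1, (a^2 + b^2 - c^2) / (2 * a * b)))) * 180 / pi
    expect_equal(bond_angle(p1, ap, p2), oracle, tolerance = 1e-9)
  }
  expect_error(bond_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("dihedrals are signed torsions matching a normal-vector oracle", {
  # planar cis and trans references
  expect_equal(dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(dihedral(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  set.seed(13)
  for (i in 1:50) {
    p <- matrix(rnorm(12, 0, 2), 4, 3)
    b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
    cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                              a[3] * b[1] - a[1] * b[3],
                              a[1] * b[2] - a[2] * b[1])
    n1 <- cross(b1, b2); n2 <- cross(b2, b3)
    cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
    oracle <- acos(min(1, max(-1, cosphi))) * 180 / pi
    oracle <- oracle * sign(sum(cross(n1, n2) * b2))
    if (oracle == 0) oracle <- abs(oracle)
    got <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(abs(got), abs(oracle), tolerance = 1e-9)
    if (abs(oracle) > 1e-6 && abs(abs(oracle) - 180) > 1e-6)
      expect_equal(sign(got), sign(oracle))
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "degenerate")
})

test_that("coordination number is the Gaussian-smoothed ligand count", {
  cl <- gen_mn_cluster(cluster_spec(spread = 0, seed = 1))
  expect_equal(coordination_number(cl$system, cl$model), 4)

  one <- toy_system(c("Mn", "O"), rbind(c(0, 0, 0), c(2.08 + 0.05, 0, 0)))
  m <- coordination_model(1, 2, r0 = 2.08, sigma = 0.05)
  expect_equal(coordination_number(one, m), exp(-0.5), tolerance = 1e-12)

  set.seed(14)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    cl <- gen_mn_cluster(cluster_spec(n, geometry = "random_sphere",
                                      spread = 0.1, seed = 100 + i))
    ri <- sqrt(rowSums(cl$system$positions[-1, , drop = FALSE]^2))
    oracle <- sum(exp(-(ri - 2.08)^2 / (2 * 0.05^2)))
    expect_equal(coordination_number(cl$system, cl$model), oracle,
                 tolerance = 1e-12)
  }

  # monotone decay as a single ligand leaves the ideal shell
  base <- coordination_number(one, m)
  vals <- vapply(seq(0.06, 0.5, by = 0.02), function(dr) {
    s <- one; s$positions[2, 1] <- 2.08 + dr
    coordination_number(s, m)
  }, numeric(1))
  expect_true(all(diff(c(base, vals)) < 0))
})

test_that("effective charge is linear, screened, and rigid-motion invariant", {
  empty <- toy_system("Mn", matrix(0, 1, 3))
  expect_equal(effective_charge(empty, coordination_model(1, integer(0))), 0)

  cc <- unit_constants()$coulomb
  one <- toy_system(c("Mn", "O"), rbind(c(0, 0, 0), c(2.08, 0, 0)),
                    charges = c(1.82, -0.40))
  m <- coordination_model(1, 2, k = 1.2)
  oracle <- -0.40 * exp(-1.2 * 2.08) * cc / 2.08
  expect_equal(effective_charge(one, m), oracle, tolerance = 1e-12)

  two <- one; two$charges <- two$charges * 2
  expect_equal(effective_charge(two, m), 2 * effective_charge(one, m))

  set.seed(15)
  cl <- gen_mn_cluster(cluster_spec(seed = 5))
  q0 <- effective_charge(cl$system, cl$model)
  for (i in 1:5) {
    rot <- random_rotation()
    shift <- rnorm(3, 0, 10)
    moved <- cl$system
    moved$positions <- sweep(cl$system$positions %*% rot, 2, shift, `+`)
    expect_equal(effective_charge(moved, cl$model), q0, tolerance = 1e-10)
  }

  coincident <- toy_system(c("Mn", "O"), matrix(0, 2, 3), charges = c(2, -0.4))
  expect_error(effective_charge(coincident, m), "geometry")
})

test_that("toy_system validates topology and masses", {
  pos <- matrix(rnorm(9), 3, 3)
  expect_error(toy_system("Xx", matrix(0, 1, 3)), "unknown element")
  expect_error(toy_system(c("C", "C", "C"), pos, bonds = rbind(c(1, 4))),
               "out of range")
  expect_error(toy_system(c("C", "C", "C"), pos, bonds = rbind(c(2, 2))),
               "repeated")
  expect_error(toy_system(c("C", "C", "C"), pos,
                          bonds = rbind(c(1, 2), c(2, 1))), "duplicate")
})
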