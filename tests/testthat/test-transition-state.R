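flat <- potential_surface(function(x) 0 * sum(x), function(x) 0 * x,
                          dimension = 2)

test_that("band forces vanish at the fixed point and are pure springs off it", {
  st <- neb_settings(n_images = 5)
  # equally spaced collinear images on a flat surface
  images <- cbind(seq(0, 1, length.out = 5), seq(0, 2, length.out = 5))
  f <- neb_forces(images, flat, st)
  expect_equal(f, matrix(0, 5, 2), tolerance = 1e-12)

  # single interior image displaced off the chord: pure spring restoring force
  images[3, ] <- images[3, ] + c(0.1, -0.2)
  f <- neb_forces(images, flat, st)
  expected <- st$spring * (images[4, ] + images[2, ] - 2 * images[3, ])
  expect_equal(f[3, ], expected, tolerance = 1e-12)

  expect_error(neb_forces(images[1:2, ], flat, st), "3 images")
})

test_that("CI-NEB recovers the quartic double-well barrier", {
  dw <- gen_double_well_surface(surface_spec(barrier = 5))
  res <- run_neb(-1, 1, dw$surface, neb_settings())
  expect_true(res$converged)
  expect_equal(res$barrier_forward, 5, tolerance = 0.01)
  expect_equal(res$barrier_reverse, 5, tolerance = 0.01)
  expect_lt(abs(res$images[res$saddle_index, 1]), 0.1)

  # degenerate band: start = end converges immediately with zero barrier
  same <- run_neb(-1, -1, dw$surface, neb_settings(max_iterations = 50))
  expect_true(same$converged)
  expect_equal(same$barrier_forward, 0, tolerance = 1e-10)

  # path energies are unimodal for a single-barrier surface
  e <- res$energies
  peak <- which.max(e)
  expect_true(all(diff(e[1:peak]) >= -1e-9))
  expect_true(all(diff(e[peak:length(e)]) <= 1e-9))
})

test_that("CI-NEB matches the grid-minimax oracle on a 2-D surface", {
  s2 <- gen_double_well_surface(surface_spec("two_minimum_2d", barrier = 8,
                                             tilt = 1))
  res <- run_neb(s2$truth$minima[1, ], s2$truth$minima[2, ], s2$surface,
                 neb_settings())
  expect_true(res$converged)
  e_saddle_neb <- res$energies[res$saddle_index]
  e_saddle_grid <- surface_energy(s2$surface, s2$truth$saddle_grid)
  expect_equal(e_saddle_neb, e_saddle_grid,
               tolerance = 0.005 * abs(e_saddle_grid))
  expect_equal(res$barrier_forward, s2$truth$barrier_forward,
               tolerance = 0.005 * s2$truth$barrier_forward)
})

test_that("finite-difference Hessians are exact on polynomial surfaces", {
  bowl <- potential_surface(function(x) 0.5 * 37 * x[1]^2, dimension = 1)
  h <- finite_difference_hessian(bowl, 0.3)
  expect_equal(h[1, 1], 37, tolerance = 1e-5)

  saddle <- potential_surface(function(x) 0.5 * 4 * x[1]^2 - 0.5 * 9 * x[2]^2,
                              dimension = 2)
  h <- finite_difference_hessian(saddle, c(0, 0))
  expect_equal(sort(eigen(h)$values), c(-9, 4), tolerance = 1e-6)

  # random cubic surface vs analytic second derivatives
  set.seed(41)
  for (rep in 1:5) {
    a <- rnorm(3); b <- rnorm(3); cxy <- rnorm(1)
    cub <- potential_surface(function(x)
      sum(a * x^3) + sum(b * x^2) + cxy * x[1] * x[2], dimension = 3)
    p <- rnorm(3, 0, 0.5)
    h <- finite_difference_hessian(cub, p, step = 1e-4)
    ana <- diag(6 * a * p + 2 * b)
    ana[1, 2] <- ana[2, 1] <- cxy
    expect_lt(max(abs(h - ana)), 1e-5)
  }
  expect_error(finite_difference_hessian(bowl, 0, step = 0), "step")
})

test_that("normal modes convert curvatures to wavenumbers with reduced masses", {
  uc <- unit_constants()
  k <- 350; m <- 12.011
  osc <- potential_surface(function(x) 0.5 * k * x[1]^2, dimension = 1)
  nm <- normal_modes(finite_difference_hessian(osc, 0), masses = m)
  expect_equal(nm$n_imaginary, 0)
  expect_equal(nm$frequencies_cm[1], uc$freq_cm * sqrt(k / m),
               tolerance = 1e-5)
  expect_equal(nm$reduced_masses[1], m, tolerance = 1e-9)

  k1 <- 4; k2 <- 9
  sad <- potential_surface(function(x) 0.5 * k1 * x[1]^2 - 0.5 * k2 * x[2]^2,
                           dimension = 2)
  nm <- normal_modes(finite_difference_hessian(sad, c(0, 0)))
  expect_equal(nm$n_imaginary, 1)
  expect_equal(nm$frequencies_cm[nm$imaginary], uc$freq_cm * sqrt(k2),
               tolerance = 1e-5)
  # eigenvectors orthonormal
  v <- nm$modes
  expect_equal(t(v) %*% v, diag(2), tolerance = 1e-10)

  expect_error(normal_modes(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
})

test_that("stationary points classify by imaginary-mode count and overlap", {
  bowl <- normal_modes(diag(c(2, 3)))
  expect_equal(classify_stationary_point(bowl), "minimum")

  sad1 <- normal_modes(diag(c(-2, 3)))
  expect_equal(classify_stationary_point(sad1), "transition_state")
  # the imaginary mode lies on coordinate 1: declaring coordinate 2 as the
  # reaction coordinate must reject it
  expect_equal(classify_stationary_point(sad1, reaction_coords = 1),
               "transition_state")
  expect_equal(classify_stationary_point(sad1, reaction_coords = 2),
               "higher_order_saddle")

  sad2 <- normal_modes(diag(c(-2, -3, 1)))
  expect_equal(classify_stationary_point(sad2), "higher_order_saddle")

  # classification is invariant under uniform mass scaling
  h <- diag(c(-5, 1, 7))
  for (s in c(0.1, 1, 12)) {
    nm <- normal_modes(h, masses = s * c(1, 12, 16))
    expect_equal(nm$n_imaginary, 1)
  }
})

test_that("descent paths from a saddle end in the flanking minima", {
  dw <- gen_double_well_surface(surface_spec(barrier = 5))
  de <- descend_path(dw$surface, 0, 1)
  ends <- sort(c(de$forward$endpoint, de$backward$endpoint))
  expect_equal(ends, c(-1, 1), tolerance = 1e-3)

  s2 <- gen_double_well_surface(surface_spec("two_minimum_2d", barrier = 6))
  nm <- normal_modes(finite_difference_hessian(s2$surface, s2$truth$saddle))
  mode <- nm$modes[, which(nm$imaginary)]
  de <- descend_path(s2$surface, s2$truth$saddle, mode)
  reached <- rbind(de$forward$endpoint, de$backward$endpoint)
  planted <- s2$truth$minima
  d1 <- min(sqrt(rowSums((reached - planted[rep(1, 2), ])^2)))
  d2 <- min(sqrt(rowSums((reached - planted[rep(2, 2), ])^2)))
  expect_lt(d1, 1e-3)
  expect_lt(d2, 1e-3)

  # degenerate use: descending from a minimum stays there
  stay <- descend_path(dw$surface, 1, 1, displacement = 1e-4)
  expect_equal(stay$forward$endpoint, 1, tolerance = 1e-3)
})

test_that("activation energies follow barrier symmetry and tilt", {
  dw <- gen_double_well_surface(surface_spec(barrier = 5))
  res <- run_neb(-1, 1, dw$surface, neb_settings())
  expect_equal(activation_energy(res), res$barrier_forward)
  expect_equal(res$barrier_forward, res$barrier_reverse, tolerance = 1e-6)

  tw <- gen_double_well_surface(surface_spec(barrier = 5, tilt = 2))
  res_t <- run_neb(tw$truth$minima[1], tw$truth$minima[2], tw$surface,
                   neb_settings())
  # independent oracle: locate the minima with optimize() and compare the
  # barrier asymmetry with the energy difference of the two wells
  f <- function(x) surface_energy(tw$surface, x)
  m1 <- stats::optimize(f, c(-1.5, -0.5))
  m2 <- stats::optimize(f, c(0.5, 1.5))
  expect_equal(res_t$barrier_forward - res_t$barrier_reverse,
               m2$objective - m1$objective, tolerance = 0.02)

  unconv <- run_neb(-1, 1, dw$surface,
                    neb_settings(max_iterations = 3))
  expect_warning(activation_energy(unconv), "not converged")
})
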